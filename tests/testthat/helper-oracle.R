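# Independent brute-force oracles: dense-vector arithmetic and all-pairs
# enumeration, sharing no code with the package's sparse/windowed path.

oracle_dense_vec <- function(peaks, params) {
  peaks <- as.matrix(peaks)
  intensity <- peaks[, 2]
  floor_abs <- params$noise_floor
  if (is.na(floor_abs)) {
    floor_abs <- params$noise_floor_relative * 1e-3 *
      (if (length(intensity)) max(intensity) else 0)
  }
  keep <- intensity >= floor_abs & intensity > 0
  mz <- peaks[keep, 1]
  w <- intensity[keep]^params$scaling_exponent
  bins <- floor(mz / params$bin_width)
  tapply(w, bins, sum)
}

oracle_score <- function(peaks_a, peaks_b, params) {
  va <- oracle_dense_vec(peaks_a, params)
  vb <- oracle_dense_vec(peaks_b, params)
  if (is.null(va) || is.null(vb) || !length(va) || !length(vb)) return(0)
  all_bins <- union(names(va), names(vb))
  a <- setNames(rep(0, length(all_bins)), all_bins)
  b <- a
  a[names(va)] <- va
  b[names(vb)] <- vb
  d <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  d <- min(1, max(0, d))
  if (params$measure == "cosine") d else 1 - 2 * acos(d) / pi
}

# All-pairs score matrix via dense crossprod (rows of A x rows of B)
oracle_score_matrix <- function(A, B, params) {
  vecs_a <- lapply(A$peaks, oracle_dense_vec, params = params)
  vecs_b <- lapply(B$peaks, oracle_dense_vec, params = params)
  all_bins <- unique(unlist(c(lapply(vecs_a, names), lapply(vecs_b, names))))
  densify <- function(vs) {
    m <- matrix(0, nrow = length(all_bins), ncol = length(vs),
                dimnames = list(all_bins, NULL))
    for (k in seq_along(vs)) {
      v <- vs[[k]]
      if (!is.null(v) && length(v)) m[names(v), k] <- v
    }
    nrm <- sqrt(colSums(m^2))
    nrm[nrm == 0] <- 1
    sweep(m, 2, nrm, "/")
  }
  s <- crossprod(densify(vecs_a), densify(vecs_b))
  s <- pmin(1, pmax(0, s))
  if (params$measure != "cosine") s <- 1 - 2 * acos(s) / pi
  s
}

# window-pass indicator matrix mirroring the documented window rules
oracle_window_matrix <- function(A, B, window) {
  n_a <- nrow(A)
  n_b <- nrow(B)
  ok <- outer(A$precursor_mz, B$precursor_mz,
              function(x, y) abs(x - y) <= window$max_precursor_dmz)
  for (i in seq_len(n_a)) {
    for (j in seq_len(n_b)) {
      if (!ok[i, j]) next
      if (!is.na(A$retention_time[i]) && !is.na(B$retention_time[j])) {
        ok[i, j] <- abs(A$retention_time[i] - B$retention_time[j]) <=
          window$max_rt_diff
      } else if (!is.na(A$scan_number[i]) && !is.na(B$scan_number[j])) {
        ok[i, j] <- abs(A$scan_number[i] - B$scan_number[j]) <=
          window$max_scan_diff
      }
    }
  }
  ok
}

oracle_matched_counts <- function(A, B, params, window) {
  if (nrow(A) == 0 || nrow(B) == 0) {
    return(list(matched_a = 0L, matched_b = 0L))
  }
  hit <- oracle_score_matrix(A, B, params) >= params$s_min &
    oracle_window_matrix(A, B, window)
  list(matched_a = sum(apply(hit, 1, any)),
       matched_b = sum(apply(hit, 2, any)))
}

# tiny literal datasets for hand-constructed cases
peaks_at <- function(mz, intensity = rep(100, length(mz))) {
  cbind(mz = mz, intensity = intensity)
}

tiny_dataset <- function(peak_list, precursor_mz,
                         retention_time = rep(NA_real_, length(peak_list)),
                         scan_number = rep(NA_integer_, length(peak_list)),
                         label = "tiny") {
  ms2_dataset(tibble::tibble(
    title = sprintf("%s_%d", label, seq_along(peak_list)),
    precursor_mz = precursor_mz,
    charge = rep(2L, length(peak_list)),
    retention_time = retention_time,
    scan_number = scan_number,
    peaks = peak_list
  ), label = label)
}

open_params <- function(...) {
  similarity_params(scaling_exponent = 1, noise_floor = 0, ...)
}

infinite_window <- function() {
  comparison_window(max_precursor_dmz = Inf, max_rt_diff = Inf,
                    max_scan_diff = Inf)
}
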