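#' Global similarity between two spectrum sets
#'
#' The average of the two directional matched fractions: the fraction of
#' spectra in A with at least one similar spectrum in B, and vice versa,
#'
#' \deqn{S = \frac{1}{2}\left(\frac{|A_B|}{|A|} + \frac{|B_A|}{|B|}\right)}
#'
#' `S` is symmetric and lies in `[0, 1]`. It is undefined (returned as
#' `NA`) when either set is empty — an empty MS/MS dataset usually means
#' the measurement failed, so the value is propagated rather than imputed.
#'
#' @param n_a,n_b Set cardinalities `|A|`, `|B|` (non-negative).
#' @param matched_a Number of spectra in A with a similar spectrum in B.
#' @param matched_b Number of spectra in B with a similar spectrum in A.
#' @return `S` in `[0, 1]`, or `NA_real_` when a set is empty.
#' @examples
#' global_similarity(4, 2, 1, 1)  # 0.375
#' @export
global_similarity <- function(n_a, n_b, matched_a, matched_b) {
  stopifnot(n_a >= 0, n_b >= 0, matched_a >= 0, matched_b >= 0)
  if (matched_a > n_a || matched_b > n_b) {
    abort("matched count exceeds set cardinality (internal inconsistency).")
  }
  if (n_a == 0 || n_b == 0) return(NA_real_)
  (matched_a / n_a + matched_b / n_b) / 2
}

#' Global distance between two spectrum sets
#'
#' `D = 1/S - 1` when `S > 0`. When `S = 0` the distance is kept finite by
#' treating the sets as if they shared a hypothetical half matching
#' spectrum: the smallest positive similarity is
#' `S_minpos = (1/n_a + 1/n_b) / 2` (exactly one similar pair), and
#' `D = 1 / (S_minpos / 2) - 1`. For two singleton sets this gives `D = 0`
#' when the spectra are similar and `D = 1` otherwise. An undefined `S`
#' propagates to an undefined `D`.
#'
#' @param S Global similarity in `[0, 1]`, or `NA`.
#' @param n_a,n_b Set cardinalities (required only when `S == 0`).
#' @return `D >= 0`, or `NA_real_`.
#' @examples
#' global_distance(0.5)          # 1
#' global_distance(0, 10, 40)    # 31
#' @export
global_distance <- function(S, n_a = NULL, n_b = NULL) {
  if (is.na(S)) return(NA_real_)
  if (S < 0 || S > 1) abort("S must lie in [0, 1].")
  if (S > 0) return(1 / S - 1)
  if (is.null(n_a) || is.null(n_b) || n_a < 1 || n_b < 1) {
    abort("the S = 0 distance floor needs both cardinalities (>= 1).")
  }
  s_minpos <- (1 / n_a + 1 / n_b) / 2
  1 / (s_minpos / 2) - 1
}

# Chromatographic closeness: RT difference when both spectra have RT,
# otherwise scan difference, otherwise unconstrained.
chrom_close <- function(rt_a, rt_b, scan_a, scan_b, window) {
  if (!is.na(rt_a) && !is.na(rt_b)) {
    return(abs(rt_a - rt_b) <= window$max_rt_diff)
  }
  if (!is.na(scan_a) && !is.na(scan_b)) {
    return(abs(scan_a - scan_b) <= window$max_scan_diff)
  }
  TRUE
}

new_pair_histogram <- function(window,
                               dmz_bin = 0.01, sim_bin = 0.01,
                               dmz_limit = NULL) {
  if (is.null(dmz_limit)) {
    dmz_limit <- if (is.finite(window$max_precursor_dmz)) {
      window$max_precursor_dmz
    } else {
      2.05
    }
  }
  n_dmz <- max(1L, ceiling(round(2 * dmz_limit / dmz_bin, 9)))
  n_sim <- max(1L, ceiling(round(1 / sim_bin, 9)))
  h <- matrix(
    0L, nrow = n_dmz, ncol = n_sim,
    dimnames = list(
      dmz = formatC(-dmz_limit + (seq_len(n_dmz) - 0.5) * dmz_bin,
                    format = "g", digits = 8),
      similarity = formatC((seq_len(n_sim) - 0.5) * sim_bin,
                           format = "g", digits = 8)
    )
  )
  attr(h, "dmz_bin") <- dmz_bin
  attr(h, "sim_bin") <- sim_bin
  attr(h, "dmz_limit") <- dmz_limit
  h
}

hist_cell <- function(h, dmz, s) {
  dmz_bin <- attr(h, "dmz_bin")
  sim_bin <- attr(h, "sim_bin")
  lim <- attr(h, "dmz_limit")
  i <- floor((dmz + lim) / dmz_bin) + 1
  i <- pmin(pmax(i, 1L), nrow(h))
  j <- floor(s / sim_bin) + 1
  j <- pmin(pmax(j, 1L), ncol(h))
  cbind(i, j)
}

#' Compare two MS/MS datasets
#'
#' The set-comparison workhorse. Every spectrum in `a` is scored against
#' the spectra of `b` that fall inside the candidate window (precursor m/z
#' difference, and retention time or scan number; see
#' [comparison_window()]). A spectrum counts as matched when at least one
#' windowed counterpart scores `>= s_min`. From the two matched counts the
#' global similarity `S` and distance `D` are derived
#' ([global_similarity()], [global_distance()]). Every evaluated pair also
#' contributes one count to a two-dimensional histogram of signed precursor
#' m/z difference (`mz(b) - mz(a)`) by similarity, a diagnostic that
#' reveals charge states and isotope-selection errors without any database
#' search.
#'
#' Candidates are found by binary search on `b`'s precursor m/z order, so
#' results are identical to brute-force all-pairs evaluation, only faster.
#'
#' @param a,b [ms2_dataset] objects.
#' @param params [similarity_params()].
#' @param window [comparison_window()].
#' @param histogram Logical; accumulate the diagnostic histogram?
#' @param hist_dmz_bin,hist_sim_bin Histogram bin widths (Th; similarity).
#' @return An object of class `ms2_comparison`: a list with the labels,
#'   cardinalities `n_a`/`n_b`, matched counts, `S`, `D`, the directional
#'   matched fractions and the histogram matrix. `S` and `D` are `NA` when
#'   either dataset is empty.
#' @examples
#' pair <- make_dataset_pair(n_spectra = 20, shared_fraction = 0.5, seed = 1)
#' cmp <- compare_datasets(pair$a, pair$b)
#' tidy(cmp)
#' @export
compare_datasets <- function(a, b,
                             params = similarity_params(),
                             window = comparison_window(),
                             histogram = TRUE,
                             hist_dmz_bin = 0.01,
                             hist_sim_bin = 0.01) {
  n_a <- nrow(a)
  n_b <- nrow(b)
  h <- if (histogram) {
    new_pair_histogram(window, hist_dmz_bin, hist_sim_bin)
  } else {
    NULL
  }

  matched_a <- logical(n_a)
  matched_b <- logical(n_b)
  n_evaluated <- 0L

  if (n_a > 0 && n_b > 0) {
    va <- lapply(a$peaks, bin_spectrum, params = params)
    vb <- lapply(b$peaks, bin_spectrum, params = params)

    ord_b <- order(b$precursor_mz)
    mz_b <- b$precursor_mz[ord_b]
    rt_b <- b$retention_time[ord_b]
    scan_b <- b$scan_number[ord_b]

    for (i in seq_len(n_a)) {
      mz_a <- a$precursor_mz[i]
      if (is.finite(window$max_precursor_dmz)) {
        lo <- findInterval(mz_a - window$max_precursor_dmz, mz_b,
                           left.open = TRUE) + 1L
        hi <- findInterval(mz_a + window$max_precursor_dmz, mz_b)
      } else {
        lo <- 1L
        hi <- n_b
      }
      if (lo > hi) next
      for (k in lo:hi) {
        j <- ord_b[k]
        if (!chrom_close(a$retention_time[i], rt_b[k],
                         a$scan_number[i], scan_b[k], window)) next
        s <- score_binned(va[[i]], vb[[j]], params)
        n_evaluated <- n_evaluated + 1L
        if (!is.null(h)) {
          cell <- hist_cell(h, mz_b[k] - mz_a, s)
          h[cell] <- h[cell] + 1L
        }
        if (s >= params$s_min) {
          matched_a[i] <- TRUE
          matched_b[j] <- TRUE
        }
      }
    }
  }

  m_a <- sum(matched_a)
  m_b <- sum(matched_b)
  S <- global_similarity(n_a, n_b, m_a, m_b)
  D <- if (is.na(S)) NA_real_ else global_distance(S, n_a, n_b)

  structure(
    list(
      label_a = dataset_label(a),
      label_b = dataset_label(b),
      n_a = n_a, n_b = n_b,
      matched_a = m_a, matched_b = m_b,
      S = S, D = D,
      n_evaluated = n_evaluated,
      params = params, window = window,
      histogram = h
    ),
    class = "ms2_comparison"
  )
}

#' Directional matched fraction
#'
#' The fraction of spectra in `a` with at least one similar spectrum in
#' `b`, i.e. one of the two terms averaged by the symmetric similarity.
#' Exposed for the directional (v1-style) comparison mode; note this is a
#' documented matched-fraction similarity, not the original published
#' asymmetric distance formula.
#'
#' @inheritParams compare_datasets
#' @return Fraction in `[0, 1]`, or `NA_real_` when `a` is empty.
#' @export
directional_similarity <- function(a, b,
                                   params = similarity_params(),
                                   window = comparison_window()) {
  cmp <- compare_datasets(a, b, params, window, histogram = FALSE)
  if (cmp$n_a == 0) return(NA_real_)
  cmp$matched_a / cmp$n_a
}

#' @export
print.ms2_comparison <- function(x, ...) {
  cat("<ms2_comparison> ", x$label_a, " vs ", x$label_b, "\n", sep = "")
  cat(sprintf("  |A| = %d (%d matched), |B| = %d (%d matched)\n",
              x$n_a, x$matched_a, x$n_b, x$matched_b))
  cat("  S =", format_undef(x$S), "  D =", format_undef(x$D), "\n")
  invisible(x)
}

format_undef <- function(x, digits = 6) {
  if (is.na(x)) "UNDEFINED" else formatC(x, format = "g", digits = digits)
}

#' @exportS3Method generics::tidy
tidy.ms2_comparison <- function(x, ...) {
  tibble::tibble(
    label_a = x$label_a, label_b = x$label_b,
    n_a = x$n_a, n_b = x$n_b,
    matched_a = x$matched_a, matched_b = x$matched_b,
    fraction_a = if (x$n_a > 0) x$matched_a / x$n_a else NA_real_,
    fraction_b = if (x$n_b > 0) x$matched_b / x$n_b else NA_real_,
    S = x$S, D = x$D
  )
}

#' @exportS3Method generics::glance
glance.ms2_comparison <- function(x, ...) {
  tibble::tibble(
    S = x$S, D = x$D,
    n_evaluated = x$n_evaluated,
    s_min = x$params$s_min,
    measure = x$params$measure,
    bin_width = x$params$bin_width,
    max_precursor_dmz = x$window$max_precursor_dmz
  )
}

#' Tidy the precursor-difference histogram of a comparison
#'
#' @param x An `ms2_comparison` with a populated histogram.
#' @return A tibble with columns `dmz` (bin centre, Th), `similarity`
#'   (bin centre) and `count`, one row per cell (zero cells included).
#' @export
histogram_tidy <- function(x) {
  h <- x$histogram
  if (is.null(h)) abort("comparison was run with histogram = FALSE.")
  tibble::tibble(
    dmz = rep(as.numeric(rownames(h)), times = ncol(h)),
    similarity = rep(as.numeric(colnames(h)), each = nrow(h)),
    count = as.integer(as.vector(h))
  )
}

#' Write the precursor-difference histogram as TSV
#'
#' Plain-text table (`dmz`, `similarity`, `count`) over the full grid,
#' suitable for external plotting; written even when all counts are zero.
#'
#' @param x An `ms2_comparison`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(x, path) {
  tab <- histogram_tidy(x)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a per-pair comparison result
#'
#' A small key–value block (labels, cardinalities, matched counts, S, D)
#' that the matrix-combining stage consumes. Undefined values are written
#' literally as `UNDEFINED`, never imputed.
#'
#' @param x An `ms2_comparison`.
#' @param path File path.
#' @return `write_pair_result()`: `path` invisibly. `read_pair_result()`:
#'   a one-row tibble in the shape of `tidy.ms2_comparison()`.
#' @export
write_pair_result <- function(x, path) {
  num <- function(v) if (is.na(v)) "UNDEFINED" else formatC(v, format = "g", digits = 12)
  writeLines(c(
    paste0("label_a\t", x$label_a),
    paste0("label_b\t", x$label_b),
    paste0("n_a\t", x$n_a),
    paste0("n_b\t", x$n_b),
    paste0("matched_a\t", x$matched_a),
    paste0("matched_b\t", x$matched_b),
    paste0("S\t", num(x$S)),
    paste0("D\t", num(x$D))
  ), path)
  invisible(path)
}

#' @rdname write_pair_result
#' @export
read_pair_result <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("key", "value"),
                          colClasses = "character")
  get <- function(k) kv$value[match(k, kv$key)]
  num <- function(k) {
    v <- get(k)
    if (identical(v, "UNDEFINED")) NA_real_ else as.numeric(v)
  }
  n_a <- as.integer(get("n_a"))
  n_b <- as.integer(get("n_b"))
  m_a <- as.integer(get("matched_a"))
  m_b <- as.integer(get("matched_b"))
  tibble::tibble(
    label_a = get("label_a"), label_b = get("label_b"),
    n_a = n_a, n_b = n_b, matched_a = m_a, matched_b = m_b,
    fraction_a = if (n_a > 0) m_a / n_a else NA_real_,
    fraction_b = if (n_b > 0) m_b / n_b else NA_real_,
    S = num("S"), D = num("D")
  )
}

#' Plot the precursor-difference by similarity histogram
#'
#' Heatmap of evaluated spectrum pairs over signed precursor m/z
#' difference and similarity. Isotope-selection errors appear as vertical
#' bands at rational m/z offsets (1/z Da multiples).
#'
#' @param object An `ms2_comparison`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ms2_comparison <- function(object, ...) {
  tab <- histogram_tidy(object) |>
    dplyr::filter(.data$count > 0)
  ggplot2::ggplot(tab, ggplot2::aes(.data$dmz, .data$similarity,
                                    fill = log10(.data$count))) +
    ggplot2::geom_tile(width = attr(object$histogram, "dmz_bin"),
                       height = attr(object$histogram, "sim_bin")) +
    ggplot2::scale_fill_viridis_c(name = "log10 count") +
    ggplot2::labs(
      x = "precursor m/z difference (Th)",
      y = "spectral similarity",
      title = paste(object$label_a, "vs", object$label_b)
    ) +
    ggplot2::theme_minimal()
}
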