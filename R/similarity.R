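#' Turn a peak list into a binned unit vector
#'
#' The vector representation behind the similarity scores. Peaks below the
#' noise floor are removed first; surviving intensities are raised to the
#' scaling exponent; each peak is assigned to bin `floor(mz / bin_width)`
#' (no splitting across neighbouring bins) and weights within a bin are
#' summed; finally the vector is scaled to unit Euclidean length. A
#' spectrum whose peaks all fall below the noise floor yields the zero
#' vector, which scores 0 against anything.
#'
#' @param peaks Two-column numeric matrix (`mz`, `intensity`), or a
#'   single-row slice of an [ms2_dataset] `peaks` column.
#' @param params [similarity_params()].
#' @return A list of class `ms2_binned` with integer `bins` (sorted),
#'   numeric unit-norm `weights`, the pre-normalisation Euclidean `norm`
#'   and the `bin_width` used.
#' @examples
#' v <- bin_spectrum(cbind(mz = c(100, 200), intensity = c(9, 16)),
#'                   similarity_params(noise_floor = 0))
#' v$weights  # 0.6, 0.8
#' @export
bin_spectrum <- function(peaks, params = similarity_params()) {
  peaks <- as.matrix(peaks)
  mz <- peaks[, 1]
  intensity <- peaks[, 2]

  floor_abs <- params$noise_floor
  if (is.na(floor_abs)) {
    # automatic mode: relative floor as a fraction (per mille) of the base peak
    bp <- if (length(intensity)) max(intensity) else 0
    floor_abs <- params$noise_floor_relative * 1e-3 * bp
  }
  keep <- intensity >= floor_abs & intensity > 0
  mz <- mz[keep]
  intensity <- intensity[keep]

  if (!length(mz)) {
    return(structure(
      list(bins = integer(0), weights = numeric(0), norm = 0,
           bin_width = params$bin_width),
      class = "ms2_binned"
    ))
  }
  w <- intensity^params$scaling_exponent
  idx <- as.integer(floor(mz / params$bin_width))
  agg <- rowsum(w, group = idx)
  bins <- as.integer(rownames(agg))
  weights <- as.numeric(agg)
  o <- order(bins)
  bins <- bins[o]
  weights <- weights[o]
  nrm <- sqrt(sum(weights^2))
  structure(
    list(bins = bins, weights = weights / nrm, norm = nrm,
         bin_width = params$bin_width),
    class = "ms2_binned"
  )
}

dot_binned <- function(u, v) {
  if (!length(u$bins) || !length(v$bins)) return(0)
  i <- match(u$bins, v$bins)
  ok <- !is.na(i)
  if (!any(ok)) return(0)
  sum(u$weights[ok] * v$weights[i[ok]])
}

check_same_binning <- function(u, v) {
  if (!isTRUE(all.equal(u$bin_width, v$bin_width))) {
    abort("cannot compare vectors binned at different bin widths.")
  }
}

#' Cosine score between binned spectra
#'
#' The cosine of the angle between the two unit-length vector
#' representations, i.e. their dot product. Ranges over `[0, 1]` because
#' intensities are non-negative; returns 0 if either vector is zero.
#' Co-directional spectra (intensities differing only by a factor) score 1.
#'
#' @param u,v `ms2_binned` vectors from [bin_spectrum()] with equal bin
#'   width.
#' @return Similarity in `[0, 1]`.
#' @export
cosine_score <- function(u, v) {
  check_same_binning(u, v)
  min(1, max(0, dot_binned(u, v)))
}

#' Spectral angle score between binned spectra
#'
#' The angle between the vector representations, rescaled to `[0, 1]` as
#' `1 - 2 * acos(cos) / pi` so that identical spectra score 1 and
#' orthogonal spectra 0. A strictly monotone function of the cosine score.
#'
#' @inheritParams cosine_score
#' @return Similarity in `[0, 1]`.
#' @export
spectral_angle_score <- function(u, v) {
  check_same_binning(u, v)
  d <- min(1, max(0, dot_binned(u, v)))
  1 - 2 * acos(d) / pi
}

score_binned <- function(u, v, params) {
  if (params$measure == "cosine") cosine_score(u, v)
  else spectral_angle_score(u, v)
}

#' Similarity between two raw spectra
#'
#' Convenience wrapper: preprocesses both peak lists with the same
#' parameters and scores them with the configured measure.
#'
#' @param peaks_a,peaks_b Two-column numeric peak matrices (`mz`,
#'   `intensity`).
#' @param params [similarity_params()].
#' @return Similarity in `[0, 1]`.
#' @examples
#' a <- cbind(mz = c(100, 200), intensity = c(1, 1))
#' b <- cbind(mz = 100, intensity = 1)
#' spectrum_similarity(a, b, similarity_params(scaling_exponent = 1,
#'                                             noise_floor = 0))
#' @export
spectrum_similarity <- function(peaks_a, peaks_b,
                                params = similarity_params()) {
  score_binned(bin_spectrum(peaks_a, params),
               bin_spectrum(peaks_b, params),
               params)
}
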