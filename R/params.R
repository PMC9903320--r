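#' Spectral similarity parameters
#'
#' Bundles the knobs that control how two spectra are turned into vectors
#' and scored against each other. Defaults follow the tool's standard
#' parameter set: cosine score, square-root intensity scaling, an absolute
#' noise floor of 10 (arbitrary intensity units) and a similarity threshold
#' `s_min = 0.8`.
#'
#' @param measure Similarity measure, `"cosine"` (dot product of
#'   unit-normalised binned spectra) or `"spectral_angle"` (the angle
#'   rescaled so identical spectra score 1 and orthogonal spectra 0).
#' @param scaling_exponent Exponent applied to peak intensities before
#'   binning, in `(0, 1]`. `0.5` takes square roots (the default), `1/3`
#'   cube roots, `1` leaves intensities untouched.
#' @param noise_floor Absolute intensity threshold; peaks strictly below it
#'   are dropped before binning. Use `0` to keep everything. If `NA`, a
#'   relative floor of `noise * 1e-3` of the base peak is applied instead
#'   (the automatic mode; `noise` is then read from `noise_floor_relative`).
#' @param noise_floor_relative Relative floor used when `noise_floor` is
#'   `NA`: peaks below `noise_floor_relative * 1e-3 * base_peak` are dropped.
#' @param bin_width Fragment m/z bin width in Thomson; peaks are assigned to
#'   bin `floor(mz / bin_width)`.
#' @param s_min Minimum similarity for two spectra to count as "similar"
#'   in set comparison, in `[0, 1]`.
#'
#' @return A list of class `ms2_params`.
#' @examples
#' similarity_params(scaling_exponent = 1, noise_floor = 0)
#' @export
similarity_params <- function(measure = c("cosine", "spectral_angle"),
                              scaling_exponent = 0.5,
                              noise_floor = 10,
                              noise_floor_relative = 10,
                              bin_width = 0.2,
                              s_min = 0.8) {
  measure <- match.arg(measure)
  stopifnot(
    is.numeric(scaling_exponent), length(scaling_exponent) == 1L,
    scaling_exponent > 0, scaling_exponent <= 1,
    is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0,
    is.numeric(s_min), length(s_min) == 1L, s_min >= 0, s_min <= 1
  )
  if (!is.na(noise_floor) && noise_floor < 0) {
    abort("`noise_floor` must be >= 0 (or NA for automatic relative mode).")
  }
  structure(
    list(
      measure = measure,
      scaling_exponent = scaling_exponent,
      noise_floor = noise_floor,
      noise_floor_relative = noise_floor_relative,
      bin_width = bin_width,
      s_min = s_min
    ),
    class = "ms2_params"
  )
}

#' Candidate-search window for set comparison
#'
#' Two spectra are only scored against each other when their precursor m/z
#' values differ by at most `max_precursor_dmz` and they are close in
#' chromatographic coordinates: retention time difference at most
#' `max_rt_diff` seconds when both spectra carry a retention time, otherwise
#' scan-number difference at most `max_scan_diff`. Spectra with neither
#' coordinate are unconstrained chromatographically. `Inf` disables a bound.
#'
#' Defaults are the tool's standard window: 2.05 Th precursor difference
#' (covering isotope-selection errors up to two neutrons at charge 1),
#' 60 s retention time, 10000 scans.
#'
#' @param max_precursor_dmz Maximum absolute precursor m/z difference (Th).
#' @param max_rt_diff Maximum absolute retention time difference (seconds).
#' @param max_scan_diff Maximum absolute scan number difference.
#' @return A list of class `ms2_window`.
#' @examples
#' comparison_window(max_precursor_dmz = Inf, max_rt_diff = Inf,
#'                   max_scan_diff = Inf)
#' @export
comparison_window <- function(max_precursor_dmz = 2.05,
                              max_rt_diff = 60,
                              max_scan_diff = 10000) {
  stopifnot(
    max_precursor_dmz >= 0,
    max_rt_diff >= 0,
    max_scan_diff >= 0
  )
  structure(
    list(
      max_precursor_dmz = max_precursor_dmz,
      max_rt_diff = max_rt_diff,
      max_scan_diff = max_scan_diff
    ),
    class = "ms2_window"
  )
}

#' @export
print.ms2_params <- function(x, ...) {
  cat("<ms2_params>\n")
  cat("  measure:         ", x$measure, "\n", sep = "")
  cat("  scaling exponent:", x$scaling_exponent, "\n")
  cat("  noise floor:     ",
      if (is.na(x$noise_floor)) {
        paste0("auto (", x$noise_floor_relative, " × 1e-3 of base peak)")
      } else {
        x$noise_floor
      }, "\n")
  cat("  bin width (Th):  ", x$bin_width, "\n")
  cat("  s_min:           ", x$s_min, "\n")
  invisible(x)
}

#' @export
print.ms2_window <- function(x, ...) {
  cat("<ms2_window> precursor dm/z <=", x$max_precursor_dmz,
      "Th; RT diff <=", x$max_rt_diff,
      "s; scan diff <=", x$max_scan_diff, "\n")
  invisible(x)
}
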