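#' Filter spectra on intensity and chromatographic coordinates
#'
#' Retains exactly the spectra with base-peak intensity at least
#' `min_basepeak`, total ion current at least `min_tic`, retention time
#' inside the closed interval `rt_range` and scan number inside the closed
#' interval `scan_range`. All comparisons are inclusive. Spectra with
#' unknown retention time or scan number pass the corresponding range
#' filter. Order is preserved and the filter is idempotent.
#'
#' Defaults are the standard parameter set: minimum base peak 10000,
#' minimum TIC 0, retention time 0–100000 s, scans 1–1000000.
#'
#' @param ds An [ms2_dataset].
#' @param min_basepeak Minimum base-peak intensity.
#' @param min_tic Minimum total ion current.
#' @param rt_range Closed retention-time interval `c(start, end)` (seconds).
#' @param scan_range Closed scan-number interval `c(start, end)`.
#' @return A filtered [ms2_dataset].
#' @examples
#' ds <- synthetic_dataset(n_spectra = 5, seed = 1)
#' filter_spectra(ds, min_basepeak = 0)
#' @export
filter_spectra <- function(ds,
                           min_basepeak = 10000,
                           min_tic = 0,
                           rt_range = c(0, 100000),
                           scan_range = c(1, 1000000)) {
  stopifnot(length(rt_range) == 2L, length(scan_range) == 2L)
  if (rt_range[1] > rt_range[2] || scan_range[1] > scan_range[2]) {
    abort("filter ranges must satisfy start <= end.")
  }
  keep <- ds$base_peak >= min_basepeak &
    ds$tic >= min_tic &
    (is.na(ds$retention_time) |
       (ds$retention_time >= rt_range[1] & ds$retention_time <= rt_range[2])) &
    (is.na(ds$scan_number) |
       (ds$scan_number >= scan_range[1] & ds$scan_number <= scan_range[2]))
  ms2_dataset(tibble::as_tibble(ds)[keep, , drop = FALSE],
              label = dataset_label(ds))
}

#' Keep only the top-N most intense spectra
#'
#' Ranks spectra by total ion current (ties broken by original file order)
#' and keeps the `n` largest, re-sorted back to original order. `n = Inf`
#' (or `"all"`) is a no-op; `n` larger than the dataset is clamped with a
#' note.
#'
#' @param ds An [ms2_dataset].
#' @param n Number of spectra to keep (positive), or `Inf`/`"all"`.
#' @return An [ms2_dataset] with `min(n, nrow(ds))` spectra.
#' @export
select_top_n <- function(ds, n = Inf) {
  if (is.character(n)) {
    if (!tolower(n) %in% "all") abort("`n` must be a positive number or \"all\".")
    n <- Inf
  }
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (is.infinite(n) || n >= nrow(ds)) {
    if (is.finite(n) && n > nrow(ds)) {
      inform(sprintf("select_top_n: n = %d exceeds dataset size %d; keeping all.",
                     as.integer(n), nrow(ds)))
    }
    return(ds)
  }
  ord <- order(-ds$tic, seq_len(nrow(ds)))
  keep <- sort(ord[seq_len(n)])
  ms2_dataset(tibble::as_tibble(ds)[keep, , drop = FALSE],
              label = dataset_label(ds))
}
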