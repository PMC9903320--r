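#' Construct an MS/MS dataset from a spectrum table
#'
#' An `ms2_dataset` is a tibble with one row per tandem mass spectrum and a
#' `peaks` list-column, plus a dataset label (normally the MGF file stem).
#' Columns `base_peak` (largest peak intensity) and `tic` (total ion
#' current, the intensity sum) are derived from the peak lists.
#'
#' @param spectra A data frame with columns `title` (character),
#'   `precursor_mz` (numeric, > 0), `charge` (integer or NA),
#'   `retention_time` (seconds, NA allowed), `scan_number` (integer or NA)
#'   and `peaks` (list of two-column numeric matrices `mz`, `intensity`,
#'   sorted by ascending m/z).
#' @param label Dataset label.
#' @return A tibble of class `ms2_dataset`.
#' @export
ms2_dataset <- function(spectra, label = "dataset") {
  spectra <- tibble::as_tibble(spectra)
  needed <- c("title", "precursor_mz", "charge", "retention_time",
              "scan_number", "peaks")
  missing_cols <- setdiff(needed, names(spectra))
  if (length(missing_cols)) {
    abort(paste0("spectrum table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(spectra) > 0 && any(spectra$precursor_mz <= 0, na.rm = TRUE)) {
    abort("precursor m/z must be positive.")
  }
  spectra$peaks <- lapply(spectra$peaks, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("mz", "intensity")
    storage.mode(p) <- "double"
    if (nrow(p) > 0) {
      if (any(p[, "mz"] <= 0) || any(p[, "intensity"] < 0)) {
        abort("peaks must have mz > 0 and intensity >= 0.")
      }
      p <- p[order(p[, "mz"]), , drop = FALSE]
    }
    p
  })
  spectra$base_peak <- vapply(
    spectra$peaks,
    function(p) if (nrow(p)) max(p[, "intensity"]) else 0,
    numeric(1)
  )
  spectra$tic <- vapply(
    spectra$peaks,
    function(p) if (nrow(p)) sum(p[, "intensity"]) else 0,
    numeric(1)
  )
  structure(
    spectra,
    label = label,
    class = c("ms2_dataset", class(tibble::tibble()))
  )
}

#' @export
print.ms2_dataset <- function(x, ...) {
  cat("<ms2_dataset> ", dataset_label(x), ": ", nrow(x),
      " spectra\n", sep = "")
  NextMethod()
}

#' Dataset label and QC metrics
#'
#' `dataset_label()` returns the label carried by an `ms2_dataset`;
#' `qc_metrics()` returns its per-dataset quality-control metrics as a named
#' numeric vector. The default (and currently only built-in) metric is
#' `spectrum_count`, the number of spectra retained after filtering.
#'
#' @param ds An `ms2_dataset`.
#' @return `dataset_label()`: a string. `qc_metrics()`: named numeric.
#' @export
dataset_label <- function(ds) {
  attr(ds, "label") %||% "dataset"
}

#' @rdname dataset_label
#' @export
qc_metrics <- function(ds) {
  c(spectrum_count = nrow(ds))
}

mgf_parse_error <- function(path, line, what) {
  abort(sprintf("MGF parse error in '%s', line %d: %s", path, line, what),
        class = "ms2dist_parse_error")
}

parse_charge <- function(token) {
  token <- trimws(token)
  # accept "2+", "+2", "2", "2-", "-2"; only the magnitude is kept
  m <- regmatches(token, regexpr("[0-9]+", token))
  if (length(m) == 0L) return(NA_integer_)
  as.integer(m)
}

#' Read a Mascot Generic Format (MGF) peak-list file
#'
#' Parses one spectrum per `BEGIN IONS`/`END IONS` block. Recognised header
#' keys are `TITLE`, `PEPMASS` (first token is the precursor m/z; an
#' optional second intensity token is ignored), `CHARGE` (`2+`, `+2` and
#' `2` all parse to 2), `RTINSECONDS` and `SCANS`; unrecognised keys are
#' skipped with a note. Peak lines are `mz intensity` pairs. Both Unix and
#' Windows line endings are accepted. Spectra keep file order.
#'
#' @param path Path to an MGF file.
#' @param label Dataset label; defaults to the file stem.
#' @return An [ms2_dataset].
#' @examples
#' f <- tempfile(fileext = ".mgf")
#' writeLines(c("BEGIN IONS", "TITLE=demo", "PEPMASS=622.8",
#'              "CHARGE=2+", "100.0 42.0", "END IONS"), f)
#' read_mgf(f)
#' @export
read_mgf <- function(path, label = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read MGF file '%s': no such file", path),
          class = "ms2dist_io_error")
  }
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)

  in_block <- FALSE
  block_start <- 0L
  cur <- NULL
  rows <- list()
  unknown_keys <- character()

  flush_spectrum <- function(cur) {
    pk <- if (length(cur$mz)) {
      cbind(mz = cur$mz, intensity = cur$intensity)
    } else {
      cbind(mz = numeric(0), intensity = numeric(0))
    }
    list(
      title = cur$title %||% NA_character_,
      precursor_mz = cur$precursor_mz %||% NA_real_,
      charge = cur$charge %||% NA_integer_,
      retention_time = cur$retention_time %||% NA_real_,
      scan_number = cur$scan_number %||% NA_integer_,
      peaks = list(pk)
    )
  }

  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    if (!in_block) {
      if (toupper(ln) == "BEGIN IONS") {
        in_block <- TRUE
        block_start <- i
        cur <- list(mz = numeric(0), intensity = numeric(0))
      }
      # anything between blocks (global headers etc.) is ignored
      next
    }
    if (toupper(ln) == "END IONS") {
      if (is.na(cur$precursor_mz %||% NA_real_)) {
        mgf_parse_error(path, block_start, "spectrum block has no PEPMASS")
      }
      rows[[length(rows) + 1L]] <- flush_spectrum(cur)
      in_block <- FALSE
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0) {
      key <- toupper(substr(ln, 1L, eq - 1L))
      val <- substr(ln, eq + 1L, nchar(ln))
      if (key == "TITLE") {
        cur$title <- val
      } else if (key == "PEPMASS") {
        tok <- strsplit(trimws(val), "[ \t]+")[[1]][1]
        mz <- suppressWarnings(as.numeric(tok))
        if (is.na(mz) || mz <= 0) {
          mgf_parse_error(path, i, sprintf("invalid PEPMASS '%s'", val))
        }
        cur$precursor_mz <- mz
      } else if (key == "CHARGE") {
        cur$charge <- parse_charge(val)
      } else if (key == "RTINSECONDS") {
        cur$retention_time <- suppressWarnings(as.numeric(val))
      } else if (key == "SCANS") {
        cur$scan_number <- suppressWarnings(as.integer(
          strsplit(trimws(val), "[-,]")[[1]][1]
        ))
      } else {
        unknown_keys <- c(unknown_keys, key)
      }
      next
    }
    # peak line: "mz intensity" (extra columns tolerated and ignored)
    tok <- strsplit(ln, "[ \t]+")[[1]]
    mzi <- suppressWarnings(as.numeric(tok[1:2]))
    if (length(tok) < 2L || anyNA(mzi)) {
      mgf_parse_error(path, i, sprintf("expected 'mz intensity', got '%s'", ln))
    }
    cur$mz <- c(cur$mz, mzi[1])
    cur$intensity <- c(cur$intensity, mzi[2])
  }
  if (in_block) {
    mgf_parse_error(path, block_start,
                    "BEGIN IONS block never closed by END IONS")
  }
  if (length(unknown_keys)) {
    inform(sprintf("read_mgf('%s'): ignored unknown header key(s): %s",
                   basename(path),
                   paste(unique(unknown_keys), collapse = ", ")))
  }

  spectra <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  if (nrow(spectra) == 0L) {
    spectra <- tibble::tibble(
      title = character(), precursor_mz = numeric(),
      charge = integer(), retention_time = numeric(),
      scan_number = integer(), peaks = list()
    )
  }
  ms2_dataset(spectra, label = label)
}

fmt_num <- function(x) {
  # shortest representation that survives a read-back to printed precision
  formatC(x, format = "g", digits = 12, width = 1)
}

#' Write an MS/MS dataset as MGF
#'
#' Serialises a dataset back to Mascot Generic Format. Reading the written
#' file with [read_mgf()] reproduces precursor m/z, charge, retention time,
#' scan number and peak lists to printed precision.
#'
#' @param ds An [ms2_dataset].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(ds, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(ds))) {
    out <- c("BEGIN IONS")
    if (!is.na(ds$title[i])) out <- c(out, paste0("TITLE=", ds$title[i]))
    out <- c(out, paste0("PEPMASS=", fmt_num(ds$precursor_mz[i])))
    if (!is.na(ds$charge[i])) {
      out <- c(out, paste0("CHARGE=", ds$charge[i], "+"))
    }
    if (!is.na(ds$retention_time[i])) {
      out <- c(out, paste0("RTINSECONDS=", fmt_num(ds$retention_time[i])))
    }
    if (!is.na(ds$scan_number[i])) {
      out <- c(out, paste0("SCANS=", ds$scan_number[i]))
    }
    p <- ds$peaks[[i]]
    if (nrow(p)) {
      out <- c(out, paste(fmt_num(p[, "mz"]), fmt_num(p[, "intensity"])))
    }
    out <- c(out, "END IONS", "")
    writeLines(out, con)
  }
  invisible(path)
}
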