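#' Write a distance matrix in MEGA format
#'
#' Minimal lower-left MEGA (.meg) dialect as accepted by MEGA11's
#' "Pairwise Distance" import: a `#mega` header, `!Title` and `!Format`
#' lines, one `#label` line per taxon, then the strictly lower-left
#' triangular matrix. Undefined entries are written with the missing-data
#' symbol `?`, which is declared in the `!Format` line.
#'
#' @param m An [ms2_distmat].
#' @param path Output file path.
#' @param title Title recorded in the `!Title` line.
#' @param triangle `"lower"` (default) or `"upper"`; the upper variant
#'   writes the strictly upper-right triangle row by row.
#' @param digits Significant digits for distances.
#' @return `path`, invisibly.
#' @export
write_mega <- function(m, path, title = "ms2dist distance matrix",
                       triangle = c("lower", "upper"), digits = 6) {
  triangle <- match.arg(triangle)
  n <- length(m$labels)
  fmt <- function(v) {
    ifelse(is.na(v), "?", formatC(v, format = "g", digits = digits))
  }
  lines <- c(
    "#mega",
    paste0("!Title ", title, ";"),
    paste0("!Format DataType=Distance DataFormat=",
           if (triangle == "lower") "LowerLeft" else "UpperRight",
           " NTaxa=", n, " MissingSymbol=?;"),
    "",
    paste0("#", m$labels),
    ""
  )
  if (triangle == "lower") {
    for (i in seq_len(n)[-1]) {
      lines <- c(lines, paste(fmt(m$values[i, seq_len(i - 1)]),
                              collapse = "\t"))
    }
  } else {
    for (i in seq_len(n - 1)) {
      lines <- c(lines, paste(fmt(m$values[i, seq(i + 1, n)]),
                              collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a MEGA distance matrix written by this package
#'
#' Parses the minimal lower-left (or upper-right) MEGA dialect produced by
#' [write_mega()]. `?` entries become `NA`.
#'
#' @param path Path to a .meg file.
#' @return An [ms2_distmat].
#' @export
read_mega <- function(path) {
  lines <- trimws(sub("\r$", "", readLines(path, warn = FALSE)))
  if (!length(lines) || tolower(lines[1]) != "#mega") {
    abort(sprintf("'%s' does not look like a MEGA file (no #mega header).",
                  path), class = "ms2dist_parse_error")
  }
  fmt_line <- grep("^!Format", lines, value = TRUE)
  upper <- length(fmt_line) && grepl("UpperRight", fmt_line[1])
  body <- lines[-1]
  body <- body[!startsWith(body, "!") & body != ""]
  labels <- sub("^#", "", body[startsWith(body, "#")])
  rows <- body[!startsWith(body, "#")]
  n <- length(labels)
  if (length(rows) != n - 1) {
    abort(sprintf("expected %d matrix rows for %d taxa, found %d.",
                  n - 1, n, length(rows)), class = "ms2dist_parse_error")
  }
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(m) <- 0
  parse_vals <- function(s) {
    v <- strsplit(s, "[ \t]+")[[1]]
    ifelse(v == "?", NA_real_, suppressWarnings(as.numeric(v)))
  }
  for (r in seq_along(rows)) {
    v <- parse_vals(rows[r])
    if (upper) {
      i <- r
      j <- seq(i + 1, n)
    } else {
      i <- r + 1
      j <- seq_len(i - 1)
    }
    if (length(v) != length(j)) {
      abort(sprintf("matrix row %d has %d values, expected %d.",
                    r, length(v), length(j)), class = "ms2dist_parse_error")
    }
    m[i, j] <- v
    m[j, i] <- v
  }
  ms2_distmat(m, labels = labels)
}

#' Write trees in Newick or NEXUS format
#'
#' Thin wrappers around \pkg{ape}'s writers: `write_newick()` writes a
#' standard parenthesised tree with branch lengths, `write_nexus()` a
#' NEXUS file with TAXA and TREES blocks.
#'
#' @param tree An \pkg{ape} `phylo` tree (e.g. from [upgma()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
write_nexus <- function(tree, path) {
  ape::write.nexus(tree, file = path)
  invisible(path)
}
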