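#' Construct a labelled symmetric distance matrix
#'
#' Container for set-level distances between samples or species. The
#' diagonal is 0 by convention; `NA` entries mark undefined distances
#' (comparisons involving empty datasets) and are preserved, never
#' imputed.
#'
#' @param values Square numeric matrix; made symmetric from its lower
#'   triangle if dimnames agree.
#' @param labels Taxon labels; defaults to `rownames(values)`.
#' @param qc Optional named numeric vector of per-label QC values
#'   (default metric: number of tandem mass spectra).
#' @return An object of class `ms2_distmat`.
#' @examples
#' m <- ms2_distmat(matrix(c(0, 4, 4, 0), 2,
#'                  dimnames = list(c("A", "B"), c("A", "B"))))
#' tidy(m)
#' @export
ms2_distmat <- function(values, labels = NULL, qc = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("distance matrix must be square.")
  labels <- labels %||% rownames(values)
  if (is.null(labels)) {
    abort("labels are required (either explicitly or as dimnames).")
  }
  if (anyDuplicated(labels)) abort("labels must be unique.")
  dimnames(values) <- list(labels, labels)
  off <- values[lower.tri(values)]
  upper <- t(values)[lower.tri(values)]
  both <- !is.na(off) & !is.na(upper)
  if (any(abs(off[both] - upper[both]) > 1e-9)) {
    abort("distance matrix is not symmetric.")
  }
  # symmetrise (fill NA on one side from the other) and zero the diagonal
  values[upper.tri(values)] <- t(values)[upper.tri(values)]
  diag(values) <- 0
  if (!is.null(qc)) {
    miss <- setdiff(labels, names(qc))
    if (length(miss)) {
      abort(paste0("qc values missing for: ", paste(miss, collapse = ", ")))
    }
    qc <- qc[labels]
  }
  structure(list(labels = labels, values = values, qc = qc),
            class = "ms2_distmat")
}

#' @export
print.ms2_distmat <- function(x, ...) {
  cat("<ms2_distmat> ", length(x$labels), " taxa\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' @export
as.matrix.ms2_distmat <- function(x, ...) x$values

#' @export
as.dist.ms2_distmat <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' @exportS3Method generics::tidy
tidy.ms2_distmat <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(lower.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    item1 = x$labels[idx[, 2]],
    item2 = x$labels[idx[, 1]],
    distance = x$values[idx[, c(2, 1), drop = FALSE]]
  )
}

#' Combine pairwise comparisons into a species-level distance matrix
#'
#' Takes per-pair results (a tibble as produced by `tidy()` on
#' `ms2_comparison` objects, or a list of such objects) together with a
#' sample-to-species mapping, and averages all defined sample-pair
#' distances between each pair of species. Intra-species distances are
#' excluded and the diagonal forced to 0. Undefined (NA) sample pairs are
#' dropped from the mean with a note; a species pair with no defined
#' comparison at all yields an `NA` entry and a warning. The per-species
#' QC value is the summed spectrum count of its member samples.
#'
#' @param results Tibble with columns `label_a`, `label_b`, `n_a`, `n_b`,
#'   `D` (other columns ignored), or a list of `ms2_comparison` objects.
#' @param mapping Optional data frame with columns `sample`, `species`;
#'   defaults to each sample being its own species.
#' @param stat Aggregation statistic across replicate sample pairs:
#'   arithmetic `"mean"` (default) or `"min"`.
#' @return An [ms2_distmat] over species.
#' @examples
#' res <- tibble::tibble(label_a = "s1", label_b = "s2",
#'                       n_a = 10, n_b = 10, D = 0.5)
#' aggregate_by_species(res)
#' @export
aggregate_by_species <- function(results, mapping = NULL,
                                 stat = c("mean", "min")) {
  stat <- match.arg(stat)
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(lapply(results, tidy))
  }
  results <- tibble::as_tibble(results)
  samples <- unique(c(results$label_a, results$label_b))
  if (is.null(mapping)) {
    mapping <- tibble::tibble(sample = samples, species = samples)
  }
  mapping <- tibble::as_tibble(mapping)
  unmapped <- setdiff(samples, mapping$sample)
  if (length(unmapped)) {
    abort(paste0("samples not present in mapping: ",
                 paste(unmapped, collapse = ", ")))
  }
  species <- unique(mapping$species)

  # per-sample spectrum counts, summed to species QC
  counts <- dplyr::bind_rows(
    dplyr::select(results, sample = "label_a", n = "n_a"),
    dplyr::select(results, sample = "label_b", n = "n_b")
  ) |>
    dplyr::distinct(.data$sample, .keep_all = TRUE) |>
    dplyr::left_join(mapping, by = "sample") |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n = sum(.data$n))
  qc <- setNames(rep(0, length(species)), species)
  qc[counts$species] <- counts$n

  sp_of <- setNames(mapping$species, mapping$sample)
  inter <- results |>
    dplyr::mutate(
      sp_a = unname(sp_of[.data$label_a]),
      sp_b = unname(sp_of[.data$label_b])
    ) |>
    dplyr::filter(.data$sp_a != .data$sp_b)

  n_sp <- length(species)
  m <- matrix(NA_real_, n_sp, n_sp, dimnames = list(species, species))
  diag(m) <- 0
  agg_fun <- if (stat == "mean") mean else min
  n_dropped <- 0L
  for (i in seq_len(n_sp - 1)) {
    for (j in seq(i + 1, n_sp)) {
      d <- inter$D[(inter$sp_a == species[i] & inter$sp_b == species[j]) |
                     (inter$sp_a == species[j] & inter$sp_b == species[i])]
      if (!length(d)) next
      defined <- d[!is.na(d)]
      n_dropped <- n_dropped + sum(is.na(d))
      if (length(defined)) {
        m[i, j] <- m[j, i] <- agg_fun(defined)
      } else {
        warn(sprintf(
          "species pair %s-%s has no defined comparison; entry left UNDEFINED.",
          species[i], species[j]
        ))
      }
    }
  }
  if (n_dropped > 0) {
    inform(sprintf(
      "aggregate_by_species: %d undefined sample-pair distance(s) excluded.",
      n_dropped
    ))
  }
  ms2_distmat(m, labels = species, qc = qc)
}

#' Heatmap of a distance matrix
#'
#' @param object An `ms2_distmat`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ms2_distmat <- function(object, ...) {
  long <- tidy(object)
  long <- dplyr::bind_rows(
    long,
    dplyr::rename(long, item1 = "item2", item2 = "item1"),
    tibble::tibble(item1 = object$labels, item2 = object$labels,
                   distance = 0)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$item1, .data$item2,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "D", na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
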