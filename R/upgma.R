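#' UPGMA tree from a distance matrix
#'
#' Unweighted pair-group average-linkage agglomeration: the closest pair
#' of clusters is merged repeatedly, the merged node placed at height
#' `d/2`, and the distance from the merged cluster to every other cluster
#' taken as the size-weighted average of its members' distances (true
#' UPGMA, not WPGMA). Ties are broken deterministically by the
#' lexicographically smallest pair of cluster representative labels (the
#' smallest leaf label in each cluster). The result is a rooted
#' ultrametric tree: every root-to-leaf path has the same length.
#'
#' @param m An [ms2_distmat] or a symmetric numeric matrix with dimnames;
#'   no undefined (`NA`) entries — exclude or impute those first.
#' @return An \pkg{ape} `phylo` tree with branch lengths.
#' @examples
#' m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma(m))  # ((A:1,B:1):3,C:4);
#' @export
upgma <- function(m) {
  if (inherits(m, "ms2_distmat")) {
    vals <- m$values
    labels <- m$labels
  } else {
    vals <- as.matrix(m)
    labels <- rownames(vals)
  }
  n <- nrow(vals)
  if (n < 2) abort("UPGMA needs at least 2 taxa.")
  if (anyNA(vals)) {
    abort(paste0(
      "distance matrix contains UNDEFINED entries; exclude those taxa or ",
      "impute the values before tree building."
    ))
  }

  node <- labels            # newick fragment per live cluster
  height <- rep(0, n)       # cluster height (distance to its leaves)
  size <- rep(1L, n)        # number of leaves
  rep_label <- labels       # smallest leaf label, for tie-breaking
  d <- vals
  alive <- rep(TRUE, n)
  fmt <- function(x) formatC(x, format = "g", digits = 15, width = 1)

  for (step in seq_len(n - 1)) {
    idx <- which(alive)
    best <- NULL
    best_d <- Inf
    best_key <- NULL
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq(a + 1, length(idx))) {
        i <- idx[a]
        j <- idx[b]
        dij <- d[i, j]
        key <- sort(c(rep_label[i], rep_label[j]))
        better <- dij < best_d ||
          (dij == best_d &&
             (key[1] < best_key[1] ||
                (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) {
          best <- c(i, j)
          best_d <- dij
          best_key <- key
        }
      }
    }
    i <- best[1]
    j <- best[2]
    # order children by representative label for a deterministic layout
    if (rep_label[j] < rep_label[i]) {
      tmp <- i; i <- j; j <- tmp
    }
    h <- best_d / 2
    merged <- paste0(
      "(", node[i], ":", fmt(h - height[i]),
      ",", node[j], ":", fmt(h - height[j]), ")"
    )
    for (k in which(alive)) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j])
    }
    node[i] <- merged
    height[i] <- h
    size[i] <- size[i] + size[j]
    rep_label[i] <- min(rep_label[i], rep_label[j])
    alive[j] <- FALSE
  }
  ape::read.tree(text = paste0(node[which(alive)], ";"))
}

#' Annotate tree leaves with a quality-control metric
#'
#' Attaches a per-leaf QC value (default metric: number of tandem mass
#' spectra) and its min–max normalised position on a `[0, 1]` colour
#' scale. When all leaves share the same value the position is 0.5 for
#' every leaf.
#'
#' @param tree An \pkg{ape} `phylo` tree.
#' @param qc Named numeric vector covering every leaf label.
#' @return An object of class `ms2_qc_tree`: list with the `tree` and an
#'   `annotations` tibble (`label`, `qc`, `position`).
#' @export
tree_with_qc <- function(tree, qc) {
  miss <- setdiff(tree$tip.label, names(qc))
  if (length(miss)) {
    abort(paste0("QC values missing for leaf label(s): ",
                 paste(miss, collapse = ", ")))
  }
  v <- unname(qc[tree$tip.label])
  rng <- range(v)
  position <- if (rng[1] == rng[2]) {
    rep(0.5, length(v))
  } else {
    (v - rng[1]) / (rng[2] - rng[1])
  }
  structure(
    list(
      tree = tree,
      annotations = tibble::tibble(
        label = tree$tip.label, qc = v, position = position
      )
    ),
    class = "ms2_qc_tree"
  )
}

#' @export
print.ms2_qc_tree <- function(x, ...) {
  cat("<ms2_qc_tree> ", length(x$tree$tip.label), " leaves\n", sep = "")
  print(x$annotations)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ms2_qc_tree <- function(x, ...) x$annotations

#' Write a QC-annotated tree
#'
#' Serialises the tree as Newick with bracketed leaf comments
#' (`label[&qc=...,scale=...]:length`) plus a sidecar TSV of the leaf
#' annotations.
#'
#' @param x An `ms2_qc_tree` from [tree_with_qc()].
#' @param path Newick output path.
#' @param qc_path Sidecar TSV path; default appends `.qc.tsv`.
#' @return `path`, invisibly.
#' @export
write_annotated_newick <- function(x, path,
                                   qc_path = paste0(path, ".qc.tsv")) {
  tree <- x$tree
  ann <- x$annotations
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- rep(NA_real_, max(tree$edge))
  blen[tree$edge[, 2]] <- tree$edge.length
  fmt <- function(v) formatC(v, format = "g", digits = 15, width = 1)
  rec <- function(node) {
    core <- if (node <= n_tip) {
      lab <- tree$tip.label[node]
      a <- ann[ann$label == lab, ]
      paste0(lab, "[&qc=", fmt(a$qc), ",scale=", fmt(a$position), "]")
    } else {
      paste0("(", paste(vapply(kids[[as.character(node)]], rec, character(1)),
                        collapse = ","), ")")
    }
    if (!is.na(blen[node])) core <- paste0(core, ":", fmt(blen[node]))
    core
  }
  writeLines(paste0(rec(n_tip + 1L), ";"), path)
  utils::write.table(ann, qc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot a QC-annotated tree
#'
#' Standard \pkg{ape} phylogram with tip labels coloured along a viridis
#' gradient by the normalised QC position.
#'
#' @param x An `ms2_qc_tree`.
#' @param ... Passed to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.ms2_qc_tree <- function(x, ...) {
  pal <- grDevices::colorRamp(c("#440154", "#21918c", "#fde725"))
  pos <- x$annotations$position[match(x$tree$tip.label,
                                      x$annotations$label)]
  cols <- grDevices::rgb(pal(pos), maxColorValue = 255)
  ape::plot.phylo(x$tree, tip.color = cols, ...)
  invisible(x)
}
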