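#' Enumerate dataset pairs for comparison
#'
#' With the symmetric metric, `(n^2 - n) / 2` unordered pairs; with the
#' directional metric, `n^2 - n` ordered pairs. Pairs are produced
#' row-major — `(2,1), (3,1), (3,2), (4,1), ...` — so each completed "row"
#' of the distance matrix triggers a checkpoint and tree update during a
#' run.
#'
#' @param n_datasets Number of datasets (>= 2).
#' @param metric_version `"v2_symmetric"` or `"v1_directional"`.
#' @return A tibble with integer columns `i`, `j` (and both orders of each
#'   pair for the directional metric).
#' @examples
#' nrow(enumerate_pairs(24))   # 276
#' nrow(enumerate_pairs(100))  # 4950
#' @export
enumerate_pairs <- function(n_datasets,
                            metric_version = c("v2_symmetric",
                                               "v1_directional")) {
  metric_version <- match.arg(metric_version)
  if (n_datasets < 2) abort("need at least 2 datasets to compare.")
  rows <- lapply(seq(2, n_datasets), function(i) {
    tibble::tibble(i = i, j = seq_len(i - 1))
  })
  pairs <- dplyr::bind_rows(rows)
  if (metric_version == "v1_directional") {
    pairs <- dplyr::bind_rows(pairs, dplyr::rename(pairs, i = "j", j = "i")) |>
      dplyr::arrange(pmax(.data$i, .data$j), pmin(.data$i, .data$j),
                     dplyr::desc(.data$i))
  }
  pairs
}

#' Read a sample-to-species mapping TSV
#'
#' Two-column tab-separated file `sample`, `species` (header optional; if
#' absent the columns are taken in that order).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `sample`, `species`.
#' @export
read_sample_mapping <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("sample", first, ignore.case = TRUE)
  tab <- utils::read.delim(path, header = has_header,
                           colClasses = "character")
  names(tab)[1:2] <- c("sample", "species")
  tibble::as_tibble(tab[, 1:2])
}

order_labels <- function(labels, counts, compare_order, seed) {
  switch(compare_order,
    alphabetical = sort(labels),
    smallest_largest_first = labels[order(counts, labels)],
    random = with_local_seed(seed, sample(labels))
  )
}

#' Run the full dataset-comparison pipeline on a directory of MGF files
#'
#' End-to-end orchestration: read every `.mgf` file in `input_dir`, apply
#' the intensity/chromatography filters and the optional top-N selection,
#' compare all dataset pairs in the configured order, aggregate the
#' pairwise distances by species and write the distance matrix (MEGA
#' format), the UPGMA tree (Newick, with QC-annotated variant and sidecar)
#' and, optionally per pair, a key-value result file and the precursor
#' m/z-difference by similarity histogram. After each completed matrix row
#' a checkpoint matrix and tree over the so-far-completed datasets are
#' written, so interrupted runs leave usable artifacts. A structured log
#' records parameters, per-pair timings and undefined-value events.
#'
#' Defaults reproduce the tool's standard configuration (symmetric metric,
#' cosine score with square-root scaling and noise floor 10, s_min 0.8,
#' precursor window 2.05 Th, RT window 60 s, minimum base peak 10000,
#' smallest-largest-first compare order, MEGA output).
#'
#' With `metric_version = "v1_directional"` each pair is scored in both
#' directions and both the strictly upper and the strictly lower
#' triangular matrices are written; the tree is built from their average.
#'
#' @param input_dir Directory containing at least two `.mgf` files.
#' @param mapping Optional sample-to-species mapping: a data frame
#'   (`sample`, `species`) or a TSV path; default, one species per sample.
#' @param params [similarity_params()].
#' @param window [comparison_window()].
#' @param min_basepeak,min_tic,rt_range,scan_range Filters, see
#'   [filter_spectra()].
#' @param top_n Keep only the N most intense spectra per dataset
#'   ([select_top_n()]); `Inf` keeps all.
#' @param metric_version `"v2_symmetric"` (default) or `"v1_directional"`.
#' @param compare_order `"smallest_largest_first"` (ascending dataset
#'   spectrum count; default), `"alphabetical"`, or `"random"`.
#' @param seed Seed for `compare_order = "random"`.
#' @param output_dir Where to write artifacts; created if needed.
#' @param output_format Tree serialisation: `"MEGA"` writes the matrix
#'   only (plus the always-written Newick tree), `"Newick"` or `"NEXUS"`
#'   additionally write the tree in that format.
#' @param aggregate_stat Replicate aggregation, `"mean"` or `"min"`.
#' @param write_histograms Write a per-pair histogram TSV?
#' @param checkpoints Write per-row checkpoint matrices/trees?
#' @return An object of class `ms2_run`: list with `comparisons` (tidy
#'   tibble, one row per pair), `samples` and `species` distance matrices
#'   ([ms2_distmat]), `tree` (phylo or `NULL` if fewer than two species
#'   have fully defined rows), `qc_tree`, `mapping`, `files` (paths
#'   written) and `log`.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' panel <- make_species_panel(n_species = 3, samples_per_species = 1,
#'                             n_spectra = 25, dir = dir, seed = 2)
#' run <- compare_ms2(dir, mapping = file.path(dir, "mapping.tsv"),
#'                    min_basepeak = 0, output_dir = tempfile())
#' tidy(run)
#' }
#' @export
compare_ms2 <- function(input_dir,
                        mapping = NULL,
                        params = similarity_params(),
                        window = comparison_window(),
                        min_basepeak = 10000,
                        min_tic = 0,
                        rt_range = c(0, 100000),
                        scan_range = c(1, 1000000),
                        top_n = Inf,
                        metric_version = c("v2_symmetric", "v1_directional"),
                        compare_order = c("smallest_largest_first",
                                          "alphabetical", "random"),
                        seed = NULL,
                        output_dir = file.path(input_dir, "ms2dist_out"),
                        output_format = c("MEGA", "Newick", "NEXUS"),
                        aggregate_stat = c("mean", "min"),
                        write_histograms = TRUE,
                        checkpoints = TRUE) {
  metric_version <- match.arg(metric_version)
  compare_order <- match.arg(compare_order)
  output_format <- match.arg(output_format)
  aggregate_stat <- match.arg(aggregate_stat)

  files <- sort(list.files(input_dir, pattern = "\\.mgf$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) < 2) {
    abort(sprintf("input directory '%s' holds %d MGF file(s); need >= 2.",
                  input_dir, length(files)))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (checkpoints) {
    dir.create(file.path(output_dir, "checkpoints"), showWarnings = FALSE)
  }
  dir.create(file.path(output_dir, "pairs"), showWarnings = FALSE)

  log_lines <- character(0)
  log_add <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  log_add("ms2dist run: %d MGF files in %s", length(files), input_dir)
  log_add(paste0(
    "parameters: measure=%s scaling=%g noise=%s bin_width=%g s_min=%g ",
    "dmz=%g rt_diff=%g scan_diff=%g min_basepeak=%g min_tic=%g top_n=%s ",
    "metric=%s order=%s"),
    params$measure, params$scaling_exponent,
    if (is.na(params$noise_floor)) "auto" else params$noise_floor,
    params$bin_width, params$s_min,
    window$max_precursor_dmz, window$max_rt_diff, window$max_scan_diff,
    min_basepeak, min_tic,
    if (is.infinite(top_n)) "all" else top_n,
    metric_version, compare_order)

  # all files are parsed (and thus format-checked) before any comparison
  datasets <- lapply(files, read_mgf)
  datasets <- lapply(datasets, function(ds) {
    ds <- filter_spectra(ds, min_basepeak = min_basepeak, min_tic = min_tic,
                         rt_range = rt_range, scan_range = scan_range)
    select_top_n(ds, top_n)
  })
  labels <- vapply(datasets, dataset_label, character(1))
  names(datasets) <- labels
  counts <- vapply(datasets, nrow, integer(1))
  for (k in seq_along(labels)) {
    log_add("dataset %s: %d spectra after filtering", labels[k], counts[k])
    if (counts[k] == 0) {
      log_add("dataset %s is empty: its comparisons will be UNDEFINED",
              labels[k])
    }
  }

  if (is.character(mapping)) mapping <- read_sample_mapping(mapping)
  if (is.null(mapping)) {
    mapping <- tibble::tibble(sample = labels, species = labels)
  }
  mapping <- tibble::as_tibble(mapping)

  ord <- order_labels(labels, counts, compare_order, seed)
  pairs <- enumerate_pairs(length(ord), metric_version)
  log_add("comparing %d datasets: %d pairwise comparisons scheduled",
          length(ord), nrow(pairs))

  res_rows <- list()
  directional <- list()
  dmat <- matrix(NA_real_, length(ord), length(ord),
                 dimnames = list(ord, ord))
  diag(dmat) <- 0
  paths <- character(0)

  checkpoint_row <- function(i) {
    done <- ord[seq_len(i)]
    sub <- dmat[done, done, drop = FALSE]
    cp_base <- file.path(output_dir, "checkpoints",
                         sprintf("after_row_%02d", i))
    write_mega(ms2_distmat(sub, labels = done),
               paste0(cp_base, ".meg"),
               title = sprintf("checkpoint after %d of %d rows",
                               i, length(ord)))
    paths <<- c(paths, paste0(cp_base, ".meg"))
    if (i >= 2 && !anyNA(sub)) {
      write_newick(upgma(ms2_distmat(sub, labels = done)),
                   paste0(cp_base, ".nwk"))
      paths <<- c(paths, paste0(cp_base, ".nwk"))
    }
  }

  done_in_row <- integer(length(ord))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs$i[p]
    j <- pairs$j[p]
    if (i < j) next  # directional duplicates are derived below
    la <- ord[i]
    lb <- ord[j]
    t0 <- proc.time()[["elapsed"]]
    cmp <- compare_datasets(datasets[[la]], datasets[[lb]],
                            params = params, window = window,
                            histogram = write_histograms)
    dt <- proc.time()[["elapsed"]] - t0
    row <- tidy(cmp)
    res_rows[[length(res_rows) + 1L]] <- row
    dmat[la, lb] <- dmat[lb, la] <- cmp$D
    if (metric_version == "v1_directional") {
      directional[[length(directional) + 1L]] <- tibble::tibble(
        from = c(la, lb), to = c(lb, la),
        fraction = c(row$fraction_a, row$fraction_b),
        n_from = c(row$n_a, row$n_b)
      )
    }
    pf <- file.path(output_dir, "pairs", paste0(la, "__", lb, ".txt"))
    write_pair_result(cmp, pf)
    paths <- c(paths, pf)
    if (write_histograms) {
      hf <- file.path(output_dir, "pairs",
                      paste0(la, "__", lb, ".histogram.tsv"))
      write_histogram(cmp, hf)
      paths <- c(paths, hf)
    }
    if (is.na(cmp$S)) {
      log_add("pair %s vs %s: S UNDEFINED (empty dataset)", la, lb)
    }
    log_add("pair %s vs %s: S=%s D=%s (%.2fs)", la, lb,
            format_undef(cmp$S), format_undef(cmp$D), dt)
    done_in_row[i] <- done_in_row[i] + 1L
    if (checkpoints && done_in_row[i] == i - 1L) {
      checkpoint_row(i)
      log_add("row %d of %d complete; checkpoint written", i, length(ord))
    }
  }

  comparisons <- dplyr::bind_rows(res_rows)

  if (metric_version == "v1_directional") {
    # directional distances: the matched fraction in the scanned direction,
    # passed through the same 1/f - 1 transform (finite floor when f = 0)
    dir_tbl <- dplyr::bind_rows(directional) |>
      dplyr::mutate(D = ifelse(
        is.na(.data$fraction), NA_real_,
        ifelse(.data$fraction > 0, 1 / .data$fraction - 1,
               2 * .data$n_from - 1)
      ))
    dmat_dir <- matrix(NA_real_, length(ord), length(ord),
                       dimnames = list(ord, ord))
    diag(dmat_dir) <- 0
    dmat_dir[cbind(dir_tbl$from, dir_tbl$to)] <- dir_tbl$D
    up <- dmat_dir
    up[lower.tri(up)] <- t(up)[lower.tri(up)]
    lo <- dmat_dir
    lo[upper.tri(lo)] <- t(lo)[upper.tri(lo)]
    for (tri in c("upper", "lower")) {
      f <- file.path(output_dir, paste0("distance_matrix_", tri, ".meg"))
      write_mega(ms2_distmat(if (tri == "upper") up else lo, labels = ord),
                 f, triangle = tri,
                 title = sprintf("directional matrix (strictly %s triangle)",
                                 tri))
      paths <- c(paths, f)
    }
    log_add("directional mode: strictly upper and lower triangular matrices written")
    # downstream matrix/tree use the average of the two directions
    avg <- (dmat_dir + t(dmat_dir)) / 2
    dmat[ord, ord] <- avg
    comparisons$D <- avg[cbind(comparisons$label_a, comparisons$label_b)]
  }

  samples_mat <- ms2_distmat(dmat, labels = ord)
  species_mat <- withCallingHandlers(
    aggregate_by_species(comparisons, mapping, stat = aggregate_stat),
    warning = function(w) {
      log_lines <<- c(log_lines, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      log_lines <<- c(log_lines, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )

  meg <- file.path(output_dir, "distance_matrix.meg")
  write_mega(species_mat, meg)
  paths <- c(paths, meg)

  # tree over the largest label set with fully defined distances: drop the
  # species contributing the most undefined entries until none remain
  vals <- species_mat$values
  ok <- species_mat$labels
  repeat {
    if (length(ok) < 2) break
    nas <- rowSums(is.na(vals[ok, ok, drop = FALSE]))
    if (!any(nas > 0)) break
    ok <- setdiff(ok, ok[which.max(nas)])
  }
  dropped <- setdiff(species_mat$labels, ok)
  if (length(dropped)) {
    log_add("excluded from tree (undefined distances): %s",
            paste(dropped, collapse = ", "))
  }
  tree <- NULL
  qc_tree <- NULL
  if (length(ok) >= 2) {
    tree <- upgma(ms2_distmat(vals[ok, ok, drop = FALSE], labels = ok))
    qc_tree <- tree_with_qc(tree, species_mat$qc[ok])
    nwk <- file.path(output_dir, "tree.nwk")
    write_newick(tree, nwk)
    ann <- file.path(output_dir, "tree_annotated.nwk")
    write_annotated_newick(qc_tree, ann)
    paths <- c(paths, nwk, ann, paste0(ann, ".qc.tsv"))
    if (output_format == "NEXUS") {
      nex <- file.path(output_dir, "tree.nex")
      write_nexus(tree, nex)
      paths <- c(paths, nex)
    }
  } else {
    log_add("fewer than two species with defined rows: no tree written")
  }

  log_file <- file.path(output_dir, "run.log")
  writeLines(log_lines, log_file)
  paths <- c(paths, log_file)

  structure(
    list(
      comparisons = comparisons,
      samples = samples_mat,
      species = species_mat,
      tree = tree,
      qc_tree = qc_tree,
      mapping = mapping,
      files = paths,
      log = log_lines
    ),
    class = "ms2_run"
  )
}

#' @export
print.ms2_run <- function(x, ...) {
  cat("<ms2_run> ", nrow(x$comparisons), " pairwise comparisons, ",
      length(x$species$labels), " species\n", sep = "")
  print(x$species)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ms2_run <- function(x, ...) x$comparisons

#' @exportS3Method generics::glance
glance.ms2_run <- function(x, ...) {
  tibble::tibble(
    n_datasets = length(x$samples$labels),
    n_species = length(x$species$labels),
    n_comparisons = nrow(x$comparisons),
    n_undefined = sum(is.na(x$comparisons$S)),
    has_tree = !is.null(x$tree)
  )
}
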