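
# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# A template "peptidoform": a reproducible random peak list with a precursor.
# Templates are random peak lists, not fragmentation simulations — the set
# metric is sequence-agnostic, so peak-list statistics are what matters.
make_template <- function(peaks_per_spectrum, precursor_range,
                          fragment_range = c(100, 1400),
                          base_peak = 50000) {
  mz <- sort(runif(peaks_per_spectrum, fragment_range[1], fragment_range[2]))
  intensity <- rlnorm(peaks_per_spectrum, meanlog = log(1000), sdlog = 1)
  intensity <- intensity / max(intensity) * base_peak * rlnorm(1, 0, 0.3)
  list(
    peaks = cbind(mz = mz, intensity = intensity),
    precursor_mz = runif(1, precursor_range[1], precursor_range[2]),
    retention_time = runif(1, 0, 3600),
    charge = sample(2:3, 1)
  )
}

# One noisy acquisition of a template: small m/z and intensity jitter plus a
# handful of sub-noise-floor peaks, emulating repeat MS/MS of the same ion.
realize_template <- function(tpl, title,
                             mz_jitter = 0.002,
                             intensity_jitter = 0.05,
                             precursor_jitter = 0.005,
                             rt_jitter = 5,
                             noise_peaks = 5,
                             noise_max = 8) {
  p <- tpl$peaks
  mz <- p[, "mz"] + rnorm(nrow(p), 0, mz_jitter)
  intensity <- p[, "intensity"] * rlnorm(nrow(p), 0, intensity_jitter)
  if (noise_peaks > 0) {
    mz <- c(mz, runif(noise_peaks, min(p[, "mz"]), max(p[, "mz"])))
    intensity <- c(intensity, runif(noise_peaks, 1, noise_max))
  }
  o <- order(mz)
  list(
    title = title,
    precursor_mz = tpl$precursor_mz + rnorm(1, 0, precursor_jitter),
    charge = tpl$charge,
    retention_time = max(0, tpl$retention_time + rnorm(1, 0, rt_jitter)),
    scan_number = NA_integer_,
    peaks = list(cbind(mz = mz[o], intensity = intensity[o]))
  )
}

templates_to_dataset <- function(templates, label, ...) {
  rows <- lapply(seq_along(templates), function(i) {
    realize_template(templates[[i]],
                     title = sprintf("%s.scan_%d", label, i), ...)
  })
  spectra <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  # scan numbers follow retention-time order, as in a real acquisition
  spectra$scan_number <- rank(spectra$retention_time,
                              ties.method = "first")
  spectra <- spectra[order(spectra$scan_number), ]
  ms2_dataset(spectra, label = label)
}

#' Generate a synthetic MS/MS dataset
#'
#' A reproducible stand-in for one LC-MS/MS run: `n_spectra` random
#' peak-list templates, each realised once with small m/z and intensity
#' jitter and a few sub-noise peaks. Useful for examples and pipeline
#' tests; see [make_dataset_pair()] for paired datasets with controlled
#' overlap.
#'
#' @param n_spectra Number of spectra.
#' @param peaks_per_spectrum Peaks per template.
#' @param precursor_range Precursor m/z range (Th).
#' @param label Dataset label.
#' @param seed Integer seed; same seed, same dataset.
#' @return An [ms2_dataset].
#' @examples
#' synthetic_dataset(n_spectra = 3, seed = 42)
#' @export
synthetic_dataset <- function(n_spectra = 100,
                              peaks_per_spectrum = 60,
                              precursor_range = c(400, 1400),
                              label = "synthetic",
                              seed = NULL) {
  with_local_seed(seed, {
    templates <- replicate(
      n_spectra,
      make_template(peaks_per_spectrum, precursor_range),
      simplify = FALSE
    )
    templates_to_dataset(templates, label)
  })
}

#' Generate a dataset pair with a planted shared fraction
#'
#' Two synthetic datasets in which a fraction `shared_fraction` of each
#' derives from common templates (independently jittered copies, pairwise
#' cosine >= 0.95 by construction) and the remainder from dataset-unique
#' templates drawn in disjoint precursor m/z ranges, so no cross matches
#' survive the precursor window. Under the set-similarity definition the
#' expected global similarity is therefore the planted fraction and the
#' expected distance `1/f - 1`.
#'
#' @param n_spectra Spectra per dataset.
#' @param shared_fraction Planted shared fraction `f` in `[0, 1]`.
#' @param peaks_per_spectrum Peaks per template.
#' @param seed Integer seed.
#' @param labels Length-2 character vector of dataset labels.
#' @return A list with `a`, `b` ([ms2_dataset]s) and `truth` (a list with
#'   `shared_fraction`, `n_shared`, `expected_S`, `expected_D`).
#' @examples
#' pair <- make_dataset_pair(n_spectra = 50, shared_fraction = 0.5, seed = 7)
#' tidy(compare_datasets(pair$a, pair$b))
#' @export
make_dataset_pair <- function(n_spectra = 1000,
                              shared_fraction = 0.5,
                              peaks_per_spectrum = 60,
                              seed = NULL,
                              labels = c("sample_a", "sample_b")) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1, n_spectra >= 1)
  with_local_seed(seed, {
    n_shared <- round(shared_fraction * n_spectra)
    n_unique <- n_spectra - n_shared
    shared <- replicate(
      n_shared,
      make_template(peaks_per_spectrum, precursor_range = c(400, 900)),
      simplify = FALSE
    )
    uniq_a <- replicate(
      n_unique,
      make_template(peaks_per_spectrum, precursor_range = c(950, 1150)),
      simplify = FALSE
    )
    uniq_b <- replicate(
      n_unique,
      make_template(peaks_per_spectrum, precursor_range = c(1200, 1400)),
      simplify = FALSE
    )
    a <- templates_to_dataset(c(shared, uniq_a), labels[1])
    b <- templates_to_dataset(c(shared, uniq_b), labels[2])
    f <- n_shared / n_spectra
    list(
      a = a, b = b,
      truth = list(
        shared_fraction = shared_fraction,
        n_shared = n_shared,
        expected_S = f,
        expected_D = if (f > 0) 1 / f - 1 else
          global_distance(0, n_spectra, n_spectra)
      )
    )
  })
}

caterpillar_fractions <- function(n_species, base_shared = 0.2,
                                  max_shared = 0.8) {
  depths <- n_species - 1L
  if (depths == 1L) return(max_shared)
  base_shared + (max_shared - base_shared) * (seq_len(depths) - 1) /
    (depths - 1)
}

#' Generate a multi-species panel of MGF files with a planted phylogeny
#'
#' Emulates a cross-species comparison study: species lie on a caterpillar
#' (ladder) tree and each species' template set is drawn from nested clade
#' pools, so the fraction of shared templates between two species is a
#' decreasing function of the depth of their most recent common ancestor.
#' The induced expected distances `1/f - 1` depend only on that ancestor,
#' so the planted topology is recoverable by UPGMA from the computed
#' distance matrix. Each sample (replicate) of a species is an independent
#' jittered realisation of the species template set.
#'
#' Writes one MGF per sample plus a two-column `mapping.tsv`
#' (sample, species) and a `truth.json` with the planted parameters and
#' tree to `dir`.
#'
#' @param n_species Number of species (>= 2).
#' @param samples_per_species Replicate LC-MS/MS runs per species.
#' @param n_spectra Spectra per sample.
#' @param base_shared,max_shared Shared template fraction at the root and
#'   at the deepest clade; intermediate clades are interpolated linearly.
#' @param peaks_per_spectrum Peaks per template.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return A list with `dir`, `mapping` (tibble `sample`, `species`),
#'   `tree` (the planted \pkg{ape} `phylo`), `expected_D` (species-level
#'   [ms2_distmat]) and `files`.
#' @examples
#' \donttest{
#' panel <- make_species_panel(n_species = 3, samples_per_species = 1,
#'                             n_spectra = 30, dir = tempfile(), seed = 1)
#' panel$mapping
#' }
#' @export
make_species_panel <- function(n_species = 5,
                               samples_per_species = 2,
                               n_spectra = 150,
                               base_shared = 0.2,
                               max_shared = 0.8,
                               peaks_per_spectrum = 60,
                               dir = tempfile("ms2panel"),
                               seed = NULL) {
  stopifnot(n_species >= 2, samples_per_species >= 1,
            base_shared > 0, max_shared < 1, base_shared <= max_shared)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(seed, {
    species <- sprintf("sp%02d", seq_len(n_species))
    f_cum <- caterpillar_fractions(n_species, base_shared, max_shared)
    depths <- n_species - 1L

    # pool sizes: node at depth d (1 = root, depths = MRCA of sp1/sp2)
    pool_n <- round(diff(c(0, f_cum)) * n_spectra)
    pools <- lapply(pool_n, function(k) {
      replicate(k, make_template(peaks_per_spectrum, c(400, 1400)),
                simplify = FALSE)
    })

    # species j sits on the path root..node_{depths - j + 2} (species 1 and 2
    # share the deepest node); remaining templates are species-unique
    path_depth <- function(j) if (j == 1L) depths else depths - j + 2L
    sp_templates <- lapply(seq_len(n_species), function(j) {
      shared <- unlist(pools[seq_len(path_depth(j))], recursive = FALSE)
      n_uniq <- n_spectra - length(shared)
      uniq <- replicate(n_uniq,
                        make_template(peaks_per_spectrum, c(400, 1400)),
                        simplify = FALSE)
      c(shared, uniq)
    })

    mapping <- tidyr::expand_grid(
      species = species,
      rep = seq_len(samples_per_species)
    ) |>
      dplyr::mutate(sample = sprintf("%s_r%d", .data$species, .data$rep)) |>
      dplyr::select("sample", "species")

    files <- character(0)
    for (j in seq_len(n_species)) {
      for (r in seq_len(samples_per_species)) {
        lab <- sprintf("%s_r%d", species[j], r)
        ds <- templates_to_dataset(sp_templates[[j]], lab)
        f <- file.path(dir, paste0(lab, ".mgf"))
        write_mgf(ds, f)
        files <- c(files, f)
      }
    }
    utils::write.table(mapping, file.path(dir, "mapping.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    # expected species-level distances and the planted tree
    mrca_depth <- function(i, j) {
      jj <- max(i, j)
      if (jj <= 2L) depths else depths - jj + 2L
    }
    D <- matrix(0, n_species, n_species,
                dimnames = list(species, species))
    for (i in seq_len(n_species - 1)) {
      for (j in seq(i + 1, n_species)) {
        f_ij <- f_cum[mrca_depth(i, j)]
        D[i, j] <- D[j, i] <- 1 / f_ij - 1
      }
    }
    expected <- ms2_distmat(D, labels = species)
    tree <- upgma(expected)

    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        list(
          n_species = n_species,
          samples_per_species = samples_per_species,
          n_spectra = n_spectra,
          shared_fraction_by_depth = f_cum,
          expected_D = D,
          tree_newick = ape::write.tree(tree)
        ),
        file.path(dir, "truth.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    list(dir = dir, mapping = mapping, tree = tree,
         expected_D = expected, files = files)
  })
}
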