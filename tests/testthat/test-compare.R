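test_that("global similarity follows the matched-fraction average", {
  expect_equal(global_similarity(1, 1, 1, 1), 1)
  expect_equal(global_similarity(3, 5, 0, 0), 0)
  expect_equal(global_similarity(4, 2, 1, 1), 0.375)
  expect_true(is.na(global_similarity(0, 5, 0, 0)))
  expect_true(is.na(global_similarity(5, 0, 0, 0)))
  expect_error(global_similarity(2, 2, 3, 0), "exceeds")
})

test_that("global distance inverts S with the finite S = 0 floor", {
  expect_equal(global_distance(1), 0)
  expect_equal(global_distance(0.5), 1)
  expect_equal(global_distance(0, 1, 1), 1)      # dissimilar singletons
  expect_equal(global_distance(0, 10, 40), 31, tolerance = 1e-14)
  expect_true(is.na(global_distance(NA_real_)))
  expect_error(global_distance(1.5), "\\[0, 1\\]")
  # the S = 0 floor always exceeds the distance at one real matched pair
  for (n_a in c(1, 3, 10)) {
    for (n_b in c(1, 7, 40)) {
      s_minpos <- (1 / n_a + 1 / n_b) / 2
      expect_gt(global_distance(0, n_a, n_b), global_distance(s_minpos))
    }
  }
})

test_that("a dataset matched against itself is fully matched", {
  ds <- synthetic_dataset(n_spectra = 15, seed = 21)
  cmp <- compare_datasets(ds, ds, window = infinite_window())
  expect_equal(cmp$matched_a, nrow(ds))
  expect_equal(cmp$matched_b, nrow(ds))
  expect_equal(cmp$S, 1)
  expect_equal(cmp$D, 0)
})

test_that("a hand-built 4-vs-2 pair with one similar pair gives S = 0.375", {
  # a1 and b1 share peaks; everything else is orthogonal
  A <- tiny_dataset(
    list(peaks_at(c(100, 200)), peaks_at(c(310, 320)),
         peaks_at(c(410, 420)), peaks_at(c(510, 520))),
    precursor_mz = c(500, 600, 700, 800), label = "A"
  )
  B <- tiny_dataset(
    list(peaks_at(c(100, 200)), peaks_at(c(910, 920))),
    precursor_mz = c(500.5, 900), label = "B"
  )
  p <- open_params()
  w <- infinite_window()
  # brute-force enumeration of all 8 pairs agrees
  bf <- oracle_matched_counts(A, B, p, w)
  expect_equal(bf$matched_a, 1L)
  expect_equal(bf$matched_b, 1L)
  cmp <- compare_datasets(A, B, p, w)
  expect_equal(cmp$matched_a, 1L)
  expect_equal(cmp$matched_b, 1L)
  expect_equal(cmp$S, 0.375)
  expect_equal(cmp$D, 1 / 0.375 - 1)
  expect_equal(directional_similarity(A, B, p, w), 0.25)
  expect_equal(directional_similarity(B, A, p, w), 0.5)
})

test_that("no pair above s_min means zero matches but a defined S of 0", {
  A <- tiny_dataset(list(peaks_at(c(100, 200))), 500, label = "A")
  B <- tiny_dataset(list(peaks_at(c(300, 400))), 500.2, label = "B")
  cmp <- compare_datasets(A, B, open_params(), infinite_window())
  expect_equal(cmp$matched_a, 0L)
  expect_equal(cmp$S, 0)
  expect_equal(cmp$D, 1)  # singleton floor
})

test_that("windowed search equals all-pairs brute force on random pairs", {
  finite <- comparison_window(max_precursor_dmz = 30, max_rt_diff = 120,
                              max_scan_diff = 100)
  p <- similarity_params()
  set.seed(19)
  for (sd in 1:12) {
    pair <- make_dataset_pair(n_spectra = sample(5:40, 1),
                              shared_fraction = runif(1), seed = sd)
    for (w in list(infinite_window(), finite)) {
      cmp <- compare_datasets(pair$a, pair$b, p, w, histogram = FALSE)
      bf <- oracle_matched_counts(pair$a, pair$b, p, w)
      expect_equal(cmp$matched_a, bf$matched_a)
      expect_equal(cmp$matched_b, bf$matched_b)
    }
  }
})

test_that("S and D are symmetric under swapping the inputs", {
  for (sd in 1:6) {
    pair <- make_dataset_pair(n_spectra = 30, shared_fraction = 0.4,
                              seed = sd)
    ab <- compare_datasets(pair$a, pair$b)
    ba <- compare_datasets(pair$b, pair$a)
    expect_equal(ab$S, ba$S)
    expect_equal(ab$D, ba$D)
  }
})

test_that("shrinking any window bound never increases matched counts", {
  pair <- make_dataset_pair(n_spectra = 40, shared_fraction = 0.6, seed = 8)
  wide <- compare_datasets(pair$a, pair$b, window = comparison_window(
    max_precursor_dmz = 5, max_rt_diff = 500, max_scan_diff = 1e5))
  for (w in list(comparison_window(max_precursor_dmz = 0.5,
                                   max_rt_diff = 500, max_scan_diff = 1e5),
                 comparison_window(max_precursor_dmz = 5,
                                   max_rt_diff = 5, max_scan_diff = 1e5))) {
    narrow <- compare_datasets(pair$a, pair$b, window = w)
    expect_lte(narrow$matched_a, wide$matched_a)
    expect_lte(narrow$matched_b, wide$matched_b)
  }
})

test_that("RT windowing falls back to scan numbers when RT is absent", {
  A <- tiny_dataset(list(peaks_at(c(100, 200))), 500,
                    scan_number = 100L, label = "A")
  B <- tiny_dataset(list(peaks_at(c(100, 200))), 500,
                    scan_number = 5000L, label = "B")
  hit <- compare_datasets(A, B, open_params(),
                          comparison_window(2.05, 60, 10000))
  expect_equal(hit$matched_a, 1L)
  miss <- compare_datasets(A, B, open_params(),
                           comparison_window(2.05, 60, 1000))
  expect_equal(miss$matched_a, 0L)
})

test_that("empty datasets propagate UNDEFINED, never impute", {
  empty <- tiny_dataset(list(), numeric(0), label = "empty")
  full <- synthetic_dataset(5, seed = 2)
  cmp <- compare_datasets(empty, full)
  expect_true(is.na(cmp$S))
  expect_true(is.na(cmp$D))
  f <- withr::local_tempfile()
  write_pair_result(cmp, f)
  expect_match(paste(readLines(f), collapse = "\n"), "S\tUNDEFINED")
  back <- read_pair_result(f)
  expect_true(is.na(back$S))
  expect_true(is.na(back$D))
})

test_that("pair result files round-trip the comparison summary", {
  pair <- make_dataset_pair(n_spectra = 25, shared_fraction = 0.4, seed = 3)
  cmp <- compare_datasets(pair$a, pair$b)
  f <- withr::local_tempfile()
  write_pair_result(cmp, f)
  back <- read_pair_result(f)
  expect_equal(back, tidy(cmp), tolerance = 1e-9)
})

test_that("every evaluated pair lands in exactly one histogram cell", {
  A <- tiny_dataset(list(peaks_at(c(100, 200))), 500, label = "A")
  B <- tiny_dataset(list(peaks_at(c(100, 200))), 500, label = "B")
  cmp <- compare_datasets(A, B, open_params())
  expect_equal(sum(cmp$histogram), 1L)
  tab <- histogram_tidy(cmp)
  hit <- tab[tab$count > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_lt(abs(hit$dmz), 0.01)
  expect_gt(hit$similarity, 0.99)
})

test_that("an all-zero histogram grid is still written", {
  A <- tiny_dataset(list(peaks_at(100)), 100, label = "A")
  B <- tiny_dataset(list(peaks_at(100)), 900, label = "B")  # outside window
  cmp <- compare_datasets(A, B, open_params())
  expect_equal(sum(cmp$histogram), 0L)
  f <- withr::local_tempfile()
  write_histogram(cmp, f)
  tab <- utils::read.delim(f)
  expect_equal(sum(tab$count), 0L)
  expect_equal(nrow(tab), nrow(cmp$histogram) * ncol(cmp$histogram))
})

test_that("isotope-selection errors appear as 1/2 Da side bands", {
  # same fragments, precursor offset by one 13C at charge 2 in each direction
  p <- open_params()
  A <- tiny_dataset(list(peaks_at(c(100, 200)), peaks_at(c(300, 400))),
                    precursor_mz = c(500, 700), label = "A")
  B <- tiny_dataset(list(peaks_at(c(100, 200)), peaks_at(c(300, 400))),
                    precursor_mz = c(500.5015, 699.4985), label = "B")
  cmp <- compare_datasets(A, B, p)
  tab <- histogram_tidy(cmp)
  hit <- tab[tab$count > 0 & tab$similarity > 0.9, ]
  expect_equal(nrow(hit), 2L)
  expect_true(all(abs(abs(hit$dmz) - 0.5) < 0.011))
  expect_setequal(sign(hit$dmz), c(-1, 1))
})

test_that("tidy and glance summarise a comparison", {
  pair <- make_dataset_pair(n_spectra = 10, shared_fraction = 1, seed = 4)
  cmp <- compare_datasets(pair$a, pair$b)
  td <- tidy(cmp)
  expect_named(td, c("label_a", "label_b", "n_a", "n_b", "matched_a",
                     "matched_b", "fraction_a", "fraction_b", "S", "D"))
  expect_equal(td$S, 1)
  gl <- glance(cmp)
  expect_equal(gl$s_min, 0.8)
  expect_gt(gl$n_evaluated, 0)
})
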