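result_row <- function(a, b, D, n_a = 100, n_b = 100) {
  tibble::tibble(label_a = a, label_b = b, n_a = n_a, n_b = n_b, D = D)
}

test_that("one sample per species passes distances through unchanged", {
  res <- dplyr::bind_rows(
    result_row("s1", "s2", 0.5),
    result_row("s1", "s3", 2),
    result_row("s2", "s3", 4)
  )
  m <- aggregate_by_species(res)
  expect_s3_class(m, "ms2_distmat")
  expect_equal(m$values["s1", "s2"], 0.5)
  expect_equal(m$values["s2", "s3"], 4)
  expect_equal(diag(m$values), c(s1 = 0, s2 = 0, s3 = 0))
})

test_that("replicate distances aggregate by the arithmetic mean", {
  mapping <- tibble::tibble(sample = c("x1", "x2", "y1", "y2"),
                            species = c("X", "X", "Y", "Y"))
  res <- dplyr::bind_rows(
    result_row("x1", "y1", 1), result_row("x1", "y2", 1),
    result_row("x2", "y1", 3), result_row("x2", "y2", 3),
    result_row("x1", "x2", 0.01), result_row("y1", "y2", 0.02)
  )
  m <- aggregate_by_species(res, mapping)
  expect_equal(m$values["X", "Y"], 2)
  # intra-species comparisons never leak into the matrix
  expect_equal(diag(m$values), c(X = 0, Y = 0))
  # min is available as an alternative
  expect_equal(aggregate_by_species(res, mapping,
                                    stat = "min")$values["X", "Y"], 1)
  # species QC = summed member spectrum counts
  expect_equal(unname(m$qc), c(200, 200))
})

test_that("24 samples over six species give a 6x6 matrix from 276 pairs", {
  samples <- sprintf("s%02d", 1:24)
  mapping <- tibble::tibble(sample = samples,
                            species = rep(sprintf("sp%d", 1:6), each = 4))
  pairs <- t(utils::combn(samples, 2))
  expect_equal(nrow(pairs), nrow(enumerate_pairs(24)))
  res <- tibble::tibble(
    label_a = pairs[, 1], label_b = pairs[, 2],
    n_a = 1000, n_b = 1000, D = runif(nrow(pairs), 0.5, 5)
  )
  m <- aggregate_by_species(res, mapping)
  expect_equal(dim(m$values), c(6L, 6L))
  expect_equal(unname(m$qc), rep(4000, 6))
})

test_that("aggregation is invariant to sample order and relabeling", {
  mapping <- tibble::tibble(sample = c("a1", "a2", "b1"),
                            species = c("A", "A", "B"))
  res <- dplyr::bind_rows(
    result_row("a1", "b1", 2), result_row("b1", "a2", 4)
  )
  m1 <- aggregate_by_species(res, mapping)
  m2 <- aggregate_by_species(res[2:1, ], mapping[c(3, 1, 2), ])
  expect_equal(m1$values["A", "B"], 3)
  expect_equal(m2$values["A", "B"], m1$values["A", "B"])
})

test_that("undefined sample pairs are excluded; empty species pairs warn", {
  mapping <- tibble::tibble(sample = c("a1", "a2", "b1"),
                            species = c("A", "A", "B"))
  res <- dplyr::bind_rows(
    result_row("a1", "b1", NA_real_), result_row("a2", "b1", 6)
  )
  expect_message(m <- aggregate_by_species(res, mapping), "excluded")
  expect_equal(m$values["A", "B"], 6)

  res2 <- result_row("a1", "b1", NA_real_)
  expect_warning(
    m2 <- aggregate_by_species(res2,
                               mapping[mapping$sample != "a2", ]),
    "UNDEFINED"
  )
  expect_true(is.na(m2$values["A", "B"]))
  expect_error(aggregate_by_species(res, mapping[1, ]), "not present")
})

test_that("MEGA files round-trip labels and values at 6 significant digits", {
  set.seed(7)
  n <- 5
  vals <- matrix(0, n, n)
  vals[lower.tri(vals)] <- runif(n * (n - 1) / 2, 0.001, 30)
  vals <- vals + t(vals)
  labels <- c("Homo_sapiens", "Pan", "Canis", "Procavia", "Odocoileus")
  dimnames(vals) <- list(labels, labels)
  m <- ms2_distmat(vals)
  f <- withr::local_tempfile(fileext = ".meg")
  write_mega(m, f)
  expect_equal(readLines(f, n = 1), "#mega")
  back <- read_mega(f)
  expect_equal(back$labels, labels)
  expect_equal(back$values, m$values, tolerance = 1e-5)
  # upper-right variant round-trips too
  f2 <- withr::local_tempfile(fileext = ".meg")
  write_mega(m, f2, triangle = "upper")
  expect_equal(read_mega(f2)$values, m$values, tolerance = 1e-5)
})

test_that("undefined matrix entries use the declared missing symbol", {
  vals <- matrix(c(0, 1, NA, 1, 0, 2, NA, 2, 0), 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m <- ms2_distmat(vals)
  f <- withr::local_tempfile(fileext = ".meg")
  write_mega(m, f)
  txt <- readLines(f)
  expect_match(txt[grepl("!Format", txt)], "MissingSymbol=\\?")
  expect_true(any(grepl("\\?", txt[!startsWith(txt, "!")])))
  back <- read_mega(f)
  expect_true(is.na(back$values["A", "C"]))
  expect_equal(back$values["B", "C"], 2)
})

test_that("tidy() flattens a distance matrix to unordered pairs", {
  m <- ms2_distmat(matrix(c(0, 4, 4, 0), 2,
                          dimnames = list(c("A", "B"), c("A", "B"))))
  td <- tidy(m)
  expect_equal(td$item1, "A")
  expect_equal(td$item2, "B")
  expect_equal(td$distance, 4)
  expect_equal(as.matrix(stats::as.dist(m))["A", "B"], 4)
})

test_that("asymmetric input is rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(ms2_distmat(bad), "not symmetric")
})
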