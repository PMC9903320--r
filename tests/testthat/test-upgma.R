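root_leaf_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

rand_distmat <- function(n, seed) {
  set.seed(seed)
  v <- matrix(0, n, n)
  v[lower.tri(v)] <- runif(n * (n - 1) / 2, 0.5, 10)
  v <- v + t(v)
  dimnames(v) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  v
}

test_that("two taxa force an ultrametric cherry at height D/2", {
  m <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(m)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(unname(root_leaf_depths(tr)), c(2, 2))
})

test_that("three taxa agglomerate with the weighted average", {
  m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(ape::write.tree(upgma(m)), "((A:1,B:1):3,C:4);")
})

test_that("all-equal distances resolve deterministically by label order", {
  labs <- c("delta", "alpha", "charlie", "bravo")
  m <- matrix(3, 4, 4, dimnames = list(labs, labs))
  diag(m) <- 0
  tr <- upgma(m)
  expect_equal(unname(root_leaf_depths(tr)), rep(1.5, 4))
  # first merge must be the lexicographically smallest pair: alpha+bravo
  first_cherry <- ape::extract.clade(
    tr, ape::getMRCA(tr, c("alpha", "bravo")))
  expect_setequal(first_cherry$tip.label, c("alpha", "bravo"))
  # identical call, identical tree
  expect_equal(ape::write.tree(upgma(m)), ape::write.tree(tr))
})

test_that("upgma agrees with average-linkage hclust on random matrices", {
  for (seed in 1:10) {
    n <- 3 + (seed %% 6)  # 3..8 taxa
    v <- rand_distmat(n, seed)
    mine <- upgma(v)
    oracle <- ape::as.phylo(stats::hclust(stats::as.dist(v), "average"))
    expect_equal(phangorn::RF.dist(mine, oracle), 0)
    # node heights agree (as.phylo halves the hclust merge heights)
    expect_equal(sort(ape::branching.times(mine)),
                 sort(ape::branching.times(oracle)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # ultrametric: all root-to-leaf path lengths equal
    depths <- root_leaf_depths(mine)
    expect_lt(diff(range(depths)), 1e-9)
  }
})

test_that("Newick serialisation round-trips topology and branch lengths", {
  v <- rand_distmat(6, 99)
  tr <- upgma(v)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_equal(phangorn::RF.dist(tr, back), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-8)
  f2 <- withr::local_tempfile(fileext = ".nex")
  write_nexus(tr, f2)
  expect_equal(phangorn::RF.dist(ape::read.nexus(f2), tr), 0)
})

test_that("undefined matrix entries stop tree building with guidance", {
  v <- rand_distmat(3, 1)
  v[1, 2] <- v[2, 1] <- NA
  expect_error(upgma(ms2_distmat(v)), "UNDEFINED")
  expect_error(upgma(matrix(0, 1, 1, dimnames = list("A", "A"))),
               "at least 2")
})

test_that("QC annotation normalises leaf values to the unit scale", {
  m <- matrix(3, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(m) <- 0
  tr <- upgma(m)
  qct <- tree_with_qc(tr, c(A = 1000, B = 2000, C = 3000))
  ann <- tidy(qct)
  expect_equal(ann$position[match(c("A", "B", "C"), ann$label)],
               c(0, 0.5, 1))
  # degenerate: all-equal QC maps to mid-scale
  flat <- tree_with_qc(tr, c(A = 5, B = 5, C = 5))
  expect_equal(tidy(flat)$position, rep(0.5, 3))
  expect_error(tree_with_qc(tr, c(A = 1, B = 2)), "C")
})

test_that("annotated Newick embeds QC comments and writes the sidecar", {
  m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  qct <- tree_with_qc(upgma(m), c(A = 10, B = 20, C = 30))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_annotated_newick(qct, f)
  nwk <- readLines(f)
  expect_match(nwk, "A\\[&qc=10,scale=0\\]:1", fixed = FALSE)
  expect_match(nwk, "C\\[&qc=30,scale=1\\]:4")
  sidecar <- utils::read.delim(paste0(f, ".qc.tsv"))
  expect_equal(sidecar$label, c("A", "B", "C"))
  expect_equal(sidecar$qc, c(10, 20, 30))
  # stripping the comments leaves a standard parseable Newick tree
  plain <- gsub("\\[[^]]*\\]", "", nwk)
  expect_equal(ape::write.tree(ape::read.tree(text = plain)),
               "((A:1,B:1):3,C:4);")
})
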