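# NJ trees with bootstrap and UPGMA dendrograms

# four 100-nt taxa engineered so p-distances are exactly additive on the
# tree ((A:0.05,B:0.10):0.05,(C:0.15,D:0.20))
make_additive_quartet <- function() {
  L <- 100
  base <- strsplit(random_dna(L, 61), "")[[1]]
  seqs <- list(A = base, B = base, C = base, D = base)
  alt <- function(b) if (b == "A") "C" else "A"
  slots <- split(1:55, rep(1:5, times = c(5, 10, 15, 20, 5)))
  for (i in slots[[1]]) seqs$A[i] <- alt(base[i])
  for (i in slots[[2]]) seqs$B[i] <- alt(base[i])
  for (i in slots[[3]]) seqs$C[i] <- alt(base[i])
  for (i in slots[[4]]) seqs$D[i] <- alt(base[i])
  for (i in slots[[5]]) { seqs$A[i] <- alt(base[i]); seqs$B[i] <- alt(base[i]) }
  vapply(seqs, paste, character(1), collapse = "")
}

test_that("NJ recovers an additive quartet exactly", {
  seqs <- make_additive_quartet()
  tree <- build_nj_tree(seqs, n_bootstrap = 100, seed = 1)
  # oracle: four-point condition names the cherry
  d <- matrix(0, 4, 4, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:4) for (j in 1:4)
    d[i, j] <- longread16S:::hamming(seqs[[i]], seqs[[j]]) / 100
  expect_identical(oracle_nj_split(d, names(seqs)), c("A", "B"))
  has_split <- function(tree, labs)
    any(vapply(tree_splits(tree), identical, logical(1), y = labs))
  expect_true(has_split(tree, c("A", "B")) || has_split(tree, c("C", "D")))
  # exact branch lengths for an additive matrix
  tips <- setNames(tree$edge.length[tree$edge[, 2] <= 4],
                   tree$tip.label[tree$edge[tree$edge[, 2] <= 4, 2]])
  expect_equal(tips[c("A", "B", "C", "D")],
               c(A = 0.05, B = 0.10, C = 0.15, D = 0.20), tolerance = 1e-9)
  internal <- tree$edge.length[tree$edge[, 2] > 4]
  expect_equal(internal[internal > 0], 0.05, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("three taxa give the closed-form star", {
  seqs <- c(A = strrep("A", 20), B = paste0(strrep("A", 18), "CC"),
            C = paste0("GGGG", strrep("A", 16)))
  d_ab <- 2 / 20; d_ac <- 4 / 20; d_bc <- 6 / 20
  tree <- build_nj_tree(seqs, n_bootstrap = 0)
  tips <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(tips[["A"]], (d_ab + d_ac - d_bc) / 2)
  expect_equal(tips[["B"]], (d_ab + d_bc - d_ac) / 2)
  expect_equal(tips[["C"]], (d_ac + d_bc - d_ab) / 2)
})

test_that("bootstrap supports are deterministic under a fixed seed", {
  seqs <- make_additive_quartet()
  t1 <- build_nj_tree(seqs, n_bootstrap = 200, seed = 42)
  t2 <- build_nj_tree(seqs, n_bootstrap = 200, seed = 42)
  expect_identical(t1$node.label, t2$node.label)
  # the root "node" of an unrooted tree carries no bipartition (NA support)
  sup <- t1$node.label[!is.na(t1$node.label)]
  expect_true(length(sup) >= 1 && all(sup >= 0 & sup <= 1))
  expect_error(build_nj_tree(seqs[1:2]), "at least 3")
})

test_that("UPGMA merge heights follow half-average linkage", {
  d <- matrix(c(0, 2, 8,
                2, 0, 8,
                8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  u <- upgma(d)
  expect_equal(u$heights, c(1, 4))
  # brute-force oracle over all possible first merges
  expect_equal(u$heights, oracle_upgma_heights(d))
  expect_setequal(u$top_split[[2]], "C")
})

test_that("UPGMA matches the naive oracle on random 5x5 matrices", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(stats::runif(25, 1, 10), 5, 5)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(letters[1:5], letters[1:5])
    expect_equal(upgma(d)$heights, oracle_upgma_heights(d),
                 tolerance = 1e-12)
  }
})

test_that("UPGMA degenerate inputs", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  u <- upgma(d)
  expect_true(all(abs(u$heights - 0.5) < 1e-12))   # all merges at d/2

  d0 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_equal(upgma(d0)$heights[1], 0)            # identical samples

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(bad), "symmetric")
})
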