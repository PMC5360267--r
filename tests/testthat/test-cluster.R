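test_that("average linkage reproduces forced small-case merges", {
  m2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- linkage_average(m2)
  expect_equal(t2$height, 0.3)

  m3 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- linkage_average(m3)
  expect_equal(sort(t3$height), c(0.1, 0.9))
})

test_that("average linkage matches a naive UPGMA oracle on random instances", {
  for (seed in 1:5) {
    n <- 8
    m <- withr::with_seed(seed, {
      x <- matrix(stats::runif(n * n), n)
      m <- (x + t(x)) / 2
      diag(m) <- 0
      m
    })
    dimnames(m) <- list(paste0("L", 1:n), paste0("L", 1:n))
    tree <- linkage_average(m)
    oracle <- naive_upgma(m)
    expect_equal(sort(tree$height), oracle$heights, tolerance = 1e-10)
    expect_equal(unname(as.matrix(stats::cophenetic(tree))),
      unname(oracle$coph), tolerance = 1e-10)
  }
})

test_that("malformed distance matrices are rejected", {
  bad <- matrix(c(0, 0.2, 0.5, 0), 2)
  expect_error(linkage_average(bad), "symmetric")
  nan <- matrix(c(0, NaN, NaN, 0), 2)
  expect_error(linkage_average(nan), "NA")
})

test_that("the Kelley penalty recovers planted cluster counts", {
  m3 <- blob_dist(c(3, 3, 3), seed = 1)
  t3 <- linkage_average(m3)
  res <- kelley_k(t3, m3)
  expect_equal(res$k, 3)
  expect_equal(res$k, naive_kelley(t3, m3))

  # note: with the scan starting at k = 2, the k = 2 cut never contains
  # between-blob distances, so a planted count of 2 is not recoverable;
  # planted counts >= 3 are.
  m4 <- blob_dist(c(4, 4, 4, 4), seed = 2)
  t4 <- linkage_average(m4)
  res4 <- kelley_k(t4, m4)
  expect_equal(res4$k, 4)
  expect_equal(res4$k, naive_kelley(t4, m4))
})

test_that("identical points give the degenerate smallest-k answer", {
  n <- 6
  m <- matrix(0, n, n, dimnames = list(paste0("L", 1:n), paste0("L", 1:n)))
  tree <- linkage_average(m)
  res <- kelley_k(tree, m)
  expect_equal(res$k, 2)
  expect_true(all(res$profile$spread == 0))
})

test_that("the penalty argmin is invariant to uniform distance rescaling", {
  m <- blob_dist(c(4, 3, 3), seed = 3)
  tree <- linkage_average(m)
  k1 <- kelley_k(tree, m)$k
  m2 <- m * 7.3
  k2 <- kelley_k(linkage_average(m2), m2)$k
  expect_equal(k1, k2)
})

test_that("merging to a target count is conservative and deterministic", {
  m <- blob_dist(c(2, 2, 2), within = 0.05, seed = 4)
  assign <- tibble::tibble(id = rownames(m), cluster = rep(1:3, each = 2))

  # identity when target equals current k
  same <- merge_to_target(assign, m, 3)
  expect_equal(same$cluster, assign$cluster)

  # forced minimum: clusters 1 and 2 closest
  m2 <- matrix(0.9, 6, 6)
  m2[1:2, 3:4] <- m2[3:4, 1:2] <- 0.2
  m2[lower.tri(m2)] <- t(m2)[lower.tri(m2)]
  diag(m2) <- 0
  dimnames(m2) <- dimnames(m)
  merged <- merge_to_target(assign, m2, 2)
  expect_equal(merged$cluster[1:4], rep(1L, 4))
  expect_equal(length(unique(merged$cluster)), 2)

  expect_error(merge_to_target(assign, m, 5), "between 1")
  expect_error(merge_to_target(assign, m, 0), "between 1")
})

test_that("many small clusters merge down with every ligand retained", {
  sizes <- rep(2, 17)
  m <- blob_dist(sizes, seed = 5)
  assign <- tibble::tibble(id = rownames(m),
    cluster = rep(seq_along(sizes), sizes))
  out <- merge_to_target(assign, m, 5)
  expect_equal(length(unique(out$cluster)), 5)
  expect_equal(sort(out$cluster), sort(match(out$cluster, unique(out$cluster))))
  expect_setequal(out$id, assign$id)
  expect_equal(nrow(attr(out, "merge_history")), 12)
})

test_that("the full clustering pipeline runs on a small chemotype library", {
  smis <- c(
    a1 = "CCO", a2 = "CCCO", a3 = "CCCCO",
    b1 = "c1ccccc1", b2 = "Cc1ccccc1", b3 = "CCc1ccccc1",
    c1 = "CC(=O)OC", c2 = "CCC(=O)OC", c3 = "CC(=O)OCC"
  )
  cl <- cluster_ligands(ligand_tbl(smis, role = "active"))
  expect_s3_class(cl, "ligand_clustering")
  expect_equal(nrow(tidy(cl)), 9)
  expect_true(all(tidy(cl)$cluster >= 1))
  g <- glance(cl)
  expect_equal(g$n, 9L)
  expect_equal(g$k, cl$k)
})
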