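test_that("ranking is score-ordered, tie-broken by id and order-invariant", {
  tab <- tibble::tibble(
    ligand_id = c("a", "d1", "d2"), score = c(-9, -5, -4),
    role = c("active", "decoy", "decoy")
  )
  r <- rank_table(tab)
  expect_equal(r$rank[r$ligand_id == "a"], 1L)

  tie <- tibble::tibble(
    ligand_id = c("zeta", "alpha"), score = c(-5, -5),
    role = c("decoy", "decoy")
  )
  expect_equal(rank_table(tie)$ligand_id, c("alpha", "zeta"))

  shuffled <- tab[c(3, 1, 2), ]
  expect_equal(rank_table(shuffled), rank_table(tab), ignore_attr = TRUE)
})

test_that("undocked ligands are dropped (reported) or sent to the bottom", {
  tab <- tibble::tibble(
    ligand_id = c("a", "b", "c"), score = c(-9, NA, -4),
    role = c("active", "decoy", "decoy"),
    docked = c(TRUE, FALSE, TRUE)
  )
  dropped <- rank_table(tab, undocked = "drop")
  expect_equal(nrow(dropped), 2)
  expect_equal(attr(dropped, "undocked")$ligand_id, "b")
  worst <- rank_table(tab, undocked = "worst")
  expect_equal(worst$rank[worst$ligand_id == "b"], 3L)
})

test_that("BEDROC hits its closed-form extremes", {
  expect_equal(bedroc(ranks = 1, N = 100, alpha = 20)$bedroc, 1,
    tolerance = 1e-3)
  expect_equal(bedroc(ranks = 100, N = 100, alpha = 20)$bedroc, 0,
    tolerance = 1e-3)
})

test_that("BEDROC equals naive summation on random configurations", {
  withr::local_seed(8)
  for (i in 1:200) {
    N <- sample(10:600, 1)
    n <- sample(1:min(8, N - 1), 1)
    ranks <- sample(N, n)
    got <- bedroc(ranks, N = N, alpha = 20)
    expect_equal(got$bedroc, naive_bedroc(ranks, n, N, 20),
      tolerance = 1e-9)
    expect_gte(got$bedroc, 0)
    expect_lte(got$bedroc, 1)
  }
})

test_that("worsening one active's rank strictly lowers BEDROC", {
  N <- 15
  cfgs <- utils::combn(N, 3)
  for (j in seq_len(ncol(cfgs))) {
    ranks <- cfgs[, j]
    b0 <- bedroc(ranks, N = N)$bedroc
    for (i in seq_along(ranks)) {
      worse <- setdiff((ranks[i] + 1):N, ranks)
      if (ranks[i] == N || !length(worse)) next
      r2 <- ranks
      r2[i] <- worse[1]
      expect_lt(bedroc(r2, N = N)$bedroc, b0)
    }
  }
})

test_that("degenerate active counts are explicit errors", {
  expect_error(bedroc(integer(0), N = 10), "n = 0")
  expect_error(bedroc(1:10, N = 10), "n = N")
  expect_error(bedroc(c(1, 1), N = 10), "distinct")
  expect_error(bedroc(11, N = 10), "1..N")
})

test_that("the exponential weight concentrates where alpha says it should", {
  expect_equal(contribution_fraction(20, 0), 0)
  expect_equal(contribution_fraction(20, 1), 1)
  expect_equal(contribution_fraction(3.7, 1), 1)
  x <- seq(0, 1, by = 0.05)
  expect_true(all(diff(contribution_fraction(20, x)) > 0))
  # alpha = 20: ~80% of the attainable score in the top 8%
  expect_equal(round(100 * contribution_fraction(20, 0.08)), 80)
})

test_that("shortlisting keeps top-k plus floor-passers and flags weak clusters", {
  withr::local_seed(2)
  weak <- tibble::tibble(
    model_id = sprintf("c3_m%02d_4k5y", 1:100), cluster_id = 3L,
    bedroc = stats::runif(100, 0.05, 0.42)
  )
  s <- shortlist_models(weak, top_k = 10, floor = 0.5)
  expect_equal(nrow(s), 10)
  expect_true(all(s$below_floor))
  expect_equal(attr(s, "cluster_status")$note, "no model selected")

  strong <- tibble::tibble(
    model_id = paste0("c1_m", 1:3, "_4oo9"), cluster_id = 1L,
    bedroc = c(0.8, 0.7, 0.6)
  )
  s2 <- shortlist_models(strong, top_k = 10, floor = 0.5)
  expect_equal(nrow(s2), 3)
  expect_false(any(s2$below_floor))

  expect_error(shortlist_models(strong[0, ]), "no enrichment results")
})

test_that("an exact-0.5 BEDROC respects the strictness switch", {
  res <- tibble::tibble(model_id = "m1", cluster_id = 1L, bedroc = 0.5)
  strict <- shortlist_models(res, top_k = 0, floor = 0.5, strict = TRUE)
  lax <- shortlist_models(res, top_k = 0, floor = 0.5, strict = FALSE)
  expect_true(attr(strict, "cluster_status")$below_floor)
  expect_equal(nrow(strict), 0)
  expect_false(attr(lax, "cluster_status")$below_floor)
  expect_equal(lax$model_id, "m1")
})

test_that("pose spread follows centroid arithmetic", {
  mk <- function(dx, dy = 0) list(atoms = tibble::tibble(
    elem = c("C", "C", "O"),
    x = c(0, 1, 2) + dx, y = c(0, 1, 0) + dy, z = c(0, 0, 0)
  ))
  expect_equal(pose_consistency(list(mk(0), mk(0))), 0)
  expect_equal(pose_consistency(list(mk(0), mk(2))), 2)
  # three centroids at an equilateral triangle with unit sides
  tri <- list(mk(0), mk(1), mk(0.5, sqrt(3) / 2))
  expect_equal(pose_consistency(tri), 1)
  expect_error(pose_consistency(list(mk(0))), "at least 2")
})
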