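# descriptor-only "actives" for planting tests
fake_active <- function(id, cluster = 1L, mw = 350, clogp = 2, hbd = 1,
                        hba = 3, rotb = 4, charge = 0L, fp = NULL) {
  tibble::tibble(
    id = id, role = "active", cluster_id = cluster, mw = mw, clogp = clogp,
    hbd = hbd, hba = hba, rotb = rotb, net_charge = charge,
    fp = list(if (is.null(fp)) sort(sample.int(2^20, 30)) else fp)
  )
}

test_that("property-matched, dissimilar candidates are eligible; twins are not", {
  withr::local_seed(11)
  act <- fake_active("A1", fp = 1:30)
  good <- tibble::tibble(
    id = "C1", role = "candidate", mw = act$mw, clogp = act$clogp,
    hbd = act$hbd, hba = act$hba, rotb = act$rotb,
    net_charge = act$net_charge, fp = list(c(1:6, 101:124)) # tanimoto 0.11
  )
  twin <- good
  twin$id <- "C2"
  twin$fp <- act$fp # tanimoto 1.0 -> over the dissimilarity ceiling
  ds <- match_decoys(act, dplyr::bind_rows(good, twin),
    match_spec(decoys_per_active = 5), seed = 1)
  expect_equal(ds$decoys$id, "C1")
})

test_that("planted pools are recovered deterministically per seed", {
  withr::local_seed(42)
  actives <- dplyr::bind_rows(
    fake_active("A1", mw = 320), fake_active("A2", mw = 380)
  )
  pool <- plant_candidates(actives, n_eligible = 7, n_background = 40,
    spec = match_spec(decoys_per_active = 5), seed = 7)
  ds1 <- match_decoys(actives, pool, match_spec(decoys_per_active = 5),
    seed = 17)
  ds2 <- match_decoys(actives, pool, match_spec(decoys_per_active = 5),
    seed = 17)
  ds3 <- match_decoys(actives, pool, match_spec(decoys_per_active = 5),
    seed = 18)

  # 5 of the 7 planted candidates per active, none from the background
  cnt <- table(ds1$decoys$matched_active)
  expect_equal(as.integer(cnt[c("A1", "A2")]), c(5L, 5L))
  expect_true(all(grepl("^plant_", ds1$decoys$id)))
  expect_identical(ds1$decoys, ds2$decoys)
  expect_false(identical(ds1$decoys$id, ds3$decoys$id))
})

test_that("every emitted decoy re-passes an exhaustive eligibility scan", {
  withr::local_seed(4)
  actives <- dplyr::bind_rows(
    fake_active("A1", cluster = 1L), fake_active("A2", cluster = 1L,
      mw = 360), fake_active("B1", cluster = 2L, mw = 500, clogp = 4)
  )
  spec <- match_spec(decoys_per_active = 10)
  pool <- dplyr::bind_rows(
    plant_candidates(actives, n_eligible = 6, n_background = 30, spec = spec,
      seed = 5),
    simulate_library(60, seed = 6)
  )
  pool <- pool[!duplicated(pool$id), ]
  ds <- match_decoys(actives, pool, spec, seed = 9)
  expect_gt(nrow(ds$decoys), 0)
  for (i in seq_len(nrow(ds$decoys))) {
    dec <- ds$decoys[i, ]
    act <- actives[actives$id == dec$matched_active, ]
    cl_act <- actives[actives$cluster_id == dec$cluster_id, ]
    expect_true(decoy_is_eligible(dec, act, cl_act, spec))
  }
  expect_false(any(ds$decoys$id %in% actives$id))
  expect_false(anyDuplicated(ds$decoys$id) > 0)
})

test_that("zero-match specs warn and return empty, not error", {
  act <- fake_active("A1", fp = 1:30)
  far <- tibble::tibble(
    id = "C1", role = "candidate", mw = act$mw + 500, clogp = act$clogp,
    hbd = act$hbd, hba = act$hba, rotb = act$rotb,
    net_charge = act$net_charge, fp = list(200:229)
  )
  expect_warning(ds <- match_decoys(act, far, match_spec(), seed = 1),
    "zero decoys|no eligible")
  expect_equal(nrow(ds$decoys), 0)
})

test_that("merged decoy sets report the documented ratio strings", {
  actives <- purrr::map_dfr(1:6, function(i) fake_active(paste0("A", i),
    cluster = 5L))
  decoys <- tibble::tibble(
    id = paste0("D", 1:87), role = "decoy", cluster_id = 5L,
    matched_active = "A1"
  )
  ds <- ligsel:::new_decoy_set(decoys, actives, match_spec(), seed = 1)
  inact <- tibble::tibble(id = paste0("I", 1:2500), cluster_id = 5L)
  merged <- merge_decoy_sets(ds, inact)
  # 6 actives vs 2587 decoys -> 1:431
  expect_equal(nrow(merged$decoys), 2587)
  expect_equal(merged$ratios$ratio, "1:431")
})

test_that("duplicate ids across decoy sources are kept once", {
  actives <- fake_active("A1")
  decoys <- tibble::tibble(id = c("D1", "D2"), role = "decoy",
    cluster_id = 1L)
  ds <- ligsel:::new_decoy_set(decoys, actives, match_spec(), seed = 1)
  merged <- merge_decoy_sets(ds, tibble::tibble(id = c("D2", "I1"),
    cluster_id = 1L))
  expect_equal(sort(merged$decoys$id), c("D1", "D2", "I1"))
  expect_equal(merged$decoys$role[merged$decoys$id == "D2"], "decoy")
})

test_that("clusters without decoys get a degenerate 1:0 ratio and warning", {
  actives <- purrr::map_dfr(1:10, function(i) fake_active(paste0("A", i)))
  expect_warning(
    ds <- ligsel:::new_decoy_set(actives[0, c("id", "role", "cluster_id")],
      actives, match_spec(), seed = 1),
    "zero decoys"
  )
  expect_equal(ds$ratios$ratio, "1:0")
})
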