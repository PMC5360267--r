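# minimal hand-built complexes
one_residue_model <- function(dist, resid = "LEU", elety = "CD1") {
  structure_model(tibble::tibble(
    chain = "A", resno = 1L, resid = resid, elety = elety,
    x = 0, y = 0, z = dist
  ), model_id = "toy")
}
one_atom_pose <- function() {
  ligand_pose(tibble::tibble(
    elem = c("C", "C", "C"), x = c(0, -1.5, -3), y = 0, z = 0, charge = 0L
  ), bonds = tibble::tibble(a1 = 1:2, a2 = 2:3, order = 1))
}

test_that("the 4 A contact boundary is inclusive", {
  pose <- one_atom_pose()
  expect_equal(nrow(contacts(one_residue_model(3.9), pose)), 1)
  expect_equal(nrow(contacts(one_residue_model(4.0), pose)), 1)
  expect_equal(nrow(contacts(one_residue_model(4.1), pose)), 0)
})

test_that("a residue cage is fully recovered by the contact scan", {
  rec <- pocket_recipe(rep("hydrophobic", 6), distance = rep(3.4, 6))
  pk <- build_pocket(rec)
  con <- contacts(pk$model, pk$pose, cutoff = 4)
  expect_equal(nrow(con), 6)
  # brute-force all-pairs distance oracle
  pat <- pk$model$atoms
  lat <- pk$pose$atoms[pk$pose$atoms$elem != "H", ]
  mind <- sapply(split(pat, pat$residue_key), function(r) {
    min(sapply(seq_len(nrow(r)), function(i) {
      sqrt((r$x[i] - lat$x)^2 + (r$y[i] - lat$y)^2 + (r$z[i] - lat$z)^2)
    }))
  })
  expect_setequal(con$residue_key, names(mind)[mind <= 4])
  expect_equal(con$min_dist, unname(mind[con$residue_key]), tolerance = 1e-9)
})

test_that("a constructed serine hydrogen bond sets exactly the planted bits", {
  # ligand N(+)-H aimed at OG, 2.9 A heavy-heavy, angle 180
  pk <- build_pocket(pocket_recipe("hbond_donor", distance = 2.9))
  bits <- sift_bits(pk$model, pk$pose)
  expect_true(bits$any_contact && bits$side_chain && bits$polar &&
    bits$hbond_donor)
  expect_false(bits$backbone || bits$hydrophobic || bits$hbond_acceptor ||
    bits$aromatic || bits$charged)
})

test_that("a hydrophobic side-chain contact sets only contact bits", {
  pk <- build_pocket(pocket_recipe("hydrophobic", distance = 3.8))
  bits <- sift_bits(pk$model, pk$pose)
  expect_true(bits$any_contact && bits$side_chain && bits$hydrophobic)
  expect_false(bits$polar || bits$backbone || bits$hbond_donor ||
    bits$hbond_acceptor || bits$aromatic || bits$charged)
})

test_that("a bad D-H...A angle suppresses the hydrogen bond but not contact", {
  model <- structure_model(tibble::tibble(
    chain = "A", resno = 1L, resid = "SER",
    elety = c("OG", "CB"), x = c(0, 0), y = c(0, 0), z = c(3.4, 4.9)
  ), model_id = "toy")
  # donor N at origin, H perpendicular to the N...OG axis: angle ~74 deg
  pose <- ligand_pose(tibble::tibble(
    elem = c("N", "H", "C", "C"), x = c(0, 1, 0, 0), y = c(0, 0, 1.4, 2.8),
    z = 0, charge = c(1L, 0L, 0L, 0L)
  ), bonds = tibble::tibble(a1 = c(1, 1, 3), a2 = c(2, 3, 4), order = 1))
  bits <- sift_bits(model, pose)
  expect_true(bits$any_contact && bits$polar && bits$side_chain)
  expect_false(bits$hbond_donor)
})

test_that("profiles count ligands, not rows", {
  pk <- build_pocket(pocket_recipe(c("hydrophobic", "polar")))
  b1 <- sift_bits(pk$model, pk$pose)
  prof <- sift_profile(b1)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$freq, c(1, 1))
  expect_true(all(prof$retained))

  # second ligand contacting only residue 1 halves one frequency
  b2 <- b1[1, ]
  b2$ligand_id <- "lig2"
  prof2 <- sift_profile(dplyr::bind_rows(b1, b2))
  expect_equal(sort(prof2$freq), c(0.5, 1))
  expect_false(prof2$retained[prof2$freq == 0.5]) # strict > 0.5
})

test_that("profiles are invariant to ligand order and match a brute recount", {
  store <- purrr::map_dfr(1:4, function(i) {
    rec <- random_pocket_recipe(5, seed = i,
      intents = c("hydrophobic", "polar", "backbone", "none"))
    b <- sift_bits(build_pocket(rec)$model, build_pocket(rec)$pose)
    b$ligand_id <- paste0("lig", i)
    b
  })
  p1 <- sift_profile(store)
  p2 <- sift_profile(store[sample(nrow(store)), ])
  expect_equal(as.data.frame(p1), as.data.frame(p2))
  oracle <- recount_profile(store)
  expect_equal(p1$freq, oracle$freq[match(p1$position, oracle$position)])
})

test_that("pooled frequencies equal the ligand-count-weighted subset mean", {
  withr::local_seed(31)
  mk_bits <- function(lig, positions) {
    tibble::tibble(
      position = positions, any_contact = TRUE, ligand_id = lig,
      model_id = "m1"
    )
  }
  all_pos <- paste0("p", 1:6)
  setA <- purrr::map_dfr(paste0("a", 1:3), function(l) {
    mk_bits(l, sample(all_pos, 4))
  })
  setB <- purrr::map_dfr(paste0("b", 1:5), function(l) {
    mk_bits(l, sample(all_pos, 3))
  })
  fA <- sift_profile(setA, cutoff = 0)
  fB <- sift_profile(setB, cutoff = 0)
  pooled <- sift_profile(dplyr::bind_rows(setA, setB), cutoff = 0)
  for (p in pooled$position) {
    a <- ifelse(p %in% fA$position, fA$freq[fA$position == p], 0)
    b <- ifelse(p %in% fB$position, fB$freq[fB$position == p], 0)
    expect_equal(pooled$freq[pooled$position == p], (3 * a + 5 * b) / 8)
  }
})

test_that("named profile presets slice the bit store as documented", {
  withr::local_seed(5)
  final_models <- c(
    "c1_m1_1u19", "c1_m2_4oo9", "c2_m1_4oo9", "c2_m2_4oo9",
    "c4_m1_4or2", "c4_m2_4or2", "c5_m1_4oo9", "c5_m2_4oo9"
  )
  store <- purrr::map_dfr(final_models, function(m) {
    cl <- as.integer(sub("^c([0-9]+).*", "\\1", m))
    purrr::map_dfr(1:3, function(i) {
      tibble::tibble(
        position = sample(paste0("p", 1:8), 4), any_contact = TRUE,
        ligand_id = paste0("c", cl, "_lig", i), model_id = m, cluster_id = cl
      )
    })
  })
  all8 <- profile_subset(store, "sift8", cutoff = 0)
  expect_equal(as.data.frame(all8), as.data.frame(sift_profile(store,
    cutoff = 0)), ignore_attr = TRUE)
  # cluster-4 preset is the mGlu1-template preset under a different name
  c4 <- profile_subset(store, "sift_c4", cutoff = 0)
  or2 <- profile_subset(store, "sift_4or2", cutoff = 0)
  expect_equal(c4$freq, or2$freq)
  expect_equal(c4$position, or2$position)
  # the class C-only profile drops the rhodopsin-based model's ligands
  s7 <- profile_subset(store, "sift7", cutoff = 0)
  expect_equal(attr(s7, "n_ligands"), 21L)
  expect_error(profile_subset(store[0, ], "sift8"), "no ligands")
})

test_that("grid-box membership follows cube geometry", {
  model <- one_residue_model(0, resid = "SER", elety = "OG")
  box <- grid_box(model, resno = 1, outer = 25, inner = 10)
  shift_pose <- function(dx) ligand_pose(tibble::tibble(
    elem = "C", x = c(0, 1.2, -1.2) + dx, y = c(0, 0.8, 0.8), z = 0,
    charge = 0L
  ))
  expect_true(box_check(shift_pose(0), box)$inside)
  expect_true(box_check(shift_pose(4.9), box)$inside)
  expect_false(box_check(shift_pose(6), box)$inside)
  expect_error(grid_box(model, resno = 99), "not found")
})

test_that("box membership is invariant under joint rigid translation", {
  pk <- build_pocket(pocket_recipe(c("hydrophobic", "polar")))
  box <- grid_box(pk$model, resno = 1, outer = 30, inner = 10)
  r1 <- box_check(pk$pose, box)
  shift <- c(11.3, -4.2, 7.7)
  m2 <- pk$model
  m2$atoms$x <- m2$atoms$x + shift[1]
  m2$atoms$y <- m2$atoms$y + shift[2]
  m2$atoms$z <- m2$atoms$z + shift[3]
  p2 <- pk$pose
  p2$atoms$x <- p2$atoms$x + shift[1]
  p2$atoms$y <- p2$atoms$y + shift[2]
  p2$atoms$z <- p2$atoms$z + shift[3]
  box2 <- grid_box(m2, resno = 1, outer = 30, inner = 10)
  expect_equal(box_check(p2, box2)$inside, r1$inside)
})

test_that("complexes round-trip through PDB + SDF files", {
  pk <- build_pocket(pocket_recipe(c("hydrophobic", "polar", "backbone")))
  dir <- withr::local_tempdir()
  paths <- write_pocket(pk, dir, "toy")
  cx <- read_complex(paths["protein"], paths["ligand"])
  expect_equal(dplyr::n_distinct(cx$model$atoms$residue_key), 3)
  expect_equal(sum(cx$pose$atoms$elem != "H"),
    sum(pk$pose$atoms$elem != "H"))
  expect_error(read_complex(file.path(dir, "missing.pdb"), paths["ligand"]),
    "not found")
})

test_that("alternate locations collapse to conformer A", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA ASER A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA BSER A   1       1.700   0.000   0.000  1.00  0.00           C",
    "END"
  ), pdb)
  mod <- read_protein(pdb)
  expect_equal(nrow(mod$atoms), 2)
  expect_equal(mod$atoms$x[mod$atoms$elety == "CA"], 1.5)
})

test_that("unknown residue names warn but still produce a fingerprint", {
  model <- one_residue_model(3.5, resid = "XYZ", elety = "C1")
  expect_warning(bits <- sift_bits(model, one_atom_pose()), "unknown residue")
  expect_true(bits$any_contact)
  expect_true(bits$side_chain)
})

test_that("bit implications hold on fuzzed pockets", {
  for (seed in 1:10) {
    rec <- random_pocket_recipe(sample(2:9, 1), seed = seed)
    pk <- build_pocket(rec, jitter = 0.15, seed = seed)
    bits <- sift_bits(pk$model, pk$pose)
    if (!nrow(bits)) next
    expect_true(all(bits$any_contact))
    expect_true(all(!bits$backbone | bits$any_contact))
    expect_true(all(!bits$side_chain | bits$any_contact))
  }
})
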