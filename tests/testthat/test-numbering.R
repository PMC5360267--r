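test_that("anchors label themselves .50x50 and offsets count from them", {
  map <- numbering_map(tibble::tibble(
    helix = 3L, anchor = 574L, start = 555L, end = 578L
  ))
  labs <- numbering_labels(map)
  expect_equal(labs$label[labs$resno == 574], "3.50x50")
  # ten residues before the TM3 anchor: the grid-box centring position
  expect_equal(labs$label[labs$resno == 564], "3.40x40")
})

test_that("bulge corrections shift only the x-part", {
  map <- numbering_map(
    tibble::tibble(helix = 1L, anchor = 10L, start = 5L, end = 15L),
    x_corrections = tibble::tibble(resno = 12L, x = 53L)
  )
  labs <- numbering_labels(map)
  expect_equal(labs$label[labs$resno == 12], "1.52x53")
  expect_equal(labs$label[labs$resno == 11], "1.51x51")
})

test_that("labelling is a bijection over the spans", {
  fx <- table1_fixture()
  for (map in fx$numbering) {
    labs <- numbering_labels(map)
    expect_false(anyDuplicated(labs$label) > 0)
    expect_false(anyDuplicated(labs$resno) > 0)
    # round trip label -> residue -> label
    idx <- match(labs$label, labs$label)
    expect_equal(labs$label[idx], labs$label)
  }
})

test_that("all tabulated positions resolve on fixture numbering maps", {
  fx <- table1_fixture()
  for (r in unique(fx$residues$receptor)) {
    labs <- numbering_labels(fx$numbering[[r]])
    res <- fx$residues[fx$residues$receptor == r, ]
    hit <- match(res$position, labs$label)
    expect_false(anyNA(hit))
    expect_equal(labs$resno[hit], res$resno)
  }
})

test_that("generic numbers cross-map between receptors", {
  fx <- table1_fixture()
  row650 <- cross_map(fx$registries, "6.50x50")
  expect_equal(row650$residue, c("C703", "W798", "W785"))
  row340 <- cross_map(fx$registries, "3.40x40")
  expect_equal(row340$residue, c("Y564", "S668", "P655"))
  expect_error(cross_map(fx$registries, "9.99x99"), "absent")
})

test_that("invalid maps are rejected", {
  expect_error(numbering_map(tibble::tibble(
    helix = 1L, anchor = 20L, start = 5L, end = 15L
  )), "anchor outside")
  expect_error(numbering_map(tibble::tibble(
    helix = c(1L, 2L), anchor = c(10L, 14L), start = c(5L, 12L),
    end = c(15L, 20L)
  )), "overlapping")
})

test_that("anchor YAML round-trips and numbers a model", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "helices:",
    "  3:",
    "    anchor_index: 574",
    "    span: [555, 578]",
    "  7:",
    "    anchor_index: 742",
    "    span: [720, 745]",
    "    x_corrections:",
    "      723: 32",
    "      724: 33"
  ), yml)
  map <- read_anchors(yml)
  labs <- numbering_labels(map)
  expect_equal(labs$label[labs$resno == 723], "7.31x32")

  model <- structure_model(tibble::tibble(
    chain = "A", resno = c(564L, 574L, 600L, 742L), resid = "ALA",
    elety = "CA", x = c(0, 5, 10, 15), y = 0, z = 0
  ))
  numbered <- assign_numbers(model, map)
  expect_equal(
    numbered$atoms$position[numbered$atoms$resno == 564], "3.40x40")
  # loop residues outside every span stay unlabeled
  expect_true(is.na(numbered$atoms$position[numbered$atoms$resno == 600]))
  bad_map <- numbering_map(tibble::tibble(
    helix = 1L, anchor = 999L, start = 990L, end = 1000L
  ))
  expect_error(assign_numbers(model, bad_map), "absent from model")
})

test_that("unlabeled residues keep raw keys in SIFt output", {
  pk <- build_pocket(pocket_recipe(c("hydrophobic", "polar")))
  map <- numbering_map(tibble::tibble(
    helix = 3L, anchor = 1L, start = 1L, end = 1L
  ))
  model <- assign_numbers(pk$model, map)
  bits <- sift_bits(model, pk$pose)
  expect_equal(sort(bits$position), c("3.50x50", "A:2"))
})
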