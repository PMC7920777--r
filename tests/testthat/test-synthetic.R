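test_that("simulated trees are binary, positive, and seed-deterministic", {
  st <- simulate_tree(50, seed = 1)
  expect_equal(length(st$tree$tip.label), 50L)
  expect_equal(nrow(st$tree$edge), 98L)  # 2n - 2 branches
  expect_true(all(st$tree$edge.length > 0))
  st2 <- simulate_tree(50, seed = 1)
  expect_identical(ape::write.tree(st$tree), ape::write.tree(st2$tree))
  st3 <- simulate_tree(50, seed = 2)
  expect_false(identical(ape::write.tree(st$tree), ape::write.tree(st3$tree)))
  expect_error(simulate_tree(2), "at least 3")
})

test_that("planted edits scale exactly the branches they claim", {
  base <- simulate_tree(40, seed = 6)
  edited <- simulate_tree(40, seed = 6, paleo = 20, neo = list(size = 5, m = 0.05))
  term <- function(tr, tip) {
    tr$edge.length[tr$edge[, 2] == which(tr$tip.label == tip)]
  }
  relict <- edited$truth$relict_tip
  expect_length(relict, 1L)
  expect_equal(term(edited$tree, relict), 20 * term(base$tree, relict))
  expect_gte(length(edited$truth$neo_tips), 2L)
  for (tip in edited$truth$neo_tips) {
    expect_equal(term(edited$tree, tip), 0.05 * term(base$tree, tip))
  }
  expect_error(simulate_tree(10, seed = 1, neo = list(size = 10, m = 0.1)),
               "radiation size")
})

test_that("planted endemics fill their blocks and absent taxa are rescued", {
  st <- simulate_tree(20, seed = 3, paleo = 20)
  scn <- scenario(n_taxa = 20, n_rows = 6, n_cols = 6, p_bg = 0,
                  paleo_block = list(rows = 1:2, cols = 1:2), neo_block = NULL)
  ls <- simulate_landscape(st, scn, seed = 4)
  X <- ls$presence$incidence
  relict <- st$truth$relict_tip
  expect_equal(sort(rownames(X)[X[, relict] == 1L]),
               sort(ls$truth$paleo_cells))
  expect_equal(unname(colSums(X)[relict]), 4L)  # exactly the 2x2 block
  other <- setdiff(colnames(X), relict)
  expect_true(all(colSums(X)[other] == 1L))     # rescued into one cell each
})

test_that("saturated occupancy gives the symmetric endemism value", {
  st <- simulate_tree(12, seed = 5)
  scn <- scenario(n_taxa = 12, n_rows = 4, n_cols = 4, p_bg = 1,
                  paleo_block = NULL, neo_block = NULL)
  ls <- simulate_landscape(st, scn, seed = 6)
  expect_true(all(ls$presence$incidence == 1L))
  expect_equal(unname(weighted_endemism(ls$presence)), rep(12 / 16, 16))
})

test_that("scenario validation rejects out-of-bounds blocks", {
  expect_error(scenario(n_rows = 4, n_cols = 4,
                        paleo_block = list(rows = 5, cols = 1)), "bounds")
  expect_error(scenario(p_bg = 1.5))
})

test_that("emitted occurrence points round-trip through cleaning and binning", {
  st <- simulate_tree(15, seed = 9)
  scn <- scenario(n_taxa = 15, n_rows = 5, n_cols = 5, p_bg = 0.2,
                  paleo_block = NULL, neo_block = NULL)
  ls <- simulate_landscape(st, scn, seed = 10)
  rec <- simulate_occurrences(ls$presence, seed = 11, corrupt_frac = 0.1)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rec, path, row.names = FALSE)
  occ <- suppressMessages(read_occurrences(path))
  expect_gt(nrow(occ), sum(ls$presence$incidence))  # corrupt rows appended
  cl <- clean_occurrences(occ)
  expect_true(all(cl$rejected$reason %in% c("zero coordinate", "missing coordinate")))
  back <- rasterize_presence(cl$records, ls$presence$grid)
  expect_identical(back$incidence, ls$presence$incidence)
})

test_that("bioregion blocks confine their clades up to background noise", {
  st <- simulate_tree(30, seed = 12)
  blocks <- list(list(rows = 1:3, cols = 1:6), list(rows = 4:6, cols = 1:6))
  scn <- scenario(n_taxa = 30, n_rows = 6, n_cols = 6, p_bg = 0,
                  paleo_block = NULL, neo_block = NULL,
                  bioregion_blocks = blocks, p_within = 0.8)
  ls <- simulate_landscape(st, scn, seed = 13)
  X <- ls$presence$incidence
  reg <- ls$truth$region_of_cell[rownames(X)]
  for (g in 1:2) {
    gt <- intersect(ls$truth$region_taxa[[g]], colnames(X))
    # with zero background noise, clade g occurs only inside block g
    expect_true(all(X[which(reg != g), gt] == 0L))
  }
})
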