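write_occ_csv <- function(df, eol = "\n", path = tempfile(fileext = ".csv")) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(colnames(df), collapse = ","),
             apply(df, 1L, paste, collapse = ","))
  writeLines(lines, con, sep = eol)
  path
}

test_that("reading keeps every row and defers unparseable coordinates", {
  df <- data.frame(species = c("Aa bb", "Cc dd", "Ee ff"),
                   decimalLatitude = c("19.1", "18.5", "20.0"),
                   decimalLongitude = c("110.1", "NA", "109.3"))
  p <- write_occ_csv(df)
  rec <- suppressMessages(read_occurrences(p))
  expect_equal(nrow(rec), 3L)
  expect_true(is.na(rec$lon[2]))   # "NA" retained as missing, not dropped
  expect_equal(rec$taxon, df$species)
  expect_error(suppressMessages(read_occurrences(p, taxon_col = "nope")), "nope")
  expect_error(suppressMessages(read_occurrences(tempfile())), "not found")
})

test_that("CRLF line endings and quoted taxon names parse identically", {
  df <- data.frame(species = c("\"Aa bb\"", "\"Cc dd\""),
                   decimalLatitude = c("19.1", "18.5"),
                   decimalLongitude = c("110.1", "109.2"))
  lf <- suppressMessages(read_occurrences(write_occ_csv(df, "\n")))
  crlf <- suppressMessages(read_occurrences(write_occ_csv(df, "\r\n")))
  attr(lf, "row.names") <- attr(crlf, "row.names")
  lf$source <- crlf$source <- NULL
  expect_identical(lf, crlf)
})

test_that("cleaning drops zero/missing coordinates and logs reasons", {
  rec <- data.frame(taxon = c("a", "b", "c", "d"),
                    lon = c(110.1, 110.1, NA, 109.5),
                    lat = c(0, 19.2, 18.1, 18.9))
  cl <- clean_occurrences(rec)
  expect_equal(nrow(cl$records), 2L)
  expect_equal(cl$rejected$reason, c("zero coordinate", "missing coordinate"))
  expect_equal(cl$records$taxon, c("b", "d"))  # survivor order preserved
})

test_that("cleaning rejects records outside the boundary", {
  sq <- boundary(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  set.seed(42)
  inside <- data.frame(taxon = sprintf("in%d", 1:7),
                       lon = runif(7, 1, 9), lat = runif(7, 1, 9))
  outside <- data.frame(taxon = sprintf("out%d", 1:3),
                        lon = c(15, -2, 11), lat = c(5, 5, 12))
  cl <- clean_occurrences(rbind(inside, outside), sq)
  expect_equal(nrow(cl$records), 7L)
  expect_equal(cl$rejected$reason, rep("outside boundary", 3L))
  expect_error(clean_occurrences(inside, "not a boundary"), "boundary")
})

test_that("point-in-boundary agrees with an independent implementation", {
  skip_if_not_installed("sp")
  set.seed(7)
  ring <- cbind(c(0, 4, 6, 3, 1), c(0, -1, 3, 5, 2))  # irregular pentagon
  b <- boundary(ring)
  x <- runif(300, -2, 8); y <- runif(300, -2, 6)
  ours <- point_in_boundary(x, y, b)
  theirs <- sp::point.in.polygon(x, y, ring[, 1], ring[, 2]) > 0
  expect_equal(ours, theirs)
})

test_that("grid construction counts cells and honors a boundary", {
  g <- build_grid(extent = c(0, 100e3, 0, 50e3), cell_size = 10e3)
  expect_equal(nrow(g$cells), 50L)
  expect_equal(c(g$n_rows, g$n_cols), c(5L, 10L))
  left <- boundary(cbind(c(0, 50e3, 50e3, 0), c(0, 0, 50e3, 50e3)))
  gb <- build_grid(extent = c(0, 100e3, 0, 50e3), bnd = left, cell_size = 10e3)
  expect_equal(nrow(gb$cells), 25L)  # only cells overlapping the left half
  expect_warning(build_grid(extent = c(0, 5e3, 0, 5e3), cell_size = 10e3),
                 "single cell")
  expect_error(build_grid(extent = c(0, 0, 0, 10), cell_size = 10), "degenerate")
})

test_that("half-open cell assignment puts an edge point in exactly one cell", {
  g <- build_grid(extent = c(0, 30e3, 0, 30e3), cell_size = 10e3)
  rec <- data.frame(taxon = "a", lon = 10e3, lat = 5e3)  # on the c0/c1 edge
  x <- rasterize_presence(rec, g)
  expect_equal(rownames(x$incidence), "r0_c1")  # edge goes to the larger index
  expect_equal(sum(x$incidence), 1L)
})

test_that("rasterization collapses duplicates and matches hand enumeration", {
  g <- build_grid(extent = c(0, 30e3, 0, 10e3), cell_size = 10e3)
  dup <- data.frame(taxon = rep("A", 5), lon = runif(5, 0, 10e3), lat = runif(5, 0, 10e3))
  x <- rasterize_presence(dup, g)
  expect_equal(sum(x$incidence), 1L)
  expect_equal(unname(taxon_ranges(x)), 1L)

  mk <- function(taxon, cell) {  # cell centers of r0_c0..r0_c2
    data.frame(taxon = taxon, lon = cell * 10e3 + 5e3, lat = 5e3)
  }
  rec <- rbind(mk("A", 0), mk("B", 0), mk("B", 1), mk("C", 1), mk("D", 1),
               mk("C", 2), mk("D", 2))
  x <- rasterize_presence(rec, g)
  expect_equal(unname(taxon_ranges(x)[c("A", "B", "C", "D")]), c(1L, 2L, 2L, 2L))
  expect_equal(unname(taxon_richness(x)), c(2L, 3L, 2L))
  # binning is invariant to record order
  x2 <- rasterize_presence(rec[sample(nrow(rec)), ], g)
  expect_identical(x$incidence, x2$incidence)
  expect_error(rasterize_presence(rec[0, ], g), "no occurrence records")
})

test_that("records outside the grid are skipped with a warning", {
  g <- build_grid(extent = c(0, 20e3, 0, 10e3), cell_size = 10e3)
  rec <- data.frame(taxon = c("a", "b"), lon = c(5e3, 25e3), lat = c(5e3, 5e3))
  expect_warning(x <- rasterize_presence(rec, g), "outside the grid")
  expect_equal(nrow(x$skipped), 1L)
  expect_equal(sum(x$incidence), 1L)
})
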