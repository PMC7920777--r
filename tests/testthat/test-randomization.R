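test_that("structured replicates preserve both marginals exactly", {
  set.seed(5)
  X <- matrix(rbinom(200, 1L, 0.3), 10, 20,
              dimnames = list(sprintf("c%d", 1:10), sprintf("t%d", 1:20)))
  X[rowSums(X) == 0L, 1L] <- 1L
  sims <- null_ensemble(X, n_rand = 20, seed = 1)
  for (r in 1:20) {
    expect_identical(rowSums(sims[, , r]), rowSums(X))
    expect_identical(colSums(sims[, , r]), colSums(X))
  }
  # pluggable sequential sampler obeys the same contract
  sims2 <- null_ensemble(X, n_rand = 5, seed = 1, method = "tswap")
  for (r in 1:5) expect_identical(colSums(sims2[, , r]), colSums(X))
})

test_that("a swap-free matrix is returned unchanged with a warning", {
  ones <- matrix(1L, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3]))
  expect_warning(out <- shuffle_structured(ones, seed = 1), "no checkerboard")
  expect_identical(out, ones)
})

test_that("a 2x2 checkerboard unit swaps between its two configurations", {
  id <- diag(2L)
  storage.mode(id) <- "integer"
  dimnames(id) <- list(c("c1", "c2"), c("t1", "t2"))
  got <- shuffle_structured(id, seed = 3)
  anti <- 1L - id
  dimnames(anti) <- dimnames(id)
  expect_true(identical(got, id) || identical(got, anti))
  expect_identical(rowSums(got), rowSums(id))
})

test_that("empirical quantiles follow the half-tie convention", {
  expect_equal(empirical_quantile(5, rep(1, 999)), 1.0)       # above all nulls
  expect_equal(empirical_quantile(2, rep(2, 999)), 0.5)       # all ties
  expect_equal(empirical_quantile(3.5, c(1, 2, 3, 4)), 0.75)  # count below
  expect_equal(empirical_quantile(c(1, 4), rbind(c(2, 3), c(2, 3))), c(0, 1))
  expect_error(empirical_quantile(1, numeric(0)))
})

test_that("identical seeds give identical significance results", {
  lnd <- random_landscape(12, 15, seed = 8)
  s1 <- significance_test(lnd$x, lnd$tree, n_rand = 49, seed = 99)
  s2 <- significance_test(lnd$x, lnd$tree, n_rand = 49, seed = 99)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  s3 <- significance_test(lnd$x, lnd$tree, n_rand = 49, seed = 100)
  expect_false(identical(s1$q, s3$q))
  expect_error(significance_test(lnd$x, lnd$tree, n_rand = 10, seed = 1),
               "at least 19")
})

test_that("richness is marginal-determined: its quantile is always 0.5", {
  lnd <- random_landscape(10, 12, seed = 11)
  sig <- significance_test(lnd$x, lnd$tree, n_rand = 49, seed = 2)
  qm <- attr(sig, "q_matrix")
  expect_true(all(qm[, "TR"] == 0.5))
})

test_that("a unique long-branch point endemic maxes out its PE quantile", {
  # one taxon carries nearly all tree length and occurs alone in a single
  # richness-1 refuge cell of a large landscape: a null replicate places it
  # there with probability ~ 1/fill, and any replicate without it falls far
  # short of the observed concentration of unique branch length
  set.seed(13)
  tr <- ape::rtree(50, tip.label = sprintf("t%02d", 1:50))
  tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "t01")] <- 1000
  X <- matrix(rbinom(100 * 50, 1L, 0.2), 100, 50,
              dimnames = list(sprintf("c%03d", 1:100), sprintf("t%02d", 1:50)))
  X[, "t01"] <- 0L
  X[1L, ] <- 0L
  X[1L, "t01"] <- 1L                    # the refuge cell holds only the relict
  X[rowSums(X) == 0L, "t02"] <- 1L
  x <- presence_matrix(X)
  sig <- significance_test(x, tr, n_rand = 199, seed = 4)
  qm <- attr(sig, "q_matrix")
  expect_equal(unname(qm["c001", "PE_orig"]), 1.0)
})

test_that("significance output is tidy and categorized by q alone", {
  lnd <- random_landscape(10, 12, seed = 21)
  sig <- significance_test(lnd$x, lnd$tree, n_rand = 19, seed = 5, alpha = 0.1)
  expect_setequal(unique(sig$metric), c("TR", "PD", "RPD", "PE_orig", "PE_alt", "RPE"))
  expect_equal(nrow(sig), 6L * nrow(lnd$x$incidence))
  expect_true(all(sig$q >= 0 & sig$q <= 1))
  expect_identical(sig$category,
                   ifelse(sig$q >= 0.9, "sig_high",
                          ifelse(sig$q <= 0.1, "sig_low", "ns")))
})
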