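#' Structured (fixed-marginal) randomization of a presence matrix
#'
#' Reshuffles taxon identities across cells while holding constant both the
#' number of taxa per cell (row sums) and the number of cells per taxon
#' (column sums) — the "structured" null of gridded diversity analysis. The
#' default sampler is vegan's `"quasiswap"`, which draws every replicate
#' independently with exact marginals, so rare (small-range) taxa carry no
#' serial memory of their observed positions. A checkerboard-swap Markov
#' chain (`"tswap"`: random 2 x 2 submatrix swaps started from the observed
#' matrix, burn-in of `burnin_mult` x (number of presences) attempted swaps
#' and the same thinning between replicates) and any other binary
#' fixed-marginal vegan sampler can be plugged in. Deterministic for a
#' given seed.
#'
#' A matrix admitting no checkerboard swap (e.g. all ones) is its own unique
#' fixed-marginal configuration and is returned unchanged with a warning.
#'
#' @param x A `ps_presence` object or binary matrix.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param n_rand Number of replicate matrices.
#' @param method Sampler name passed to [vegan::nullmodel()]; any binary
#'   fixed-marginal method ("quasiswap", "tswap", "swap", "curveball") may
#'   be plugged in.
#' @param burnin_mult,thin_mult Burn-in and thinning for sequential
#'   (swap-chain) samplers, as multiples of the matrix fill (number of 1
#'   entries), counted in attempted swaps; ignored by non-sequential
#'   samplers such as the default.
#' @return For `shuffle_structured()` a single binary matrix; for
#'   `null_ensemble()` a cells x taxa x `n_rand` integer array.
#' @export
shuffle_structured <- function(x, seed = NULL, method = "quasiswap",
                               burnin_mult = 10, thin_mult = 5) {
  null_ensemble(x, n_rand = 1L, seed = seed, method = method,
                burnin_mult = burnin_mult, thin_mult = thin_mult)[, , 1L]
}

#' @rdname shuffle_structured
#' @export
null_ensemble <- function(x, n_rand, seed = NULL, method = "quasiswap",
                          burnin_mult = 10, thin_mult = 5) {
  X <- if (inherits(x, "ps_presence")) x$incidence else x
  stopifnot(is.matrix(X), all(X %in% c(0L, 1L)))
  if (nrow(X) < 2L || ncol(X) < 2L) stop("need at least 2 cells and 2 taxa")
  storage.mode(X) <- "integer"
  if (!.has_checkerboard(X)) {
    warning("matrix admits no checkerboard swap; replicates equal the input")
    sims <- array(X, dim = c(dim(X), n_rand),
                  dimnames = c(dimnames(X), list(NULL)))
    return(sims)
  }
  fill <- sum(X)
  nm <- vegan::nullmodel(X, method)
  sims <- if (isTRUE(nm$commsim$isSeq)) {
    stats::simulate(nm, nsim = n_rand, seed = seed,
                    burnin = ceiling(burnin_mult * fill),
                    thin = ceiling(thin_mult * fill))
  } else {
    stats::simulate(nm, nsim = n_rand, seed = seed)
  }
  sims <- array(as.integer(sims), dim = c(dim(X), n_rand),
                dimnames = c(dimnames(X), list(NULL)))
  rs <- rowSums(X); cs <- colSums(X)
  for (r in seq_len(n_rand)) {
    if (!identical(rowSums(sims[, , r]), rs) || !identical(colSums(sims[, , r]), cs)) {
      stop("internal error: replicate ", r, " violates fixed marginals")
    }
  }
  sims
}

# a 2x2 checkerboard (swap unit) exists iff some row pair i,j has
# both a column with (1,0) and a column with (0,1)
.has_checkerboard <- function(X) {
  C <- tcrossprod(X)
  r <- rowSums(X)
  ok <- (r > C) & t(r > C)
  diag(ok) <- FALSE
  any(ok)
}

#' Empirical quantile of an observation within a null distribution
#'
#' `q = (#\{null < obs\} + 0.5 #\{null == obs\}) / n`: the half-tie
#' convention, so an observation equal to every null sits at q = 0.5.
#'
#' @param observed Numeric vector of observed values (one per cell).
#' @param nulls Numeric matrix of null values, one row per observation,
#'   columns are replicates; or a vector when `observed` is scalar.
#' @return Numeric vector of quantiles in `[0, 1]`.
#' @export
empirical_quantile <- function(observed, nulls) {
  if (is.vector(nulls)) nulls <- matrix(nulls, nrow = length(observed),
                                        ncol = length(nulls), byrow = TRUE)
  stopifnot(nrow(nulls) == length(observed), ncol(nulls) >= 1L)
  (rowSums(nulls < observed) + 0.5 * rowSums(nulls == observed)) / ncol(nulls)
}

# TR, PD, RPD, PE_orig, PE_alt, RPE for one binary matrix, given the taxon x
# branch membership M and original / comparison branch lengths
.metric_panel <- function(X, M, L, L_alt) {
  B <- (X %*% M) > 0L
  Rb <- pmax(colSums(B), 1L)
  pd <- drop(B %*% L)
  pd_alt <- drop(B %*% L_alt)
  pe <- drop(B %*% (L / Rb))
  pe_alt <- drop(B %*% (L_alt / Rb))
  cbind(TR = rowSums(X), PD = pd, RPD = pd / pd_alt,
        PE_orig = pe, PE_alt = pe_alt, RPE = pe / pe_alt)
}

#' Randomization significance test for diversity metrics
#'
#' Compares observed per-cell PD, RPD, PE (on the original and on the
#' comparison tree) and RPE against a null ensemble of structured
#' randomizations (see [shuffle_structured()]): taxon identities are
#' reshuffled with row and column sums fixed, branch lengths are never
#' touched. Each metric is recomputed on every replicate and the observed
#' value is placed in its null distribution as an empirical quantile `q`
#' (half-tie convention). Cells are flagged two-tailed: `sig_high` for
#' `q >= 1 - alpha`, `sig_low` for `q <= alpha`.
#'
#' TR is included as a built-in control: richness is fixed by the null's
#' marginals, so its quantile is 0.5 everywhere by construction.
#'
#' @param x A `ps_presence` object.
#' @param tree A reconciled `phylo` object.
#' @param n_rand Number of randomizations (at least 19; 999 for mapping).
#' @param seed Integer seed for the null sampler.
#' @param alpha Per-tail significance level (default 0.025).
#' @param ... Passed to [null_ensemble()] (sampler method, burn-in, thinning).
#' @return A data frame of class `ps_significance` with columns `cell_id`,
#'   `metric`, `observed`, `q`, `category`; attributes `n_rand`, `seed`,
#'   `alpha`, and `q_matrix` (cells x metrics).
#' @export
significance_test <- function(x, tree, n_rand = 999, seed = NULL,
                              alpha = 0.025, ...) {
  stopifnot(inherits(x, "ps_presence"))
  if (n_rand < 19L) stop("n_rand must be at least 19 to resolve alpha = 0.025")
  tree <- validate_tree(tree)
  if (!setequal(tree$tip.label, colnames(x$incidence))) {
    stop("tree tips and matrix taxa differ; run reconcile() first")
  }
  bm <- branch_membership(tree)
  taxa <- colnames(x$incidence)
  M <- bm$membership[taxa, , drop = FALSE]
  L <- bm$lengths
  L_alt <- rep(sum(L) / length(L), length(L))
  obs <- .metric_panel(x$incidence, M, L, L_alt)
  sims <- null_ensemble(x, n_rand = n_rand, seed = seed, ...)
  metrics <- colnames(obs)
  nulls <- lapply(metrics, function(m) {
    matrix(NA_real_, nrow(obs), n_rand, dimnames = list(rownames(x$incidence), NULL))
  })
  names(nulls) <- metrics
  for (r in seq_len(n_rand)) {
    panel <- .metric_panel(sims[, , r], M, L, L_alt)
    for (m in metrics) nulls[[m]][, r] <- panel[, m]
  }
  q <- vapply(metrics, function(m) empirical_quantile(obs[, m], nulls[[m]]),
              numeric(nrow(obs)))
  if (nrow(obs) == 1L) q <- matrix(q, 1L, dimnames = list(NULL, metrics))
  rownames(q) <- rownames(x$incidence)
  category <- matrix("ns", nrow(q), ncol(q), dimnames = dimnames(q))
  category[q >= 1 - alpha] <- "sig_high"
  category[q <= alpha] <- "sig_low"
  out <- data.frame(
    cell_id = rep(rownames(q), times = length(metrics)),
    metric = rep(metrics, each = nrow(q)),
    observed = as.vector(obs[, metrics]),
    q = as.vector(q),
    category = as.vector(category),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, class = c("ps_significance", "data.frame"),
            n_rand = n_rand, seed = seed, alpha = alpha, q_matrix = q)
}
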