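# Brute-force reference implementations used as independent oracles.
# Deliberately loop-based and built on phangorn::Descendants for branch tip
# sets, sharing no code with the package's vectorized matrix path.

oracle_branch_sets <- function(tree) {
  lapply(seq_len(nrow(tree$edge)), function(e) {
    node <- tree$edge[e, 2L]
    tips <- if (node <= length(tree$tip.label)) node else
      phangorn::Descendants(tree, node, "tips")[[1L]]
    tree$tip.label[tips]
  })
}

# all six per-cell metrics by explicit enumeration
oracle_metrics <- function(x, tree) {
  X <- x$incidence
  desc <- oracle_branch_sets(tree)
  L <- tree$edge.length
  ne <- length(L)
  L_alt <- rep(sum(L) / ne, ne)
  cell_taxa <- apply(X, 1L, function(r) colnames(X)[r == 1L], simplify = FALSE)
  range_b <- sapply(seq_len(ne), function(e) {
    sum(sapply(cell_taxa, function(tx) any(desc[[e]] %in% tx)))
  })
  r_t <- sapply(colnames(X), function(t) sum(X[, t]))
  out <- data.frame(cell_id = rownames(X), TR = NA, WE = NA, PD = NA, PE = NA,
                    PD_alt = NA, PE_alt = NA, RPD = NA, RPE = NA)
  for (i in seq_len(nrow(X))) {
    tx <- cell_taxa[[i]]
    present <- sapply(seq_len(ne), function(e) any(desc[[e]] %in% tx))
    out$TR[i] <- length(tx)
    out$WE[i] <- sum(1 / r_t[tx])
    out$PD[i] <- sum(L[present])
    out$PE[i] <- sum(L[present] / range_b[present])
    out$PD_alt[i] <- sum(L_alt[present])
    out$PE_alt[i] <- sum(L_alt[present] / range_b[present])
  }
  out$RPD <- out$PD / out$PD_alt
  out$RPE <- out$PE / out$PE_alt
  out
}

# range-weighted phylo-Sorensen dissimilarity by pairwise enumeration
oracle_turnover <- function(x, tree) {
  X <- x$incidence
  desc <- oracle_branch_sets(tree)
  L <- tree$edge.length
  ne <- length(L)
  cell_taxa <- apply(X, 1L, function(r) colnames(X)[r == 1L], simplify = FALSE)
  pres <- sapply(seq_len(ne), function(e) {
    sapply(cell_taxa, function(tx) any(desc[[e]] %in% tx))
  })
  w <- L / pmax(colSums(pres), 1L)
  n <- nrow(X)
  d <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      Si <- sum(w[pres[i, ]])
      Sj <- sum(w[pres[j, ]])
      W <- sum(w[pres[i, ] & pres[j, ]])
      d[i, j] <- 1 - 2 * W / (Si + Sj)
    }
  }
  diag(d) <- 0
  d
}
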