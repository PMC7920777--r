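#' Weighted endemism (WE)
#'
#' Per-cell sum over the taxa present of the inverse of their range size,
#' `WE_c = sum_t 1/r_t`: a taxon found in a single cell contributes 1 there,
#' a widespread taxon contributes little anywhere. Summed over all cells,
#' WE equals the number of taxa.
#'
#' @param x A `ps_presence` object.
#' @return Named numeric vector over analyzable cells.
#' @export
weighted_endemism <- function(x) {
  stopifnot(inherits(x, "ps_presence"))
  drop(x$incidence %*% (1 / taxon_ranges(x)))
}

# Per-cell PD and PE given a branch incidence; the shared computational core.
.pd_pe <- function(br) {
  L <- br$lengths
  pd <- drop(br$incidence %*% L)
  w <- L / pmax(br$range_size, 1L)   # unsampled branches cannot occur post-reconcile
  pe <- drop(br$incidence %*% w)
  list(pd = pd, pe = pe, w = w)
}

#' Faith's phylogenetic diversity (PD)
#'
#' Per cell, the summed branch length of the subtree spanning the cell's
#' taxa and the root (the root path is included, so a one-taxon cell scores
#' that tip's full root-path length).
#'
#' @param x A `ps_presence` object.
#' @param tree A reconciled `phylo` object (see [reconcile()]).
#' @return Named numeric vector over analyzable cells.
#' @export
faith_pd <- function(x, tree) {
  .pd_pe(branch_incidence(tree, x))$pd
}

#' Phylogenetic endemism (PE)
#'
#' PD with every branch down-weighted by its range: each branch contributes
#' `L_b / |R_b|` to every cell in its range, where `|R_b|` is the number of
#' cells occupied by at least one descendant of the branch. PE partitions
#' the total tree length across cells: summed over all cells it equals the
#' total branch length.
#'
#' @inheritParams faith_pd
#' @return Named numeric vector over analyzable cells.
#' @export
phylo_endemism <- function(x, tree) {
  .pd_pe(branch_incidence(tree, x))$pe
}

#' All per-cell diversity and endemism metrics
#'
#' Computes, per analyzable cell: taxon richness (TR), weighted endemism
#' (WE), phylogenetic diversity (PD) and phylogenetic endemism (PE) on the
#' supplied tree, the same two on the equal-branch-length comparison tree
#' (`PD_alt`, `PE_alt`), and the relative metrics `RPD = PD / PD_alt`,
#' `RPE = PE / PE_alt`. RPD above 1 marks a concentration of longer-than-
#' average branches (ancient lineages), below 1 of short branches (recent
#' radiations); RPE does the same for the range-weighted tree.
#'
#' @inheritParams faith_pd
#' @return A data frame of class `ps_metrics` with one row per analyzable
#'   cell and columns `cell_id`, `TR`, `WE`, `PD`, `PE`, `PD_alt`, `PE_alt`,
#'   `RPD`, `RPE`.
#' @export
cell_metrics <- function(x, tree) {
  stopifnot(inherits(x, "ps_presence"))
  br <- branch_incidence(tree, x)
  br_alt <- branch_incidence(equalize_branches(tree), x)
  orig <- .pd_pe(br)
  alt <- .pd_pe(br_alt)
  bad <- alt$pd <= 0 | alt$pe <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with zero comparison-tree diversity flagged (NA ratios)")
  }
  out <- data.frame(
    cell_id = rownames(x$incidence),
    TR = as.integer(taxon_richness(x)),
    WE = weighted_endemism(x),
    PD = orig$pd,
    PE = orig$pe,
    PD_alt = alt$pd,
    PE_alt = alt$pe,
    RPD = ifelse(bad, NA_real_, orig$pd / alt$pd),
    RPE = ifelse(bad, NA_real_, orig$pe / alt$pe),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("ps_metrics", "data.frame")
  out
}
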