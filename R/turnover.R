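#' Range-weighted phylo-Sorensen turnover between cells
#'
#' Sorensen-type dissimilarity computed on branch sets with each branch
#' weighted by `w_b = L_b / |R_b|` (its length divided by its range size):
#' `d_ij = 1 - 2 W_ij / (S_i + S_j)` where `S_i` is the summed weight of the
#' branches present in cell i (identically the cell's phylogenetic
#' endemism) and `W_ij` the summed weight of the branches shared by i and j.
#' Deep branches shared by everything have large ranges and hence small
#' weight, so the index is driven by range-restricted lineages; 0 means
#' identical lineage composition, 1 no shared branch weight.
#'
#' @param x A `ps_presence` object.
#' @param tree A reconciled `phylo` object.
#' @return A [stats::dist] object over analyzable cells (class also
#'   `ps_turnover`), with attribute `S` (per-cell branch-weight totals).
#' @export
rw_phylosor <- function(x, tree) {
  stopifnot(inherits(x, "ps_presence"))
  if (nrow(x$incidence) < 2L) stop("need at least 2 analyzable cells")
  br <- branch_incidence(tree, x)
  core <- .pd_pe(br)
  S <- core$pe
  if (any(S <= 0)) {
    warning(sum(S <= 0), " cell(s) with zero branch weight excluded from turnover")
  }
  keep <- S > 0
  B <- br$incidence[keep, , drop = FALSE]
  Sk <- S[keep]
  W <- tcrossprod(sweep(B, 2L, core$w, "*"), B)
  d <- 1 - 2 * W / outer(Sk, Sk, "+")
  d[d < 0] <- 0  # guard against floating-point undershoot
  diag(d) <- 0
  dd <- stats::as.dist(d)
  attr(dd, "S") <- Sk
  class(dd) <- c("ps_turnover", class(dd))
  dd
}

#' Delineate bioregions by clustering phylogenetic turnover
#'
#' Agglomerative clustering of the range-weighted phylo-Sorensen matrix
#' (average linkage / UPGMA by default) cut into `k` regions. `k` is the
#' user's choice, typically made by inspecting the dendrogram; see
#' [bioregion_silhouette()] for a diagnostic.
#'
#' @param turnover A `ps_turnover` / [stats::dist] object.
#' @param k Number of regions, `1 <= k <=` number of cells.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return An object of class `ps_bioregions`: list with `assignment`
#'   (named integer vector, labels `1..k` in order of first appearance),
#'   `dendrogram` (an `hclust`), and `k`.
#' @export
cluster_bioregions <- function(turnover, k, linkage = "average") {
  stopifnot(inherits(turnover, "dist"))
  n <- attr(turnover, "Size")
  if (k < 1L || k > n) stop("k must be between 1 and the number of cells (", n, ")")
  hc <- stats::hclust(turnover, method = linkage)
  raw <- stats::cutree(hc, k = k)
  # relabel regions 1..k by order of first appearance for determinism
  lev <- unique(raw)
  assignment <- match(raw, lev)
  names(assignment) <- names(raw)
  structure(list(assignment = assignment, dendrogram = hc, k = as.integer(k)),
            class = "ps_bioregions")
}

#' Mean silhouette widths over a range of k
#'
#' Diagnostic to help choose the number of bioregions; reports, never
#' auto-selects.
#'
#' @param turnover A `ps_turnover` / [stats::dist] object.
#' @param ks Integer vector of cluster counts to evaluate (each >= 2).
#' @param linkage Passed to [cluster_bioregions()].
#' @return Data frame with columns `k` and `mean_silhouette`.
#' @export
bioregion_silhouette <- function(turnover, ks = 2:6, linkage = "average") {
  stopifnot(all(ks >= 2L))
  d <- as.matrix(turnover)
  res <- vapply(ks, function(k) {
    a <- cluster_bioregions(turnover, k, linkage)$assignment
    mean(vapply(seq_along(a), function(i) {
      own <- d[i, a == a[i] & seq_along(a) != i]
      ai <- if (length(own)) mean(own) else 0
      bi <- min(vapply(setdiff(unique(a), a[i]),
                       function(g) mean(d[i, a == g]), numeric(1L)))
      if (length(own) == 0L) 0 else (bi - ai) / max(ai, bi)
    }, numeric(1L)))
  }, numeric(1L))
  data.frame(k = as.integer(ks), mean_silhouette = res)
}

#' @export
print.ps_bioregions <- function(x, ...) {
  cat(sprintf("<ps_bioregions> %d cells in %d regions\n",
              length(x$assignment), x$k))
  print(table(region = x$assignment))
  invisible(x)
}
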