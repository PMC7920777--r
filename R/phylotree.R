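#' Parse a rooted Newick phylogeny
#'
#' Thin wrapper around [ape::read.tree()] adding the checks the pipeline
#' relies on: the tree must be rooted with unique tip labels; missing branch
#' lengths are set to zero with a warning; a root edge, if present, is
#' ignored with a warning (a "branch" here is always the edge above a
#' non-root node, so the root itself carries none). Polytomies are kept.
#'
#' @param path Path to a Newick file, or a Newick string via `text`.
#' @param text Optional Newick string (overrides `path`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else {
    if (is.null(path) || !file.exists(path)) stop("tree file not found: ", path)
    ape::read.tree(path)
  }
  if (is.null(tree)) stop("could not parse Newick input")
  validate_tree(tree)
}

#' @rdname parse_newick
#' @param tree A `phylo` object to validate in place.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!is.null(tree$root.edge) && tree$root.edge > 0) {
    warning("root edge ignored; the root carries no branch")
    tree$root.edge <- NULL
  }
  tree
}

#' Total branch length of a tree
#' @param tree A `phylo` object.
#' @return Sum of all branch lengths (root edge excluded).
#' @export
total_tree_length <- function(tree) {
  sum(validate_tree(tree)$edge.length)
}

#' Reconcile a tree with a presence matrix
#'
#' Guarantees exact agreement between tree tips and matrix taxa: tips absent
#' from the matrix are pruned (unifurcations created by pruning are collapsed
#' by summing branch lengths), and matrix columns absent from the tree are
#' dropped. Idempotent.
#'
#' @param tree A `phylo` object.
#' @param x A `ps_presence` object.
#' @return List with `tree`, `presence`, and `report` (character vectors
#'   `tips_pruned`, `taxa_dropped`).
#' @export
reconcile <- function(tree, x) {
  tree <- validate_tree(tree)
  stopifnot(inherits(x, "ps_presence"))
  taxa <- colnames(x$incidence)
  common <- intersect(tree$tip.label, taxa)
  if (length(common) == 0L) stop("tree and presence matrix share no taxa")
  tips_pruned <- setdiff(tree$tip.label, common)
  taxa_dropped <- setdiff(taxa, common)
  if (length(tips_pruned)) {
    tree <- ape::keep.tip(tree, common)  # collapses singles, summing lengths
  }
  if (length(taxa_dropped)) {
    x <- presence_matrix(x$incidence[, common, drop = FALSE],
                         grid = x$grid, skipped = x$skipped)
  }
  list(tree = tree, presence = x,
       report = list(tips_pruned = tips_pruned, taxa_dropped = taxa_dropped))
}

#' Equal-branch-length comparison tree
#'
#' Returns a tree with identical topology in which every branch has length
#' `total_length / n_branches`, so the total tree length is preserved
#' exactly. Diversity ratios against this tree (RPD, RPE) are then pure
#' tree-shape contrasts with expectation near 1.
#'
#' @param tree A `phylo` object with at least one branch.
#' @return A `phylo` object with equalized branch lengths.
#' @export
equalize_branches <- function(tree) {
  tree <- validate_tree(tree)
  ne <- nrow(tree$edge)
  if (ne < 1L) stop("tree has no branches")
  tree$edge.length <- rep(sum(tree$edge.length) / ne, ne)
  tree
}

#' Per-branch tip membership matrix
#'
#' For each branch (edge above a non-root node) the set of descendant tips,
#' as a binary taxa x branches matrix, computed in one postorder pass
#' (polytomies supported). Branch order is the postorder edge order of the
#' returned tree.
#'
#' @param tree A `phylo` object.
#' @return List with `membership` (tips x branches binary matrix, rows named
#'   by tip label), `lengths` (branch lengths in the same order), and `tree`
#'   (the postorder-reordered tree).
#' @keywords internal
branch_membership <- function(tree) {
  tree <- validate_tree(tree)
  po <- stats::reorder(tree, "postorder")
  nt <- length(po$tip.label)
  ne <- nrow(po$edge)
  M <- matrix(0L, nt, ne, dimnames = list(po$tip.label, NULL))
  node_tips <- vector("list", nt + po$Nnode)
  node_tips[seq_len(nt)] <- seq_len(nt)
  for (e in seq_len(ne)) {
    child <- po$edge[e, 2L]
    tips <- node_tips[[child]]
    M[tips, e] <- 1L
    par <- po$edge[e, 1L]
    node_tips[[par]] <- c(node_tips[[par]], tips)
  }
  list(membership = M, lengths = po$edge.length, tree = po)
}

#' Spatial incidence of tree branches
#'
#' For every branch, the set of grid cells in which at least one of its
#' descendant taxa occurs (the branch "range"), computed bottom-up. The
#' range of a parent branch is always a superset of each child's range.
#'
#' @param tree A `phylo` object whose tips exactly match the matrix taxa
#'   (see [reconcile()]).
#' @param x A `ps_presence` object.
#' @return An object of class `ps_branches`: list with `incidence`
#'   (cells x branches binary matrix), `range_size` (branch range sizes
#'   `|R_b|`), `lengths`, `membership`, and `tree` (postorder).
#' @export
branch_incidence <- function(tree, x) {
  stopifnot(inherits(x, "ps_presence"))
  bm <- branch_membership(tree)
  taxa <- colnames(x$incidence)
  if (!setequal(rownames(bm$membership), taxa)) {
    stop("tree tips and matrix taxa differ; run reconcile() first")
  }
  B <- (x$incidence %*% bm$membership[taxa, , drop = FALSE]) > 0L
  storage.mode(B) <- "integer"
  structure(list(incidence = B, range_size = colSums(B),
                 lengths = bm$lengths, membership = bm$membership,
                 tree = bm$tree),
            class = "ps_branches")
}

#' @export
print.ps_branches <- function(x, ...) {
  cat(sprintf("<ps_branches> %d cells x %d branches, total length %g\n",
              nrow(x$incidence), ncol(x$incidence), sum(x$lengths)))
  invisible(x)
}
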