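# Shared fixtures: a 4-taxon / 3-cell landscape whose metrics are small
# enough to enumerate by hand, and random landscape generators for
# property-style tests.

fixture_tree <- function() {
  parse_newick(text = "((A:1,B:1):1,(C:2,D:2):0.5);")
}

fixture_presence <- function() {
  X <- matrix(0L, 3, 4, dimnames = list(c("c1", "c2", "c3"), c("A", "B", "C", "D")))
  X["c1", c("A", "B")] <- 1L
  X["c2", c("B", "C", "D")] <- 1L
  X["c3", c("C", "D")] <- 1L
  presence_matrix(X)
}

# random binary landscape with no empty rows/columns, plus a random tree on
# the same taxa; tree drawn with ape::rtree (uniform topology), independent
# of the generator under test
random_landscape <- function(n_taxa, n_cells, p = 0.35, seed = 1) {
  set.seed(seed)
  taxa <- sprintf("s%02d", seq_len(n_taxa))
  repeat {
    X <- matrix(rbinom(n_cells * n_taxa, 1L, p), n_cells, n_taxa,
                dimnames = list(sprintf("c%02d", seq_len(n_cells)), taxa))
    if (all(rowSums(X) > 0L) && all(colSums(X) > 0L)) break
  }
  tree <- ape::rtree(n_taxa, tip.label = sample(taxa))
  list(x = presence_matrix(X), tree = tree)
}
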