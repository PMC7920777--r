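# run code under a local RNG stream without disturbing the caller's state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate a phylogeny with planted endemism features
#'
#' Draws a pure-birth (Yule) tree and optionally plants two kinds of
#' ground-truth signal used to validate endemism detection: a
#' *paleo-relict* — the tip with the longest terminal branch gets that
#' branch multiplied by `m_paleo` (a long, isolated lineage) — and a
#' *neo-radiation* — a clade of about `neo_size` tips has all its terminal
#' branches multiplied by `m_neo` (a burst of recent, barely divergent
#' species). Among the clades whose tip count is closest to `neo$size`
#' (excluding any containing the relict tip), the *youngest* — smallest
#' total within-clade branch length — is chosen: a radiation is by
#' definition a recent burst, and an old clade of the same size would carry
#' long internal branches and read as mixed rather than neo-endemism.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param seed Integer seed; identical seeds give identical trees.
#' @param paleo Terminal-branch multiplier `m_paleo` for the relict tip, or
#'   `NULL` for no relict.
#' @param neo List `list(size =, m =)` — clade size and terminal multiplier
#'   `m_neo` — or `NULL` for no radiation.
#' @return List with `tree` (a `phylo`) and `truth`
#'   (`relict_tip`, `neo_tips` character vectors, possibly empty).
#' @export
simulate_tree <- function(n_taxa, seed = NULL, paleo = NULL, neo = NULL) {
  if (n_taxa < 3L) stop("n_taxa must be at least 3")
  tree <- .with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tree$tip.label <- sprintf("t%03d", seq_len(n_taxa))
  truth <- list(relict_tip = character(0), neo_tips = character(0))
  nt <- length(tree$tip.label)
  term <- match(seq_len(nt), tree$edge[, 2L])  # edge index of each tip
  if (!is.null(paleo)) {
    m_paleo <- as.numeric(paleo)
    if (m_paleo <= 0) stop("paleo multiplier must be > 0")
    relict <- which.max(tree$edge.length[term])
    tree$edge.length[term[relict]] <- tree$edge.length[term[relict]] * m_paleo
    truth$relict_tip <- tree$tip.label[relict]
  }
  if (!is.null(neo)) {
    if (!is.list(neo) || is.null(neo$size) || is.null(neo$m)) {
      stop("neo must be list(size =, m =)")
    }
    if (neo$size < 2L || neo$size > nt - 1L) {
      stop("neo radiation size must be in [2, n_taxa - 1]")
    }
    if (neo$m <= 0) stop("neo multiplier must be > 0")
    bm <- branch_membership(tree)
    sizes <- colSums(bm$membership)
    internal <- which(sizes >= 2L & sizes < nt)
    if (length(truth$relict_tip)) {
      internal <- internal[bm$membership[truth$relict_tip, internal] == 0L]
    }
    if (!length(internal)) stop("no clade available for the neo radiation")
    # total branch length inside each candidate clade (edges whose tips all
    # descend from it), excluding its stem
    clade_len <- vapply(internal, function(e) {
      tips <- bm$membership[, e] == 1L
      inside <- colSums(bm$membership[tips, , drop = FALSE]) ==
        colSums(bm$membership) & colSums(bm$membership) < sizes[e]
      sum(bm$lengths[inside])
    }, numeric(1L))
    best_size <- min(abs(sizes[internal] - neo$size))
    cand <- internal[abs(sizes[internal] - neo$size) == best_size]
    pick <- cand[order(clade_len[match(cand, internal)],
                       bm$tree$edge[cand, 2L])][1L]
    tips <- rownames(bm$membership)[bm$membership[, pick] == 1L]
    idx <- term[match(tips, tree$tip.label)]
    tree$edge.length[idx] <- tree$edge.length[idx] * neo$m
    truth$neo_tips <- tips
  }
  list(tree = tree, truth = truth)
}

#' Describe a synthetic landscape scenario
#'
#' Bundles the knobs of [simulate_landscape()] with validation. Cell blocks
#' are given as `list(rows =, cols =)` of 1-based grid row/column indices.
#'
#' Defaults describe a mid-sized island-like study: a 10 x 10 grid of 10 km
#' cells, 60 taxa, background occupancy 0.08 (a typical taxon occupies ~8
#' cells). The neo radiation is confined to a 2 x 2 block (its signal is
#' carried by several co-occurring restricted taxa), while the paleo relict
#' defaults to a single refugium cell: a lone taxon of range b enters a
#' fixed-marginal null replicate of one of its cells with probability of
#' about b / n_cells, so a single-tip signal is only resolvable against a
#' per-tail 0.025 test when its range is a small fraction of the grid.
#'
#' @param n_taxa Number of taxa the tree must provide.
#' @param n_rows,n_cols Grid dimensions.
#' @param cell_size Cell edge length in meters.
#' @param p_bg Background presence probability per (taxon, cell).
#' @param paleo_block,neo_block Cell blocks confining the relict tip and
#'   the radiation clade (`NULL` to plant nothing).
#' @param bioregion_blocks Optional list of cell blocks; the non-planted
#'   taxa are split into contiguous clades (by cladewise tip order), one
#'   per block, each confined to its block.
#' @param p_within Within-block presence probability for bioregion-clade
#'   taxa (planted endemics always fill their block).
#' @return A validated list of class `ps_scenario`.
#' @export
scenario <- function(n_taxa = 60, n_rows = 10, n_cols = 10, cell_size = 10000,
                     p_bg = 0.08,
                     paleo_block = list(rows = 1, cols = 1),
                     neo_block = list(rows = (n_rows - 1):n_rows,
                                      cols = (n_cols - 1):n_cols),
                     bioregion_blocks = NULL, p_within = 0.6) {
  stopifnot(n_taxa >= 3, n_rows >= 1, n_cols >= 1, cell_size > 0,
            p_bg >= 0, p_bg <= 1, p_within >= 0, p_within <= 1)
  chk <- function(b, what) {
    if (is.null(b)) return(invisible())
    if (!all(b$rows >= 1 & b$rows <= n_rows) ||
        !all(b$cols >= 1 & b$cols <= n_cols)) {
      stop(what, " block outside grid bounds")
    }
    if (!length(b$rows) || !length(b$cols)) stop(what, " block is empty")
  }
  chk(paleo_block, "paleo")
  chk(neo_block, "neo")
  for (b in bioregion_blocks) chk(b, "bioregion")
  structure(list(n_taxa = n_taxa, n_rows = n_rows, n_cols = n_cols,
                 cell_size = cell_size, p_bg = p_bg,
                 paleo_block = paleo_block, neo_block = neo_block,
                 bioregion_blocks = bioregion_blocks, p_within = p_within),
            class = "ps_scenario")
}

# cell ids (r<row>_c<col>, 0-based) covered by a 1-based block spec
.block_cells <- function(block, grid) {
  ids <- as.vector(outer(block$cols - 1L, block$rows - 1L,
                         function(co, ro) sprintf("r%d_c%d", ro, co)))
  intersect(grid$cells$cell_id, ids)
}

#' Simulate a presence landscape with planted structure
#'
#' Generates a binary cells x taxa landscape over a rectangular grid in
#' abstract planar meters. Background presences are independent Bernoulli
#' draws at `p_bg`. Planted endemics (the relict tip and the radiation
#' clade of `sim_tree$truth`) are overwritten to occupy exactly their block
#' (within-block occupancy 1, nothing outside). Bioregion-clade taxa are
#' confined to their blocks with within-block occupancy `p_within`. Any
#' taxon left without a presence is rescued into one random cell (inside
#' its block when confined). Cells that end up empty are excluded from
#' analysis downstream, as in real sparsely sampled grids.
#'
#' @param sim_tree Result of [simulate_tree()] (or a list with `tree` and
#'   `truth`).
#' @param scn A `ps_scenario`.
#' @param seed Integer seed.
#' @return List with `presence` (a `ps_presence` whose grid matches the
#'   scenario) and `truth` (list: `relict_tip`, `neo_tips`, `paleo_cells`,
#'   `neo_cells`, `region_of_cell` named vector or `NULL`, `region_taxa`).
#' @export
simulate_landscape <- function(sim_tree, scn, seed = NULL) {
  stopifnot(inherits(scn, "ps_scenario"))
  tree <- sim_tree$tree
  truth <- sim_tree$truth
  if (length(tree$tip.label) != scn$n_taxa) {
    stop("tree has ", length(tree$tip.label), " tips but scenario expects ",
         scn$n_taxa)
  }
  grid <- build_grid(extent = c(0, scn$n_cols * scn$cell_size,
                                0, scn$n_rows * scn$cell_size),
                     cell_size = scn$cell_size)
  cell_ids <- grid$cells$cell_id
  taxa <- tree$tip.label
  .with_seed(seed, {
    X <- matrix(stats::rbinom(length(cell_ids) * length(taxa), 1L, scn$p_bg),
                length(cell_ids), length(taxa),
                dimnames = list(cell_ids, taxa))
    out_truth <- list(relict_tip = truth$relict_tip, neo_tips = truth$neo_tips,
                      paleo_cells = character(0), neo_cells = character(0),
                      region_of_cell = NULL, region_taxa = NULL)
    plant <- function(X, tips, block) {
      cells <- .block_cells(block, grid)
      X[, tips] <- 0L
      X[cells, tips] <- 1L
      list(X = X, cells = cells)
    }
    if (length(truth$relict_tip) && !is.null(scn$paleo_block)) {
      p <- plant(X, truth$relict_tip, scn$paleo_block)
      X <- p$X; out_truth$paleo_cells <- p$cells
    }
    if (length(truth$neo_tips) && !is.null(scn$neo_block)) {
      p <- plant(X, truth$neo_tips, scn$neo_block)
      X <- p$X; out_truth$neo_cells <- p$cells
    }
    if (!is.null(scn$bioregion_blocks)) {
      nb <- length(scn$bioregion_blocks)
      free <- setdiff(taxa, c(truth$relict_tip, truth$neo_tips))
      # contiguous cladewise tip order approximates disjoint clades
      free <- free[order(match(free, tree$tip.label))]
      groups <- split(free, cut(seq_along(free), nb, labels = FALSE))
      region_of_cell <- stats::setNames(rep(NA_integer_, length(cell_ids)), cell_ids)
      for (g in seq_len(nb)) {
        cells <- .block_cells(scn$bioregion_blocks[[g]], grid)
        gt <- groups[[g]]
        # block core at p_within on top of the p_bg draws, which remain as
        # cross-block noise
        core <- matrix(stats::rbinom(length(cells) * length(gt), 1L, scn$p_within),
                       length(cells), length(gt))
        X[cells, gt] <- pmax(X[cells, gt], core)
        region_of_cell[cells] <- g
      }
      out_truth$region_of_cell <- region_of_cell
      out_truth$region_taxa <- groups
    }
    # rescue: every taxon occupies at least one cell
    empty_taxa <- taxa[colSums(X) == 0L]
    for (t in empty_taxa) {
      X[sample(cell_ids, 1L), t] <- 1L
    }
    list(presence = presence_matrix(X, grid = grid), truth = out_truth)
  })
}

#' Emit point occurrence records from a presence matrix
#'
#' Writes one record per (taxon, cell) presence, with the point jittered
#' uniformly inside its cell so that half-open binning edges are exercised
#' on re-import. A fraction of deliberately corrupt rows (zero or missing
#' coordinates) can be appended to test cleaning; corrupt rows are extra —
#' re-cleaning and re-binning the output reproduces the input exactly.
#'
#' @param x A `ps_presence` with a grid.
#' @param seed Integer seed for the jitter.
#' @param corrupt_frac Fraction (of the number of presences) of bad rows to
#'   append.
#' @return A data frame with Darwin-Core-style columns `species`,
#'   `decimalLongitude`, `decimalLatitude` (planar meters).
#' @export
simulate_occurrences <- function(x, seed = NULL, corrupt_frac = 0) {
  stopifnot(inherits(x, "ps_presence"), !is.null(x$grid))
  grid <- x$grid
  idx <- which(x$incidence == 1L, arr.ind = TRUE)
  cells <- grid$cells[match(rownames(x$incidence)[idx[, 1L]], grid$cells$cell_id), ]
  .with_seed(seed, {
    n <- nrow(idx)
    s <- grid$cell_size
    u <- stats::runif(n) * s
    v <- stats::runif(n) * s
    # keep jitter strictly inside the half-open cell
    u <- pmin(u, s * (1 - 1e-12))
    v <- pmin(v, s * (1 - 1e-12))
    rec <- data.frame(
      species = colnames(x$incidence)[idx[, 2L]],
      decimalLongitude = cells$x0 + u,
      decimalLatitude = cells$y0 + v,
      stringsAsFactors = FALSE
    )
    n_bad <- round(corrupt_frac * n)
    if (n_bad > 0L) {
      pick <- sample.int(n, n_bad, replace = TRUE)
      bad <- rec[pick, , drop = FALSE]
      kind <- sample(c("zero_lon", "zero_lat", "na_lon", "na_lat"), n_bad,
                     replace = TRUE)
      bad$decimalLongitude[kind == "zero_lon"] <- 0
      bad$decimalLatitude[kind == "zero_lat"] <- 0
      bad$decimalLongitude[kind == "na_lon"] <- NA_real_
      bad$decimalLatitude[kind == "na_lat"] <- NA_real_
      rec <- rbind(rec, bad)
    }
    rownames(rec) <- NULL
    rec
  })
}
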