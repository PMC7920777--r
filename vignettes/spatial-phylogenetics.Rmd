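---
title: "Methods: gridded spatial phylogenetics with phyloscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded spatial phylogenetics with phyloscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloscape)
```

# The model

`phyloscape` quantifies how evolutionary history is distributed over a
study region. The data model is deliberately minimal: a binary incidence
matrix of grid cells by taxa, and a rooted phylogeny with branch lengths
whose tips are the matrix columns. Everything downstream is a function of
these two objects.

## From occurrences to a presence matrix

Occurrence records (taxon, x, y) are cleaned by three rules: records with
unparseable or missing coordinates are dropped, records with an exact-zero
latitude or longitude are dropped (zero is a widespread placeholder for "no
coordinate" in aggregated occurrence data; we match it by exact equality
only, since a genuine collection at a zero meridian/equator crossing is
conceivable but a tolerance band would silently bite real data), and —
when a study-area polygon is supplied — records outside it are dropped.
Every removal is logged with its reason.

The grid is a lower-left-anchored lattice of half-open square cells
`[x0, x0+s) × [y0, y0+s)` (default edge `s` = 10 km), so each point of the
plane belongs to exactly one cell; a point on a shared edge goes to the
cell with the larger index. All coordinates are planar meters: projection
from geographic coordinates is the user's responsibility, because no
single projected CRS suits all study regions and silently defaulting to
one would corrupt cell areas. When a boundary polygon is given, only cells
whose intersection with it has positive area are kept (a
Sutherland–Hodgman clip of each ring against the cell rectangle; cells
merely touching an edge are excluded). Cells retained but containing no
records are reported as "no records" and excluded from analysis — they are
the white cells of a diversity map, not zeros.

Duplicate records of a taxon in a cell collapse to a single presence.
Abundance weighting is out of scope: aggregated occurrence data confound
abundance with collection effort.

## Per-cell metrics

With `r_t` the number of cells occupied by taxon `t`, `L_b` the length of
branch `b` (the edge above each non-root node; the root carries no edge,
and a root edge in the input is ignored with a warning), and `R_b` the set
of cells where at least one descendant of `b` occurs:

* `TR_c` — richness, the row sum;
* `WE_c = Σ_{t∈c} 1/r_t` — weighted endemism;
* `PD_c = Σ_{b∈B_c} L_b` — Faith's PD over the branches `B_c` whose range
  includes `c`. The path to the root is included, so a single-taxon cell
  scores that tip's root-path length rather than zero; this makes PD sums
  across nested cells consistent and is the convention of the standard
  gridded-biodiversity tools;
* `PE_c = Σ_{b∈B_c} L_b/|R_b|` — phylogenetic endemism. Because every
  sampled branch has `|R_b| ≥ 1`, PE partitions total tree length:
  `Σ_c PE_c = Σ_b L_b` exactly. The analogous identity `Σ_c WE_c = n_taxa`
  holds for WE. Both are asserted to `1e-10` in the tests;
* `RPD_c`, `RPE_c` — PD and PE divided by their values on a *comparison
  tree*: same topology, every branch set to `total_length / n_branches`.
  Preserving total length makes the ratios pure tree-shape contrasts with
  expectation near 1 (the normalization is a free choice; any constant
  rescaling of the comparison tree cancels in the randomization quantiles,
  so it affects only the readability of the raw ratios).

Branch ranges are computed bottom-up in one postorder pass (polytomies
retained as-is, zero-length branches permitted), then all metrics are
matrix products of the cell × branch incidence with branch-weight vectors.
Tests verify every metric against a deliberately naive loop-based oracle
on random instances, and PD additionally against `picante::pd`.

## The structured null model

Observed diversity patterns are confounded by sampling: richer cells have
more branches by construction. The null model therefore reshuffles taxon
identities across cells *holding both marginals fixed* — each cell keeps
its richness, each taxon keeps its range size — and recomputes PD, RPD, PE
(on both trees) and RPE on every replicate; branch lengths are never
shuffled. The observed value's empirical quantile
`q = (#{null < obs} + ½·#{null = obs}) / n_rand` is the test statistic;
two-tailed flags use `q ≥ 1−α` / `q ≤ α` with per-tail `α = 0.025` by
default, and 999 replicates are the mapping default.

Sampling binary matrices with fixed marginals is a classical problem and we
delegate it to `vegan`'s null-model engine. The default sampler is
`quasiswap`, which draws each replicate independently with exact marginals.
We initially ran a sequential checkerboard-swap chain (`tswap`, burn-in
10 × fill attempted swaps, thinning 5 × fill), but a chain started at the
observed matrix moves a range-1 taxon only when a trial swap hits its
single presence — roughly once per thousand trials at our problem sizes —
so early replicates remembered exactly the range-restricted placements the
endemism tests care about, inflating null resemblance at planted hotspots.
Independent draws remove serial memory entirely; the sequential samplers
remain available through the `method` argument for users who want them,
with the burn-in/thinning multipliers applied. Marginal preservation is
hard-asserted on every replicate, not assumed.

Two built-in controls: TR is a deterministic function of the preserved row
sums, so its quantile is 0.5 everywhere by construction (asserted in
tests); and on structureless landscapes (independent random placement) the
two-tailed flag rate per metric is within binomial 99% bounds of the
nominal 0.05 (asserted over 500 cells per metric).

## CANAPE

Endemism hotspots are classified in two steps. *Candidacy*: a cell
qualifies if PE on the original tree or on the comparison tree is
one-tailed significant at `α = 0.05` (testing both trees catches hotspots
whose endemism is carried by branch lengths or purely by restricted
ranges). *Character*: among candidates, RPE's upper 0.025 tail marks
*paleo* (concentration of range-restricted long branches), the lower tail
*neo* (range-restricted short branches), the rest *mixed*; mixed cells with
both PE quantiles extreme at 0.01 are *super* (collapsible into mixed via
`collapse_super` for the 3-way scheme). All four thresholds are arguments;
the defaults above are the established CANAPE convention. No
multiple-testing correction is applied across cells, also by convention:
the per-cell randomization test is reported as a map, not as a family of
decisions.

## Turnover and bioregions

Lineage turnover between cells is the Sorensen index on branch sets with
branch weights `w_b = L_b/|R_b|`:
`d_ij = 1 − 2W_ij/(S_i + S_j)`, with `S_i` (= `PE_i`, asserted in tests)
the summed weight in cell `i` and `W_ij` the shared weight. Any two
occupied cells share the deep branches near the root, but those have large
ranges and hence vanishing weight, so no ad-hoc branch exclusion is
needed. The matrix is clustered by UPGMA (average linkage, the default of
the field's gridded-analysis tools; configurable) and cut at a
user-chosen `k`. We deliberately do not auto-select `k`: the number of
biogeographic zones is an interpretive choice made by inspecting the
dendrogram, and `bioregion_silhouette()` only reports mean silhouette
widths as a diagnostic.

# The synthetic-data generator

`simulate_tree()` draws a pure-birth tree and plants ground truth:

* a **paleo relict** — the tip with the longest terminal branch has that
  branch multiplied by `m_paleo` (default 20 in the validation scenarios),
  emulating a long-isolated lineage;
* a **neo radiation** — the *youngest* clade of about the requested size
  (smallest total within-clade branch length) has its terminal branches
  multiplied by `m_neo` (default 0.05). Youth matters: an old clade of the
  same size carries long internal branches and is, correctly, mixed rather
  than neo endemism — picking it would plant a feature whose "failure" to
  classify as neo is actually the classifier being right.

`simulate_landscape()` lays these on a grid: background presences are
independent Bernoulli draws at `p_bg`, planted endemics occupy exactly
their blocks, bioregion clades (contiguous groups in cladewise tip order)
are confined to theirs at within-block occupancy `p_within` on top of the
background noise, and any taxon left empty is rescued into one random
cell. Default validation conditions: 60 taxa on a 10 × 10 grid of 10 km
cells with `p_bg = 0.08`, so a typical taxon occupies ~8 cells and cell
richness is ~5 — sparse, like real herbarium-derived grids. The neo
radiation fills a 2 × 2 corner block; the relict defaults to a *single*
refuge cell. The latter is a detectability constraint worth stating
plainly: under a fixed-marginal null, a lone taxon of range `b` lands in
one of its observed cells with probability ≈ `b/n_cells`, so a single-tip
signal smeared over 4 of 100 cells caps its quantile near 0.98 with high
variance — structurally borderline against a 0.975 tail regardless of
replicate count. A point endemic (`b = 1`) is both the archetypal relict
and statistically resolvable; multi-taxon signals like the radiation do
not suffer from this, which is why its block can be larger.

What the generator does *not* emulate: spatial autocorrelation of ranges
(each background presence is independent), collection-effort gradients,
range cohesion, or coalescent tree shapes. Passing tests therefore show
the pipeline recovers planted structure under ideal sampling, not that
real data meet these assumptions — in particular the null model itself
assumes no spatial autocorrelation in occurrences, and flags on real
autocorrelated data are anticonservative to an extent the package cannot
estimate.

# Numerical and design choices

* Tolerances: exact-arithmetic identities (marginal preservation,
  partition identities) are asserted at `1e-10`–`1e-12`; statistical
  recoveries use the binomial bounds or rate thresholds stated above.
* Determinism: every stochastic entry point takes a seed, restores the
  caller's RNG state, and derives per-stage streams in the pipeline so
  that disabling one stage does not shift another's draws; pipeline reruns
  are byte-identical.
* Degenerate inputs: a matrix admitting no checkerboard swap (its
  marginals force a unique configuration) is returned unchanged with a
  warning; cells with zero comparison-tree diversity are flagged and
  excluded from ratios; `n_rand < 19` is refused since it cannot resolve
  `α = 0.025`.
* Validation problem sizes (50 oracle instances at ≤ 10 taxa × ≤ 15 cells;
  5 × 100 cells for type-I calibration at 199 replicates; 20 seeded runs
  for hotspot and bioregion recovery) were chosen as the smallest scales
  at which the binomial bounds are informative, keeping the full suite
  around a minute.

# Known limitations

* No taxonomic name resolution, coordinate-uncertainty filtering, or
  cross-source deduplication beyond per-cell presence collapse.
* No abundance weighting, rarefaction or effort standardization — the
  randomization conditions on observed marginals instead.
* Geographic inputs must be pre-projected; the package does no CRS
  handling beyond planar arithmetic.
* The turnover analysis offers no ordination view, and `k` selection is
  manual by design.
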