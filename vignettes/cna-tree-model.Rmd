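---
title: "Joint copy-number calling and event-tree inference: the model behind scnatree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint copy-number calling and event-tree inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnatree)
```

## The problem

Shallow whole-genome single-cell DNA sequencing (on the order of 0.1x per
cell) produces a matrix of read counts per genomic bin per cell. After GC and
mappability correction the counts are, in expectation, proportional to the
underlying copy number, but at 2–8 reads per bin the per-cell signal is far
too noisy to call integer copy numbers cell by cell. Tumour cells, however,
share an evolutionary history: copy-number alterations (CNAs) accumulate
along a tree, and cells in the same subclone share the same profile.
`scnatree` exploits that structure, jointly inferring

1. a **CNA event tree** — a rooted tree whose non-root nodes carry sets of
   signed per-segment copy-number changes — and
2. the **attachment** of every cell to a node, which determines its full
   integer copy-number profile by accumulating all events on the path from
   the root.

This joint treatment pools reads across the cells of each (unknown) clone,
which is what makes integer calling possible at depths where per-cell
callers fail.

## Breakpoint detection and segmentation

CNAs span many bins, so bins are first collated into segments between
detected breakpoints. For each cell and each bin boundary we compare a
two-mean to a one-mean negative-binomial model on the flanking windows
(default `window = 10` bins on each side; the detection dispersion `nu_bp`
defaults to 1, i.e. deliberately permissive about overdispersion). Because
with a fixed size parameter the NB profile log-likelihood depends on a
window only through its count sum and bin count, all `B - 1` boundary
statistics per cell cost O(B) with prefix sums, and the full matrix costs
O(mB). Per-cell statistics are rectified at zero and summed across cells —
an event present in any subset of cells adds coherent signal at the same
boundary — and boundaries exceeding `median + threshold_sd * MAD` (default
multiplier 4) are selected greedily with a `min_separation` exclusion zone
(default one window), lower index winning ties. Cells are scaled to a common
mean beforehand, since corrected counts are proportional rather than
absolute.

Counts are then summed per segment: the model below only ever sees the
`m x K` segment matrix `D` and the segment sizes `s_k` (in bins).

## The observation model

A cell attached at node `sigma` with per-segment states
`c_k` receives reads in segment `k` with probability
`p_k = c_k s_k / Z`, `Z = sum_k c_k s_k`. Fully deleted segments keep a
residual floor `eta` (default `1e-4`) so that stray mis-mapped reads do not
zero out the likelihood. Counts are modelled as Dirichlet-multinomial with
concentration `nu * Z` — `nu` is an inverse overdispersion, walked over
during sampling — which reduces to the multinomial as `nu` grows. The
multinomial coefficient is omitted throughout: it is constant across
attachments and trees, and only likelihood ratios enter the inference. For
numerical stability the Gamma-function difference
`log G(x) - log G(x + N)` is evaluated through `lbeta`, which remains
accurate at the enormous concentrations of the multinomial limit.

All attachment log-likelihoods are stored relative to the root. The root
column is shared by every tree on the same data and is recomputed only when
`nu` changes. The full `m x (n+1)` table is built by a root-to-leaf
traversal updating only the product terms of the segments each event
touches (plus the normalizer-dependent terms), so it costs
O(m(n + total event size)) rather than O(mnK).

## Tree score

Two scores are available. The marginal (`"sum"`) score averages each cell
over all `n + 1` attachment points and multiplies the event-vector prior
`P(V|T)`, a tree-size penalty `P'(T) = exp(-kappa n)` (default
`kappa = 1`) against the combinatorial growth of larger trees, and the
uniform-prior normalization `(n+1)^-(n-1+m)`. The maximized (`"max"`) score
places each cell at its best attachment and drops the size penalty; it is
the default, and it is the better performer for copy-number calling.

Biological validity gates both scores: any tree where a state goes
negative, a fully deleted segment is later regained, or two distinct nodes
carry identical genotypes (a redundant description of the same set of
profiles) scores `-Inf`.

**The event prior.** `P(V|T)` factorizes over nodes and is exactly the
generative distribution used by the simulator: the number of touched
segments is `1 + Poisson(lambda_s)` (default 0.1), the specific subset of
segments is uniform among the `C(K, k)` possibilities, each magnitude is
`1 + Poisson(lambda_c)` (default 0.2), and the sign is fair. The subset
factor `1/C(K, k)` matters: without it the prior is not a normalized
distribution over events, and the extra `log C(K, k)` of entropy per node
makes posterior mass grow without bound in tree size for realistic segment
counts — chains then drift into enormous trees. Matching the prior to the
simulator keeps inference consistent with the generative model and keeps
the posterior proper over event vectors.

## The sampler

A Metropolis–Hastings chain moves over `(T, V, nu)` with six structural
moves — prune & reattach, label swap, add/remove one unit of copy-number
change, add/remove a node, condense/split a node, and a
genotype-preserving prune & reattach — plus a Gaussian random walk on
`log nu` (step 0.1, bounds `10^-2..10^6`). All moves have weight 1 except
the genotype-preserving move (0.4), which rescans its entire neighbourhood
and is comparatively expensive. Invalid proposals are rejected rather than
resampled.

Design choices worth recording, since they were genuinely open:

* **Labelled-space reversibility.** Node-adding moves insert the new node
  at a uniformly chosen label (relabelling upward), and removals relabel
  downward. With this convention every move is exactly reversible on the
  space of labelled trees, and the Hastings ratios include the label-slot
  terms. This is what makes the sampler auditable: on a fully enumerable
  space (up to two nodes, two segments, bounded deltas) the visit
  frequencies of a long chain match the enumerated normalized posterior to
  a few percent total variation, which the test suite checks.
* **Condense/split.** A split assigns each child of the split node to the
  new child independently with probability 1/2, and a condense is rejected
  when parent and child events touch a common segment. Both restrictions
  exist to make the pair exactly reversible: an "inherit all children"
  split could never undo a condense of a node whose parent had other
  children, and summed deltas on a shared segment could not be
  re-partitioned.
* **Genotype-preserving reattach.** When a subtree is reattached, the moved
  node's event is rewritten as the genotype difference to its new parent,
  so every node keeps its genotype and the whole attachment table is
  unchanged. Only the event prior differs across the neighbourhood, so the
  move samples a neighbour proportionally to `exp(prior)` and the
  acceptance ratio collapses to the ratio of neighbourhood normalizers.
  Because genotypes, non-negativity and distinctness are all preserved,
  only the regained-after-zero constraint needs rechecking, which reduces
  to an O(K) test per candidate using precomputed zero-state flags.
* **Tree-size bounds during search.** Under the maximized score the
  sampling target is nearly flat in tree size once the data are explained
  (the score is a search objective, not a normalized posterior), so
  unbounded chains waste most of their time random-walking through
  oversized trees. The staged search therefore caps the walk at three
  times the starting tree size plus ten; the cap is configurable and the
  reported best tree always sits well below it.

## Staged search and robustness

The full search works stepwise. Stage 1 clusters the cells (Ward
hierarchical clustering with the Calinski–Harabasz index choosing the
cluster count — the backend is pluggable, any labelling works), averages
their segment counts weighted by cluster size, and searches for a
cluster-level tree with `n_chains` (default 10) chains of length
`4000 n`. The starting tree comes from rounding normalized counts to
integers and reading a dendrogram over the profiles, with internal-node
genotypes filled by unanimity among descendant leaves, zero-change nodes
pruned and duplicate genotypes merged so the start is always valid. A round
is robust when at least half the chains score within 5 log units of the
best; otherwise all chains restart from the best tree so far.

Stage 2 first learns `nu` on the full data with the cluster tree fixed
(a chain with only the `nu` walk enabled), then refines the tree on the
full data from the cluster tree. Full-data rounds stop when either the
score window holds or the mean pairwise tree distance among the best half
of chains falls below 0.02 (the `tau` metric below, which already counts
in single-event units). From the winning tree, each cell's maximum
likelihood attachment yields its per-bin integer profile.

## Simulator and metrics

The simulator draws a uniform composition of bins into segments, a random
tree (each node's parent uniform among the root and earlier nodes — uniform
over increasing-labelled rooted trees, which is adequate for benchmarking
and fully seedable), events from the same shifted-Poisson distribution the
prior uses, uniform cell attachments, and Dirichlet-multinomial reads with
concentration `nu_sim = 4` and exactly `reads_per_bin * n_bins` reads per
cell. Rejected (invalid) trees are resampled from scratch. Defaults mirror
the benchmark design: 10 000 bins, 20 nodes, 40 segments, 400 cells, 2–8
reads per bin.

Two metrics evaluate an inference against the retained truth. `delta` is
the RMSE between true and inferred per-cell per-bin copy numbers — it
measures calling accuracy and is defined for any caller. `tau` compares
tree structures through cells: on each annotated tree, the distance between
two cells is the total per-bin absolute state change along the path through
their most recent common ancestor, normalized by the expected event size
`n_bins/n_segments`; `tau` is the RMS difference of the two upper-triangular
cell-pair matrices. When segmentations differ, both matrices are normalized
by the reference tree's event-size unit so they are compared on one scale.

What the simulator does *not* emulate: GC/mappability bias (the model
consumes corrected counts by contract), cycling-cell artefacts, per-bin
outliers, or doublets. Passing the recovery tests therefore demonstrates
correctness of the inference machinery under the stated generative model,
not robustness to uncorrected real-data artefacts.

## Problem sizes used by the test suite

The packaged tests run the oracle-equivalence checks at `m <= 20`,
`n <= 8`, `K <= 6` (500 instances), the sampler audit on the enumerable
two-node space with a 200 000-iteration chain, and parameter recovery on
ten seeded replicates at 1000 bins, 20 segments, 10 nodes, 50 cells and 4
reads per bin with chains shortened to 1000 iterations per node — sizes
chosen so the whole suite runs on a laptop in minutes while still
exercising every stage at realistic depth. The full-scale benchmark grid
(40 trees per setting at 10 000 bins) is reproducible through the
`inst/exec/scnatree` command-line wrapper but is deliberately not part of
the default test run.

## Worked example

```{r example}
tree <- cna_tree(parents = c(0, 1, 2, 2, 1),
                 events = list(c(S1 = 1, S2 = 1), c(S2 = 1, S3 = 1),
                               c(S1 = -1), c(S4 = -1), c(S1 = 1)),
                 n_segments = 5)
tree
compute_genotypes(tree)
```

The clone attached below events 1 and 5 has profile `(4, 3, 2, 2, 2)`: two
gains on S1, one on S2, baseline elsewhere.

```{r pipeline}
set.seed(7)
sim <- generate_dataset(sim_settings(n_bins = 300, n_nodes = 4,
                                     n_segments = 8, reads_per_bin = 8,
                                     n_cells = 40))
fit <- scnatree(sim$counts, seed = 1,
                config = search_config(n_chains = 4,
                                       chain_length_factor = 500,
                                       max_rounds = 2))
summary(fit)
delta_rmse(sim$profiles, fit$cnv)
delta_rmse(sim$profiles, matrix(2L, nrow(sim$counts), ncol(sim$counts)))
```

## Known limitations

* Breakpoint detection uses a windowed statistic with a robust global
  threshold; breakpoints private to very few cells at low depth fall below
  it, merging adjacent true segments. Downstream calls remain integer and
  tree-consistent, but boundary placement inherits this resolution limit.
* The `nu` estimate is a point value from the maximized score, not a
  posterior summary; with few cells it can sit well away from the
  generating value while leaving calls unaffected.
* Whole-genome duplication is handled by comparing runs under alternative
  root ploidies (`compare_root_ploidies()`); the package reports score
  differences and deliberately makes no automatic ploidy decision, since
  absolute ploidy is not identifiable from proportional read depth alone.
* Allele-specific states, per-locus likelihoods and gene-level annotation
  of events are out of scope.
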