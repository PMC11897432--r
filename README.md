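# scnatree

Joint copy-number calling and event-tree reconstruction for shallow
whole-genome single-cell DNA sequencing.

## The problem

High-throughput single-cell DNA protocols sequence hundreds of tumour cells
at ~0.1x coverage: a few reads per genomic bin per cell. At that depth,
calling integer copy numbers cell by cell is hopeless — but tumour cells
share an evolutionary history, and cells of the same subclone share the same
copy-number profile. `scnatree` turns that structure into statistical power:
it jointly infers a **CNA event tree** (a rooted tree whose nodes carry sets
of segment-level amplifications and deletions) and the **attachment** of
every cell to a node. A cell's integer profile is the root ploidy plus all
events on its root path, so reads are effectively pooled within each
inferred clone.

It is aimed at anyone analysing binned, GC/mappability-corrected single-cell
read-count matrices (e.g. from 10x CNV or DLP-style protocols) who wants
per-cell integer copy numbers *and* the event history that produced them.

## The model

After multi-cell breakpoint detection partitions the `B` bins into `K`
segments of sizes `s_k`, a cell `j` attached at node `σ_j` of tree `(T, V)`
has segment states `c_kj(T,V,σ_j)` and read probabilities

    p_kj = c_kj s_k / Z_j,   Z_j = Σ_k c_kj s_k

(fully deleted segments keep a small floor `η = 1e-4`). Segment counts are
Dirichlet-multinomial with concentration `νZ_j` (inverse overdispersion `ν`,
sampled by a log-space random walk), which tends to the multinomial for
large `ν`. Trees are scored either by marginalizing each cell over all
attachments ("sum", with an `exp(-κn)` size penalty) or by placing each cell
at its best attachment ("max", the default). Trees that drive a state
negative, regain a fully deleted segment, or repeat a genotype at two nodes
are forbidden. A Metropolis–Hastings sampler with six structural moves plus
the `ν` walk searches the space; a staged scheme (cluster-level tree first,
then full data, with multi-chain robustness checks) keeps the search
practical. A full generative simulator and the evaluation metrics `Δ`
(per-bin copy-number RMSE) and `τ` (RMS difference of cell-pair event-path
distance matrices) are included.

## Worked example

The five-segment example tree with parent vector `(0,1,2,2,1)` and events
`(+S1+S2, +S2+S3, -S1, -S4, +S1)`:

```r
library(scnatree)
tree <- cna_tree(parents = c(0, 1, 2, 2, 1),
                 events = list(c(S1 = 1, S2 = 1), c(S2 = 1, S3 = 1),
                               c(S1 = -1), c(S4 = -1), c(S1 = 1)),
                 n_segments = 5)
compute_genotypes(tree)
#>   S1 S2 S3 S4 S5
#> 0  2  2  2  2  2
#> 1  3  3  2  2  2
#> 2  3  4  3  2  2
#> 3  2  4  3  2  2
#> 4  3  4  3  1  2
#> 5  4  3  2  2  2
```

Row `5` is the clone that experienced the `+S1+S2` gain and then a further
`+S1` gain: profile `(4, 3, 2, 2, 2)` across the five segments. The full
pipeline on simulated data:

```r
set.seed(7)
sim <- generate_dataset(sim_settings(n_bins = 300, n_nodes = 4,
                                     n_segments = 8, reads_per_bin = 8,
                                     n_cells = 40))
fit <- scnatree(sim$counts, seed = 1,
                config = search_config(n_chains = 4,
                                       chain_length_factor = 500,
                                       max_rounds = 2))
fit
#> Copy-number event tree fit
#>   40 cells, 300 bins, 5 segments
#>   tree: 4 event node(s); score (max) = -116801.6; nu = 2.920021
delta_rmse(sim$profiles, fit$cnv)                                  # inferred
#> [1] 0.132916
delta_rmse(sim$profiles, matrix(2L, nrow(sim$counts), ncol(sim$counts)))  # diploid baseline
#> [1] 0.3855732
```

The inferred per-bin profiles sit three-fold closer to the truth (RMSE
0.13 copies) than the all-diploid baseline (0.39); `summary(fit)` lists each
node's genotype and how many cells attach to it, and `plot(fit)` draws the
tree. `predict()`, `simulate()`, `residuals()` and `logLik` behave as for
any fitted model. A thin command-line wrapper with `simulate`,
`detect-breakpoints`, `infer` and `evaluate` subcommands is installed at
`inst/exec/scnatree`.

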