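# clonetrace

Clonal lineage tracing and gene-module analysis for B-cell repertoire
studies that combine droplet single-cell transcriptomics (with paired
V(D)J capture) and bulk heavy-chain libraries from multiple tissue
compartments — the design used to ask where gut-induced plasma-cell
lineages end up in the rest of the body.

It is written for immunologists and computational biologists who have
AIRR-style rearrangement tables and a gene × cell count matrix in hand
(annotation, denoising and clustering already done upstream) and need the
bespoke downstream computations as tested, reusable functions rather than
one-off scripts.

## What it computes

**Single-cell QC and gene modules.** Cells failing any of the standard
filters are removed in documented order: mitochondrial fraction > 10%,
fewer than 1200 UMIs or 500 detected genes (strict), upstream doublet
flags, more than one IG heavy or light chain; genes seen in fewer than 10
cells are dropped. After median-library log-normalization and
highly-variable-gene selection, genes are clustered into modules by the
unsigned weighted-correlation construction

> a_ij = |cor(g_i, g_j)|^β,  TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij),

with Ward clustering of 1 − TOM cut to a fixed module count. Per-cell
module scores (mean of ℓ2-rescaled gene vectors, bounded to [0,1]) are
tested against each cell cluster with a Gaussian GLM on the one-vs-rest
indicator; the reported statistic is the percent residual-deviance
difference 100 · (D_null − D_fit)/D_null = 100 · R².

**Clonal lineages.** Heavy chains from single-cell and bulk sequencing are
clustered together: identical V and J allele, identical CDR3 length, and
single-linkage closure of "CDR3 mismatch fraction ≤ 20%". Lineages whose
cells disagree on the light chain are split by light V/J/CDR3-length key,
and chains without a light chain rejoin the sub-lineage at minimum
Levenshtein distance to a single-cell reference CDR3. Isotypes are called
from constant-region identity; SHM is the V-gene mismatch percentage
against germline.

**Cross-tissue tracing.** Caecal lineages are traced into each bulk
library with duplicate-weighted relative abundance, plus per-compartment
SHM distributions, heavy-chain V/J usage and isotype composition.

**Synthetic data.** `simulate_repertoire()` and `simulate_expression()`
generate study-shaped inputs (power-law clones, bounded CDR3 divergence,
per-tissue dissemination, IgA-dominated isotypes; cluster-structured
negative-binomial counts with planted modules and QC failures) together
with ground truth, so recovery is measurable without any external data.

## Worked example

```r
library(clonetrace)

dir <- tempfile()
write_fixtures(dir)                    # default bundle: 50 lineages, 1500 heavy chains,
                                       # 410 cells x 800 genes, seed 1
res <- run_pipeline(dir, file.path(dir, "out"))

res$qc$report
#>   rule               n_removed n_cells
#> 1 high_mito_fraction         2      NA
#> 2 low_umi_or_genes           4      NA
#> 3 doublet                    2      NA
#> 4 multi_ig_chain             2      NA
#> 5 retained                  NA     400

res$manifest$lineage_ari
#> [1] 1

head(res$isotypes, 3)
#>   isotype count percentage
#> 1 IgA       307      85.0
#> 2 IgM        23       6.37
#> 3 IgG2      14       3.88

glance(res$association)
#>   n_modules n_clusters n_cells max_percent_deviance
#> 1         8          3     400                 87.2
```

Reading the output: the ten planted QC failures are the ten cells removed
(each by the one rule it violates); an adjusted Rand index of 1 means the
inferred lineage partition is identical to the simulated truth; the
isotype table recovers the configured IgA-dominated mixture (83% expected,
85% observed among 361 paired cells at this seed); and the strongest
module–cluster association explains 87% of that module score's deviance.
Plots: `autoplot(res$association)`, `plot_lineage_trace(res$trace)`,
`plot_shm_by_compartment(res$shm)`, `plot_vj_usage(res$usage)`.

A thin command-line wrapper ships at `inst/cli/clonetrace.R`
(subcommands `simulate`, `qc`, `modules`, `lineages`, `trace`,
`pipeline`).

## Scope

Upstream steps are consumed, not reimplemented: V(D)J annotation and
germline inference, amplicon denoising and chimera removal, doublet
detection, graph clustering and embeddings. See the methods vignette
(`vignettes/clonetrace-methods.Rmd`) for the model details, parameter
meanings, generator assumptions and known limitations.
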