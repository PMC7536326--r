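# wcadrift

Tools for finding the genes that drive progressive, heritable
transcriptional deregulation across generations — the kind of slow drift
seen in germlines of chromatin-mutant *C. elegans* lines that become
sterile over a handful of generations. The package is aimed at anyone with
a small replicate-lineage RNA-seq design: a few independent lineages, each
sampled at ordered generation states (here `P0`, `F2`, `F4_fertile`,
`F4_sterile`), and the question "which genes change consistently along the
path to the terminal state, in every lineage, despite large
lineage-to-lineage differences?"

## The statistic at the core

Lineage identity dominates ordinary PCA of such data, hiding the shared
trajectory. The package therefore implements **within-class analysis
(WCA)**: PCA performed after removing each lineage's mean expression
profile. For the samples-by-genes matrix \(X\) (log2(x+1) of
median-of-ratios-normalized counts, restricted to expressed genes):

1. center every gene: \(X_c = X - \bar{x}\);
2. subtract per-gene class means: \(W_{ij} = X_{c,ij} - \bar{x}_{j}^{(class(i))}\);
3. eigendecompose \(\tfrac{1}{n} W^\top W\).

The class-centered matrix \(W\) has zero class means by construction, so
lineages overlay on the components and the first component traces the
shared path from fertile to sterile states. Its unit-norm gene loadings
are the **WCA scores**: positive for genes progressively upregulated along
the path, negative for downregulated genes. The most extreme scores define
the **contributor** lists (defaults: 1000 up, 250 down), which are then
characterized by per-gene trajectories (early "priming" `P0→F2`, later
"amplification" toward the sterile branch), exact hypergeometric
enrichment against gene sets (GMT), chromosome distributions (X versus
autosomes), and a Wilcoxon comparison of X-linked versus autosomal scores.

A negative-binomial simulator (`simulate_counts()`) generates count
matrices with this exact design — planted up/down contributors whose log2
effect grows linearly with state severity, lineage-private deregulation,
library-size variation, and an X-enrichment of planted up genes — so every
stage is testable against known truth.

## Worked example

```r
library(wcadrift)

sim <- simulate_counts(simulation_params(n_genes = 2000, seed = 1))
sf  <- estimate_size_factors(sim$counts)
lm  <- log_transform(normalize_counts(sim$counts, sf))
universe <- filter_expressed(lm, threshold = 5)
length(universe)
#> [1] 1014

res <- wca(t(lm[universe, ]), sim$design$lineage,
           state_rank = match(sim$design$state, sim$params$states))
res
#> within-class analysis: 12 samples, 3 classes, 9 components
#> PC1 pve: 73.6% of within-class variance (within/total = 0.87)
```

The first within-class component captures 73.6% of the lineage-corrected
variance, and sample coordinates on it are ordered along the path to
sterility within each lineage:

```r
res$sample_coordinates[sim$design$lineage == "L1", 1]
#>         L1_P0         L1_F2 L1_F4_fertile L1_F4_sterile
#>    -22.429082     -6.052697      1.990855     26.490924
```

Selecting contributors from the WCA scores recovers all 200 planted
upregulated genes in this run, and the planted X-desilencing signal is
detected in the contributor list:

```r
scores <- wca_scores(res)
sets <- select_contributors(scores, n_down = 50, n_up = 200)
truth_up <- sim$truth$gene_id[sim$truth$label == "up_contributor"]
mean(truth_up %in% sets$up)
#> [1] 1

cd <- chromosome_distribution(sets$up, sim$annotation, universe)
subset(cd$per_chromosome, set == "X")
#>   set    N   K   n   k     fold       p_over p_under
#> 6   X 1014 221 200 100 2.294118 7.342084e-24       1
```

Here 100 of the 200 up-contributors are X-linked against an expectation of
~44 (fold 2.29, hypergeometric p ≈ 7e-24). Enrichment of any gene list
against the published contingency counts works the same way; with 389
transcription-factor genes in a 7,238-gene universe and 101 of them among
1,250 contributors:

```r
fold_enrichment(101, 389, 1250, 7238)
#> [1] 1.50342
hypergeom_tail(101, 389, 1250, 7238, "over")
#> [1] 6.069789e-06
```

The full pipeline (normalize → filter → PCA → difference PCA → WCA →
contributors → trajectories → enrichment, with TSV outputs and a
checksummed JSON manifest) runs via `run_all(pipeline_config(...))`, or
from the shell through `inst/cli/wcadrift.R` subcommands
(`simulate`, `normalize`, `wca`, `contributors`, `enrich`, `run`).

## Documentation

The methods vignette (`vignettes/wcadrift-methods.Rmd`) describes the
model, the simulator's stated world and its limits, numerical conventions
(sign orientation, tie-breaks, thresholds), and known limitations,
including why the differential-expression stage is a deliberately simple
surrogate for a full NB-GLM.
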