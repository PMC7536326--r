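---
title: "Methods: within-class analysis of transgenerational transcriptome drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-class analysis of transgenerational transcriptome drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcadrift)
```

# The problem and the model

The package analyses a replicate-lineage, ordered-state RNA-seq design:
a small number of independent mutant lineages (classes), each sampled once
per generation state along a path from fertility to sterility
(`P0`, `F2`, `F4_fertile`, `F4_sterile`). Two facts shape the method:

* lineage identity is the dominant source of variance — each lineage
  derails in its own way, so ordinary PCA separates lineages rather than
  states;
* the biological question concerns the *shared* component of drift: genes
  that move in the same direction, in every lineage, increasingly with
  state severity.

Within-class analysis (WCA) addresses both. Writing $X$ for the
samples-by-genes matrix of $\log_2(x+1)$ normalized expression restricted
to expressed genes, the procedure is: (1) center each gene over all
samples; (2) subtract from each sample its lineage's mean profile;
(3) eigendecompose the covariance of the class-centered matrix under
uniform row weights $1/n$. Step 2 removes between-lineage variance
exactly (class means of the centered matrix are zero to machine
precision, asserted in the tests), so the leading eigenvector captures
the largest mode of *within*-lineage variation — empirically, the ordered
path to sterility. The unit-norm gene loadings on this first component
are the WCA scores; samples' projections on it give per-lineage
trajectories that overlay across lineages.

Eigenvalues use the $1/n$ (not $1/(n-1)$) convention throughout, matching
the classical duality-diagram formulation of PCA with uniform row
weights; `pve` is each eigenvalue as a percent of the within-class total,
and `within_total_ratio` reports how much of the globally centered
variance survives class centering. Components are truncated at
$\min(n_\text{samples} - n_\text{classes},\, n_\text{genes})$ and
eigenvalues below $10^{-12}$ of the largest are dropped as numeric zeros.

## Sign convention

Eigenvectors are sign-ambiguous. Component 1 is oriented so that the
Spearman correlation between sample coordinates and the per-sample state
severity rank is positive; genes upregulated along the path then carry
positive scores and downregulated genes negative scores, which is what
makes "top/bottom of the score distribution" a meaningful directional
statement. When no state ranking is supplied (or the correlation is
degenerate), the fallback — used for all other components — is to make
the largest-magnitude loading positive. This is deterministic under
permutations of gene order (ties break toward the earlier column).

## Degenerate designs

Two limits are accepted with a warning rather than an error, because both
are well defined linear-algebraically even though scientifically
degenerate: a single class covering all samples (class centering reduces
to global centering; WCA equals plain centered PCA, asserted in the
acceptance suite) and all-singleton classes (the class-centered matrix is
identically zero; no components are returned).

# Preprocessing

* **Size factors** are classical median-of-ratios: the reference is the
  per-gene geometric mean over samples, restricted to genes positive in
  every sample, and each sample's factor is the median ratio to that
  reference. The even-count median is the midpoint mean. An exactly
  $2\times$-scaled pair yields $(2^{-1/2}, 2^{1/2})$ — the reference sits
  geometrically between the samples — and this is pinned in the tests.
* **Transform**: $\log_2(x+1)$, elementwise, on normalized values.
* **Expression filter**: a gene enters the analysis universe when its
  *maximum* log expression over samples is strictly greater than the
  threshold (default 5). The strictness matters at the boundary (a gene
  peaking at exactly 5.0 is excluded) and is tested. The accompanying
  per-gene (max, sd) summary reproduces the diagnostic used to choose the
  threshold: below it, sd rises with max (background noise); above it,
  sd reflects condition differences.
* **BH adjustment** is the step-up rule
  $\tilde p_{(i)} = \min_{j \ge i} \min(1, m p_{(j)}/j)$, implemented
  directly and checked against a brute-force oracle.

## The differential-expression surrogate

The per-state "number of deregulated genes vs P0" counter exists to
reproduce a counting behaviour, not to be a serious DE engine — the
pipeline's downstream stages never consume its output. It compares
normalized group means (lineages as replicates) with a Wald statistic on
the log2 ratio, a delta-method standard error, and a method-of-moments
NB dispersion in which the across-gene *median* of per-gene moment
estimates serves as a common dispersion: per-gene estimates on ~4 df are
far too noisy to divide by, and full pooling is the stable choice in a
simulator whose true dispersion is shared. Two consequences, both
deliberate and test-pinned: power on large planted effects
($\ge 4$ log2 units at low dispersion) exceeds 95%, and the null is
mildly anti-conservative (the type-I fraction at $p<0.05$ is bounded at
0.075 in the tests, not 0.05). A full NB-GLM with dispersion shrinkage
is explicitly out of scope. The default reporting threshold for adjusted
p-values is $10^{-5}$; the printed threshold this mirrors is typographically
ambiguous ("10e-6"), so the value is a configuration knob, read literally
by default.

# The synthetic world

`simulate_counts()` draws counts as NB with mean
$\mu_{g,(l,s)} = sf_{(l,s)} \cdot 2^{\beta_g + \delta_g t(s) + \pi_{g,l} t(s)}$
and variance $\mu + \alpha \mu^2$ ($\alpha = 0$ degenerates to Poisson).
Defaults, fixed once and used by the acceptance suite:

| parameter | default | why |
|---|---|---|
| genes | 8000 | desk-scale stand-in for a ~20k transcriptome |
| design | 3 lineages × 4 states × 1 library | the replicate-lineage design under study |
| severity $t(s)$ | 0, 1, 1.5, 3 | monotone worsening; fertile F4 between F2 and sterile F4 |
| planted up / down | 200 / 50 | a minority of deregulated genes, biased toward upregulation |
| effect | 1.0 log2 per severity unit | moderate drift: 8× at the sterile endpoint |
| lineage-private genes | 100 at 1.0 log2 | the lineage-specific deregulation WCA must ignore |
| baseline mixture | log2-means 2 / 8 (sd 1), 60% background | the filter threshold 5 bisects the two populations |
| dispersion $\alpha$ | 0.05 | typical bulk RNA-seq biological variability |
| library factors | lognormal, sdlog 0.15, geometric mean 1 | realistic depth variation |
| X fraction | 0.5 (planted up) vs 0.15 (rest) | the X-desilencing signal to be detected |

The severity multiplier acting linearly in log space is a modelling
choice; only monotone worsening is biologically given. Planted and
lineage-private genes draw baselines from the expressed mixture component
so that recovery is well defined (a planted gene filtered out of the
universe could never be recovered).

What the generator does *not* emulate: gene length and GC bias, batch
effects beyond library size, count correlation between genes, splicing,
and any real chromosome structure beyond a single X-assignment
probability. A green recovery test therefore establishes that the
machinery isolates the planted shared signal under NB noise and
lineage-private interference — not that any particular biological dataset
will behave as cleanly.

## A compositional artifact worth knowing about

With many more planted up- than downregulated genes, high-severity
libraries genuinely contain more RNA from the planted set; estimated
median-of-ratios factors absorb a sliver of that signal, which tilts the
normalized background down slightly — enough to flip the *sign count* of
near-zero background scores negative even though the planted excess is
positive. The sign-asymmetry power test in the suite therefore normalizes
by the simulator's true factors; with estimated factors the asymmetry
statistic still works, but measures planted excess *minus* compositional
tilt. Real data have the same property; score sign counts should be read
with this in mind. Extreme-score selection is essentially unaffected
(the tilt is orders of magnitude below contributor-scale loadings).

# Contributors, trajectories, enrichment

* **Selection** is top-$N$ by signed score (defaults 250 down / 1000 up,
  the published list sizes), restricted to genes of the required sign,
  ties at a boundary broken lexicographically by gene id so results do
  not depend on input order.
* **Priming**: a gene is primed when its `P0→F2` change is nonzero with
  the same sign in all lineages.
* **Amplification**: per lineage, the `F2→F4_sterile` change must go
  strictly further in its own direction than the `F2→F4_fertile` change
  ($d = \mathrm{sign}(\Delta_s) \ne 0$ and $d\,\Delta_s > d\,\Delta_f$);
  a configurable lineage quorum (default: all) aggregates the per-lineage
  flags. The comparison deliberately does not constrain the sign of the
  fertile-branch change: a noisy near-zero fertile change flips sign
  frequently, and the scientific statement is about the sterile branch
  exceeding it.
* **Enrichment** is the exact hypergeometric tail, computed by
  log-sum-exp over log densities so that p-values at the $10^{-100}$
  scale retain relative accuracy; both tails are always reported
  (depletion is as informative as enrichment), raw by default with BH as
  an option. Fold enrichment is $kN/(Kn)$. The default universe is the
  filtered (WCA) gene list and is always explicit in outputs. For
  chromosome distributions both a per-chromosome hypergeometric test and
  a global chi-square goodness-of-fit are computed, since either may be
  wanted and the choice between them is a reporting decision, not a
  mathematical one.

# Pipeline and determinism

`run_all()` chains the stages, writes every intermediate as TSV (tab
delimiter, no quoting, 10-significant-digit floats so checksums are
platform-stable) and records MD5 checksums per stage in a JSON manifest;
identical config, inputs and seed give identical checksums, and a stage
failure aborts with the stage name, leaving the manifest marked
incomplete. The only random stage is simulation, seeded from the config.

# Known limitations

* One library per (lineage, state) cell is the design under study;
  the simulator accepts replicates, but `build_diff_matrix()` then
  averages cells before differencing rather than modelling
  within-cell variance.
* The DE surrogate's calibration is approximate by construction (see
  above); its counts are indicative, not inferential.
* WCA assumes the shared drift is approximately linear in the
  class-centered space; a strongly non-monotone shared trajectory would
  load on later components and escape the score ranking.
* Enrichment p-values are raw hypergeometric probabilities; with many
  gene sets, use the BH option.
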