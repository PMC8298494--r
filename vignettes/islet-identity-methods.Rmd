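---
title: "Methods: hormone gating, identity gene sets and differential expression for islet transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hormone gating, identity gene sets and differential expression for islet transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletID)
```

## The scientific problem

Adult pancreatic islets contain four monohormonal endocrine cell types —
α (glucagon, *Gcg*), β (insulin, *Ins2*), δ (somatostatin, *Sst*) and
γ/PP (pancreatic polypeptide, *Ppy*) — plus rare *bihormonal* cells that
express *Ppy* together with a second hormone. Characterising these hybrids
from single-cell RNA-seq requires three statistical steps that this package
implements as a reusable pipeline:

1. **Hormone gating.** Decide, per cell and per hormone, whether the hormone
   is expressed. Because hormone transcripts are either near-absent or
   massively abundant, the distribution of log-normalized expression across
   all cells is bimodal; the expression threshold is the *antimode*, the
   density minimum between the two principal modes.
2. **Identity gene sets.** A cell type's identity (ID) genes are the genes
   upregulated in that type against *each* of the other three types in
   pairwise differential expression — the intersection of the three
   upregulated sets. Bihormonal populations are then profiled by the overlap
   between their upregulated genes and the partner type's ID set.
3. **Differential expression.** Single-cell comparisons use a negative
   binomial (NB) GLM per gene with nuisance covariates and Bonferroni
   correction; sorted-population bulk comparisons use median-of-ratios size
   factors, gene-wise NB Wald tests, normal-prior log-fold-change shrinkage
   and Benjamini–Hochberg adjustment.

Because the real datasets are large and partly restricted-access, the package
ships a synthetic islet generator with planted ground truth; all
property-based validation runs against it.

## Normalization and quality control

Cells are kept when they have at least 1,000 UMIs, at least 500 detected
genes and at most 7% mitochondrial UMIs — all boundaries inclusive, and the
mitochondrial fraction computed on raw counts before any gene handling.
Normalization is the standard counts-per-10,000 log transform on the natural
scale,

$$v_{gc} = \ln\!\left(1 + 10^4 \frac{x_{gc}}{\sum_g x_{gc}}\right),$$

which maps zeros to zero exactly, so sparsity is preserved and all
downstream "fold change" language refers to natural-log units in the
single-cell branch.

## Antimode gating

For each hormone the density of $v_{gc}$ across *all* cells (zeros included;
the non-expressing mass is the left mode) is estimated with a Gaussian
kernel on ≥512 evenly spaced points, bandwidth by Silverman's rule unless
overridden. Local maxima are located by the sign change of the first
difference; the two highest are the principal modes; the threshold is the
grid point of minimum density strictly between them. Confidence is the
bimodality amplitude

$$A = \frac{h_\text{low} - h_\text{anti}}{h_\text{low}} \in [0, 1],$$

with $h_\text{low}$ the smaller principal-mode height and $h_\text{anti}$
the antimode height; $A \le 0.05$ flags a low-confidence threshold.

Two numerical choices matter here:

* **Mode floor.** Kernel densities of finite samples develop tiny wiggles in
  their tails; a maximum below 1% of the global peak is treated as noise,
  not a mode. Without this guard a strictly unimodal sample can masquerade
  as bimodal. Genuine hormone modes in islet-like data sit far above this
  floor (the expressing mode carries ≥5–10% of cells).
* **Ties.** A cell whose expression equals the threshold exactly is *not*
  expressing — the gate is a strict inequality.

Cells are labelled by the sorted "+"-joined set of expressed hormones
(`"Gcg+Ppy"`; anchored views can display `"Ppy+Gcg"`); the empty set is
`"none"` and flagged non-endocrine. A cluster-consistency filter then keeps
monohormonal cells only inside their type's cluster and bihormonal
anchor-positive cells only inside the designated hybrid cluster, recording
the exclusion reason for everything else.

## Single-cell differential expression

Candidate genes must first pass a fold-change floor of 0.5 natural-log
units, where

$$\mathrm{lnFC}(g) = \ln\frac{\overline{\exp(v)-1}_A + 1}{\overline{\exp(v)-1}_B + 1},$$

the expm1-mean-with-pseudocount convention standard in single-cell toolkits
(the 0.5 floor is only meaningful relative to a stated formula). Candidates
are tested with a per-gene NB regression of *raw* counts on the group
indicator plus nuisance covariates — experimental replicate, log total UMIs
and log detected genes by default, each dropped automatically when constant
— with gene-wise maximum-likelihood dispersion and a Wald test on the group
coefficient. Non-convergent genes fall back to the Poisson limit; genes
failing both are reported with `p = NA` and never enter significant sets.
P-values are Bonferroni-corrected against the *total* number of genes in
the dataset, not the candidate count. The upregulated set is
`lnFC ≥ 0.5 & p_adj ≤ 0.05`, ordered by fold change.

The Wald choice (rather than a likelihood-ratio test) matches common
single-cell practice; the test suite bounds the discrepancy against a
profile-likelihood grid oracle on a tiny instance in the moderate-p regime,
where the quadratic approximation is accurate.

## Bulk differential expression

The bulk branch is deliberately self-contained: per pairwise comparison,
genes with mean raw count below 5 are discarded (boundary retained), size
factors are the median across always-expressed genes of the ratio to the
gene's geometric mean, and each gene gets an NB GLM with a log size-factor
offset, gene-wise ML dispersion (Poisson fallback) and a Wald test,
BH-adjusted. There is no empirical-Bayes dispersion-trend sharing across
genes: validation is by simulation recovery, not by replicating any
external tool's exact numbers (an installed reference implementation is
used only as an independent cross-check in the tests, where median
fold-change agreement is within 0.1 log2 units).

Shrinkage is the posterior mode under a zero-centered normal prior,

$$\tilde\beta_g = \hat\beta_g \frac{\sigma_0^2}{\sigma_0^2 + \mathrm{se}_g^2},$$

which contracts every estimate toward zero and never flips a sign. The
`"auto"` prior matches the prior's 95th percentile to the 95th percentile of
the observed $|\hat\beta|$ — a deterministic, data-driven rule recorded in
the result's provenance. DE calls are $|\tilde\beta| \ge 1$ and
$p_\text{adj} \le 0.05$, both boundaries inclusive.

## Scored-cell quantification

Count tables transcribed from scored images or cell tallies (unit,
category, numerator, denominator) are summarised as pooled shares
(share-of-total for partitions, numerator/denominator otherwise) and as
per-unit percentages with mean ± s.e.m. across biological units. Display
formatting is one-decimal *truncation* for single-cell-derived shares and
integer rounding for ID-overlap percentages — the two conventions the source
tallies use — with raw fractions always retained. Group comparisons use a
two-sided Mann–Whitney test: exact enumeration of all assignments (mid-ranks
for ties) up to combined $n = 12$, normal approximation with tie and
continuity corrections above.

## The synthetic islet generator

`simulate_sc()` draws each cell's counts from NB distributions with mean
$\exp(\text{type profile} + \text{batch}) \times \text{libsize}$, dispersion
shared per gene — exactly the model the DE stages assume, which makes
parameter recovery a fair test. Its defaults *are* the study conditions of
the validation suite:

| parameter | default | rationale |
|---|---|---|
| composition | α 0.35, β 0.45, δ 0.10, γ 0.10 | realistic adult islet |
| bihormonal shares of the γ pool | 0.24 / 0.05 / 0.04 (γ-α / γ-δ / γ-β) | observed rarity structure |
| hormone high mean | $\ln 800$ | hormone transcripts dominate islet libraries |
| hormone low mean / dropout | $\ln 0.1$ / 0.6 | non-expressing mass sits at zero (no ambient-RNA modelling) |
| ID genes | 25 per type, lnFC 1.2, baseline $U(1, 2.5)$ | marker-like abundance; the pseudocount-1 lnFC of every planted gene stays above the 0.5 floor |
| library size | lognormal, σ = 0.3 | typical depth spread |
| dispersion | 0.3 (single-cell), 0.05 (bulk) | single cells are far more overdispersed than sorted-bulk replicates |
| replicates | 2, gene-wise batch SD 0.1 | two-experiment design |
| cluster mislabel rate | 0.02 | exercises the consistency filter without a clusterer |

Bihormonal cells draw *both* hormones from the high component and half of
the partner type's ID genes from the partner profile, so their upregulated
genes genuinely overlap the partner identity. Cluster labels are
truth-derived with a small mislabel rate — clustering itself is out of
scope. Ground truth records every cell's type and hormone set, every gene's
planted role and fold change, and the expected identity set of each type
(planted ID genes plus the type's own hormone gene).

What the generator does *not* emulate: ambient RNA and barcode collisions,
dropout that depends on cell state, mean–variance trends across genes,
non-NB zero inflation of non-hormone genes, and real cluster uncertainty.
Passing tests therefore demonstrate correctness of the gating, testing and
set logic under the stated model, not robustness to those artefacts.

## Validation scale and reproducibility

The suite validates at sizes chosen to exercise the asymptotics the methods
rely on while staying desk-sized: the end-to-end recovery run uses the
default 5,000 cells × 2,000 genes; single-cell null calibration uses 20
seeds of 5,000 genes at 200 + 200 cells; power uses 100 seeds at 300 cells
per group; bulk recovery uses 50 seeds of 3 + 3 samples and the null FDR 20
seeds of 2,000 genes. Every random stage is seed-pinned, and a fixed config
plus seed reproduces output tables byte-for-byte, including through the
command-line interface.

## Known limitations

* Densities with more than two genuine modes are not decomposed; the two
  highest maxima win. Per-replicate thresholds are deliberately not
  offered — gating is defined on the pooled dataset.
* Gene-wise dispersion estimation with 3 samples per group is noisy; the
  bulk branch compensates with shrinkage but will not match
  moderated-dispersion tools gene-for-gene at tiny $n$.
* The ortholog mapper is name-based (uppercase fallback or a supplied
  two-column table); it does not consult genome annotation.
* Human identity sets are consumed as gene-list files, never recomputed:
  the underlying human data is restricted-access, and only the overlap
  logic is owned here.
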