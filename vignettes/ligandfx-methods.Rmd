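---
title: "Inferring condition-dependent ligand effects from single-cell variability"
author: "ligandfx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring condition-dependent ligand effects from single-cell variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandfx)
```

## The inference problem

Within a tumour (or any tissue), not every receptor-bearing cell is engaged
by its cognate ligand, and ligand abundance varies with experimental
condition — for instance between chromosomally unstable (CIN^high),
chromosomally stable (CIN^low) and *Sting1*-depleted tumours. `ligandfx`
turns this intrinsic variability into a test for which ligand–receptor
interactions actually elicit a transcriptional response in the
receptor-expressing ("target") cell type, without any prior knowledge of
downstream target genes.

Two nested questions are asked per gene, per (receptor, target cell type):

1. **Target test.** Does the gene differ between receptor-detected
   (target+, at least one receptor molecule observed) and receptor-null
   cells of the target type? The hurdle model

   $$Y \approx \mathrm{CDR} + \mathrm{condition} + \mathrm{target}$$

   is compared against the model without `target` by likelihood ratio.
   `CDR`, the cellular detection rate (fraction of genes detected per
   cell), is the standard nuisance covariate for single-cell regressions;
   `condition` is a full categorical over all condition levels present.

2. **Interaction test.** Is that association itself condition-specific?
   Restricted to the two levels of one contrast (e.g. CIN^high vs
   CIN^low), the model gains a binary indicator marking cells that are
   both target+ and from the condition of interest:

   $$Y \approx \mathrm{CDR} + \mathrm{condition} + \mathrm{target} +
     \mathrm{target{:}condition_{interest}}$$

   and the likelihood ratio drops only that indicator.

The logic of the two tests together is the package's core discriminator:
a gene merely co-expressed with the receptor (an unobserved confounder)
passes the target test in *every* condition alike and therefore fails the
interaction test; a genuine ligand effect responds only where the ligand
is available, and passes both. The contrast is only informative for
interactions whose ligand is differentially available, which the **ligand
condition test** (`Y ~ CDR + condition` within the donor cell type)
establishes, with the fold-change sign oriented toward the first
(numerator) contrast level.

## The hurdle engine

Single-cell expression is zero-inflated, so each model above is fit in
two parts: logistic regression on the detection indicator `1[y > 0]`, and
Gaussian regression on log-normalized expression among detected cells.
Both parts are plain maximum likelihood; the test statistic is twice the
summed log-likelihood gain over both parts, referred to a chi-square
whose degrees of freedom count the dropped parameters in the parts that
are non-degenerate in both fits. We deliberately do not apply
empirical-Bayes variance shrinkage: plain ML keeps the likelihood exactly
reproducible by an independent numerical maximizer, which is how the
engine is validated in the test suite (20 random tiny instances against a
BFGS/Nelder–Mead oracle, at 10^-6^ relative tolerance).

Numerical choices worth knowing:

* **Degeneracy.** A gene detected in all or no cells contributes no
  discrete information (0 df); fewer than `k_min = 3` detected cells, or
  zero residual variance, disables the continuous part. A test whose
  comparable degrees of freedom vanish is reported `degenerate` with
  p = 1 and is excluded from the BH family (family = genes with a valid
  p-value).
* **Perfect separation.** When the logistic part separates (common for a
  receptor tested against its own detection indicator), the fit falls
  back to a deterministic ridge-penalized optimization (L2 penalty
  10^-6^) and is flagged; the reported log-likelihood is the unpenalized
  one at the penalized optimum.
* **Effect size.** The reported log2 fold change is model-based: the
  difference in predicted expression
  $P(\text{detect}) \times E[y \mid \text{detected}]$ between the two
  contrast levels, other covariates at their means, rescaled to log2.
  A config switch (`log2fc_mode = "continuous"`) reports the
  continuous-part coefficient alone instead, since the combination rule
  is a modelling choice rather than a forced consequence of the model.
* **Multiple testing.** Benjamini–Hochberg within each (receptor, cell
  type, contrast) slice; Bonferroni (same per-slice family) only inside
  the response score below.

## From tests to interactions

Per-gene results are aggregated by `summarize_interactions()` under the
combined significance rule, all thresholds configurable with defaults as
used throughout: an interaction is significant when **every** configured
contrast shows (1) at least 10 genes passing the interaction test at
FDR < 0.25, (2) the ligand differentially expressed in the donor type at
FDR < 0.05 with |log2FC| > 0.12, and (3) ligand fold changes agreeing in
sign across contrasts. Interactions are ranked by the number of
significant interaction effects — taken as the maximum over contrasts,
matching the "whichever is greater" convention used for ribbon weights in
the exported link table — with ties broken by the number of target-test
DEGs and then lexicographically for determinism.

**Response scores** condense each target-test slice into a signed vector:
$-\log_{10}(P_{\mathrm{bonf}}) \times \log_2(\mathrm{FC})$ per gene, zero
where untested. Rows (one per receptor × target type) are embedded by PCA
with the dimensionality chosen at the kneepoint of the cumulative
variance curve (maximum perpendicular distance to its chord — a
deterministic elbow rule), and ordered by the first diffusion component:
the leading nontrivial eigenvector of the row-normalized affinity from a
k-nearest-neighbour Gaussian kernel with per-point adaptive bandwidth
(distance to the ⌈k/2⌉-th neighbour, k = min(15, rows−1)). DC1's sign is
fixed so the row with the largest response-score norm is non-negative.
The kernel parameters are our concrete choices; the upstream literature
delegates this embedding to external tools without printing parameters.

**Subcluster mapping** takes the dot product between a response-score row
and each subcluster's one-vs-rest marker log2FCs (masked to zero at
FDR > 0.15), standardizes by the maximum over subclusters, and assigns
subclusters strictly above 0.5 — several may qualify, none when no dot
product is positive. Negative dot products are retained but can never be
assigned. Ligands map to subclusters simply by positive enrichment
(log2FC > 0, FDR < 0.15).

## Spatial colocalization

For spot-level spatial transcriptomics with deconvolved cell-type
probabilities, a predicted interaction is scored as

$$\sum_{\text{spots}} \log(1 + \text{ligand expr}) \times
  \Pr(\text{target type}) \times 1[\text{receptor expr} > 0],$$

and referred to a null obtained by permuting the ligand vector across
spots (100 permutations by default), with the add-one convention
$p = (1 + \#\{\text{perm} \ge \text{obs}\}) / (1 + n_{\mathrm{perm}})$ so
p is never zero and the test is exact-conservative. `log1p` is our
pseudocount choice for the unspecified "log of ligand expression"; an
optional pooling radius (in μm, inclusive, Euclidean on stored
coordinates) first sums each spot's ligand signal over its
neighbourhood — permutation precedes pooling so the null respects the
neighbourhood structure. These radius conventions are package decisions;
the source material does not detail the construction.

## Karyotype diversity (CNV_SDI)

Samples are stratified by chromosomal instability with a
copy-number-weighted Shannon index over the inferred variant states of a
sample's tumour cells: with per-variant cell fraction $freq_i$ and
alteration magnitude $\delta_i = \sum_{\text{bins}} |state - neutral|$,

$$s_i = \frac{freq_i\,\delta_i}{\sum_j freq_j\,\delta_j},\qquad
  \mathrm{CNV_{SDI}} = \sum_i -s_i \ln s_i \in [0, \ln n].$$

Zero-weight variants are dropped before normalization (0·ln 0 := 0); a
fully neutral sample scores 0 and is flagged. The neutral state defaults
to 3, the centre of the common 6-state model; δ is computed in state
units, since the upstream HMM's state-to-copy-number convention is not
part of this package's scope.

## Benchmarking utilities

Ranked interaction lists are compared by the overlap coefficient
$|X \cap Y| / \min(|X|, |Y|)$, which unlike Jaccard does not penalize
methods that report fewer interactions. External cytokine-response
signatures are compared to predicted responses via a weighted-KS
connectivity score (running sum: +1/|hits| at members, −1/|misses|
elsewhere; score = signed maximum deviation). The exact normalization of
the score's published ancestor is not reproduced anywhere we could
verify, so this concrete form is isolated behind one function and
drop-in replaceable; matched-vs-all comparisons use a one-sided
Mann–Whitney test with the lineage-level matching groups
(epithelial/stromal, myeloid, lymphoid) editable via configuration.

## What the synthetic generator emulates — and what it does not

`simulate_tme()` generates the study conditions all sensitivity and
calibration claims are made under: three conditions (CIN^high, CIN^low,
STING-knockdown; the first is ligand-available), a donor (tumour) and a
target (macrophage) cell type with 500 cells per type and condition (so
each interaction-test arm holds ~250 cells), 1,000 background genes,
negative-binomial counts (dispersion 0.5) with log-normal gene means
(meanlog log 0.5, sdlog 1.2) and log-normal per-cell size factors
(sdlog 0.35) producing CDR heterogeneity. Receptors are detected in a
configurable fraction (default 0.5) of target-type cells; ligands are
donor-restricted with a log2 fold change of 1.5 in the ligand-available
condition; planted effect genes shift by log2FC = 1 only in (target+,
ligand-available) cells; confounder genes shift in target+ cells of all
conditions.

Two generator choices matter for interpreting the tests:

* Planted genes draw their base means from the detectable range
  ([0.5, 8] counts per cell) of the same log-normal. A response planted
  in a silent gene is invisible to any expression-based method, so
  including such genes would measure the transcriptome's detection floor,
  not the test's discrimination.
* The background transcriptome (1,000 genes) keeps planted responders a
  small fraction of each cell's library. In early, smaller configurations
  the planted shift was partly absorbed by library-size normalization and
  the CDR covariate — a compositional artifact real tissues (with ~20k
  genes and responders a tiny fraction) do not show.

The generator does **not** emulate ambient RNA, doublets, batch effects,
cell-type misannotation, or spatially structured ligand diffusion (ligand
"availability" is pure donor differential expression). Passing tests on
this synthetic TME therefore demonstrate the statistical machinery —
calibration, confounder rejection, sensitivity at the stated effect
sizes — not robustness to those artefacts.

Calibration checks pool four replicate null datasets (250 genes each):
genes within one dataset share a single receptor draw and cell sample, so
a lone dataset carries a common random mode that inflates
Kolmogorov–Smirnov distances regardless of test calibration; replication
across receptor draws removes it. The spatial-null uniformity check uses
300 replicate layouts for the analogous reason: the Kolmogorov–Smirnov
noise floor of a uniform sample must sit well below the bound being
asserted.

## Problem sizes and determinism

All simulations in the test-suite and the acceptance script run at the
sizes above or smaller (the end-to-end ranking run tests ~1,200 genes ×
6 receptors × 2 contrasts and completes in about two minutes on one
core). Every stochastic step takes an explicit seed; generators save and
restore the caller's RNG state, so a pipeline run is a pure function of
(config, seed), and rerunning `run_pipeline()` with the same inputs
produces byte-identical outputs.

## Known limitations

* The hurdle engine assumes cells are exchangeable given covariates —
  no sample-level random effects; pseudo-replication within samples is
  not modelled (matching the per-cell regression convention of the
  field's standard implementations).
* The interaction test restricts to each contrast's two condition levels;
  a multi-condition joint test is not provided.
* The ML continuous part is mildly liberal at very small detected-cell
  counts; the per-slice detection filter (default 1%) bounds, but does
  not eliminate, this regime.
* Multi-ortholog mapping implements the average-or-drop policy only;
  judgement calls beyond that (as published gene lists sometimes make)
  must be encoded through the drop list.
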