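---
title: "Methods: tissue-specific coexpression and the expression-level confound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specific coexpression and the expression-level confound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Coexpression — correlation between two genes' RNA levels across samples —
changes between tissues, and such *differential coexpression* is often read
as evidence of regulatory rewiring. But coexpression is confounded with
expression level: a gene that is simply not expressed in a tissue cannot be
coexpressed there, and the variance of expression tracks its level. `puredc`
measures tissue-specific coexpression and then asks, link by link, how much
of it is predictable from the genes' mean expression alone. Links whose
tissue specificity survives that test, with both genes expressed in every
tissue, are called **pure** differential coexpression — the rewiring
candidates. The rest are **expression-associated** or outright
**expression-induced** (an off-state gene in at least one tissue).

## Pipeline and assumptions

Inputs are a collection of genes-by-samples log-scale expression matrices
(log2 intensities or log-CPM), each from one *dataset* (an independent
cohort) and tagged with a *tissue*. The method assumes data are already
normalized within each dataset; between-dataset comparability is achieved
only through the rank transform below, never by renormalizing. Several
datasets per tissue are required — the whole design rests on recurrence
across independent cohorts, not on within-cohort significance.

### Tissue-aggregated networks (TAN)

Per dataset, Pearson correlations between all pairs of genes expressed in
the dataset's tissue. A binary network keeps the pairs whose correlation is
strictly above the dataset's 90th percentile (`tan_percentile = 0.90`;
strict `>` on the ceiling(p·n)-th order statistic, so ties at the cutoff are
excluded and a sort-based oracle reproduces the link set exactly). A
tissue's TAN keeps links present in at least *n* of its K binary networks.
Under the null a link enters each binary network independently with
probability 0.1, so its support is Binomial(K, 0.1); *n* is the smallest
support whose empirical FDR

\[
\widehat{FDR}(n) = \frac{N_{pairs}\,P(X \ge n)}{\#\{\text{links with
support} \ge n\}}
\]

is at or below `tan_fdr = 1e-4`. A support level with no observed links
also qualifies: no discoveries means the FDR is trivially controlled and
the TAN is empty (an error here would make clean null data fatal). When no
observed counts exist yet (planning mode) the conservative tail criterion
\(P(X \ge n) \le fdr\) is used instead; both modes are exposed in
`dc_config(tan_fdr_mode=)`.

### Expressed genes

Expression data on the log scale are bimodal: an off population (background
noise) and an expressed population. The default `gmm2` method fits a
2-component Gaussian mixture (`mclust`) to the tissue-wide per-gene mean
log-expression and marks genes assigned to the higher component (posterior
≥ 0.5) as expressed. If the two components are separated by less than two
pooled within-component SDs the data are effectively unimodal — a
2-component fit of a single Gaussian typically lands its means about one
pooled SD apart, while genuinely bimodal expression data sit at 4–12 — and
the method falls back to a fixed threshold at the median, with a warning.
A user-specified fixed threshold (`expressed_threshold_method = "fixed"`)
is available for data where the bimodality assumption is known to fail;
the null-calibration analyses in this package use it for exactly that
reason (see *Calibration* below).

### Binned rank transform and the tissue-specificity score

Raw correlations are not comparable across datasets (sample size, global
correlation structure), so each correlation is replaced by its quantile bin
among all expressed-pair correlations of its dataset: `n_bins = 1000` bins,
i.e. per-milles, on the scale (0, 1]. Negative correlations carry no
evidence of coexpression and would act as outliers; they are pinned to the
middle bin 0.5, and non-negative values are floored there, so SB ∈ [0.5, 1].
We keep SB on the unit scale (rather than integer per-milles) so the TSS and
its 0.4 cross-tissue ceiling live on one coherent [0, 0.5] scale; with 1000
bins the per-mille granularity is preserved exactly.

For link (i, j) and target tissue *t*, with dataset-wise binned values SB:

\[
TSS(i,j,t) = \frac{1}{|C_t|\,|C_{\bar t}|}
  \sum_{p \in C_t} \sum_{q \in C_{\bar t}} \max(SB_p - SB_q,\, 0)
\]

where \(C_t\) are the target-tissue datasets and \(C_{\bar t}\) all others.
TSS is 0 when the link's binned correlations are exchangeable across
tissues and reaches 0.5 for a link at the top bin in every target dataset
and at the floor everywhere else. A link that is not evaluable in a dataset
(a gene not expressed in that dataset's tissue, hence absent from its
correlation pool) contributes SB = 0.5 — the no-coexpression floor, the
least-assumption choice consistent with the treatment of negative
correlations. Being rank-based, TSS is invariant to any strictly monotone,
sign-preserving transform of the correlations within a dataset.

A one-sided Wilcoxon rank-sum test (target SB > other SB) is provided as an
alternative score (`tss_wilcoxon`); the two rank the links near-identically
(Spearman ≥ 0.8 on synthetic data) and the TSS is used downstream.

### Pseudo-tissue null and the TSS FDR

The TSS null comes from *pseudo-tissues*: random subsets of datasets the
same size as the mirrored tissue, stratified so every real tissue
contributes a floor-or-ceiling share (remainders to tissues drawn uniformly
at random). `n_pseudo = 30` independent sets are drawn per tissue. The FDR
at a TSS value is the mean pseudo-tissue exceedance count over the real
exceedance count, capped at 1. On finite data this raw curve can be
non-monotone, so a running minimum enforces monotone non-increase before
thresholding; the per-tissue threshold is the smallest TSS with smoothed
FDR ≤ `tss_fdr = 0.01`. Where the real exceedance count is zero (at and
above the maximum real TSS) the FDR is defined as 0. Selected links must
also have TSS < `tss_other_max = 0.4` in every other tissue, removing links
"specific" to several tissues at once. Pseudo-tissue TSS is computed on the
mirrored tissue's TAN links — the same universe the threshold is applied
to.

### The expression model and link classes

Per tissue-specific link, ordinary least squares across datasets k:

\[
SB_{ijk} = \beta_0 + \beta_1 (e_{ik} + e_{jk}) + \beta_2 |e_{ik} - e_{jk}|
\]

with \(e_{ik}\) gene i's mean log-expression in dataset k. The sum captures
the genes' total expression, the absolute difference their imbalance; the
absolute value keeps the model symmetric under swapping the genes (a link
is unordered). The response is the binned correlation by default
(`model_response = "raw"` fits the raw Pearson r instead). The fit pools
all datasets where the link is evaluable — both genes expressed in the
dataset's tissue, so SB is defined; fewer than 4 evaluable datasets
(3 parameters + 1 df) marks the fit invalid. For the links whose class
actually depends on R² (both genes expressed everywhere) this equals the
full pooled fit across every dataset.

The R² null shuffles each gene's expression vector independently across the
link's datasets and refits (`n_shuffles = 200`), breaking any
expression–correlation coupling while preserving each gene's expression
distribution. The empirical p-value is (1 + #{null R² ≥ observed}) /
(1 + n_shuffles); Benjamini–Hochberg across all tissue-specific links at
`r2_fdr = 0.01` gives the significance call. Classes:

* `induced_offgene` — at least one gene unexpressed in at least one tissue
  (covering both one-gene-off and both-genes-off flavours);
* `pure` — both genes expressed in every tissue AND R² not significantly
  above its null; invalid fits are never called pure (conservative);
* `expression_associated` — the rest.

### Validation and enrichment

External reproducibility thresholds the external cohort's correlations so
its binary network matches the reference TAN's density on the shared gene
universe (equal link count up to ties; links outside the shared universe
are untestable, not failures). Reported per link group (TAN, TSN, pure):
the overlap likelihood ratio (observed external overlap over group size ×
density), the reproduced fraction (membership in the density-matched
network — the documented criterion in this package), and the external
correlation distribution against the all-pairs null. Topological overlap
of a link's two neighborhoods, |N(a) ∩ N(b)| / min(|N(a)|, |N(b)|)
excluding the pair itself, is min-normalized — bounded and symmetric.

Term enrichment of a network counts links with both endpoints in a term's
gene set against a null of size-matched random gene sets
(`enrichment_null = "gene_sampling"`); degree-preserving edge rewiring
(`"rewire"`, via igraph) is the alternative for networks where hubs could
bias the gene-sampling null — neither is asserted as canonical. Terms with
fewer than 2 genes in the universe are skipped rather than reported at
p = 1, to avoid diluting the BH correction. The drop-out analysis removes a
designated link set (the pure links), equal-size random link sets, and
equal-size random subsets of the expression-induced links, and counts which
previously enriched terms lose enrichment under each condition, with
one-sided empirical p-values for the pure removal causing *fewer*
drop-outs.

## The synthetic-data generator

`simulate_collection` draws each dataset from a multivariate Gaussian on
the log2 scale. The correlation matrix is an equicorrelated background
(`rho_background = 0`) with planted 2×2 blocks and module blocks overlaid —
block assembly on disjoint gene sets, so positive semi-definiteness holds
by construction and is verified by Cholesky (a non-PSD assembly is fatal,
naming the offending block). Planted classes mirror the taxonomy the
pipeline is built to separate:

* **pure** — both genes at `on_mean` in all tissues; correlation
  `rho_target = 0.7` in target-tissue datasets, background elsewhere;
* **induced1** — one gene at `on_mean` only in the target tissue
  (`off_mean` elsewhere); correlated with its partner only there;
* **induced2** — both genes off outside the target tissue.

Defaults: 5 tissues, 7–15 datasets per tissue (drawn uniformly), 20–120
samples per dataset, 600 genes, 20 planted links per class,
`off_mean = 4.0` and `on_mean = 9.0` log2 units (typical microarray
background vs expressed intensities), `noise_sd = 1.0`. Off-state genes
have their SD shrunk by `mean_variance_coupling = 0.3` (to 0.7·noise_sd,
interpolated linearly in the mean for background genes), emulating the
empirical variance–mean relationship; setting the coupling to 0 switches
the confound off. Five constitutive 10-gene modules are correlated at
`rho_target` in *every* tissue: they populate the TANs with realistic
non-tissue-specific links, so TSS thresholding and the FDR machinery are
exercised on a non-trivial universe (without them a null TAN would be
nearly empty and the selection step vacuous). Background genes are
independent with means drawn uniformly in [`off_mean`, `on_mean` + 2],
constant across tissues.

What the generator does *not* emulate: probe-level noise, batch effects
within a tissue, library-size artifacts, correlated module overlap, or any
dataset-level mean shifts. Passing tests therefore demonstrate the
correctness and calibration of the machinery under its own model — clean
Gaussian data with planted effects — not performance on real microarray or
RNA-seq collections, where expressed-gene marking and between-dataset
heterogeneity are harder.

## Calibration, numerical choices, problem sizes

* Correlations involving a zero-variance gene are set to 0 and flagged,
  never propagated as NaN.
* Degenerate regression responses (constant SB across datasets) give
  R² = 0.
* All randomness flows from one root seed through named child streams
  (`child_seed`), so pseudo-tissue draws, shuffles and synthetic data are
  independently reproducible.
* The no-signal calibrations use the fixed expressed-threshold option: a
  modules-only null collection has no off-state gene population, so the
  mixture split is undefined there and its fallback would inject artificial
  per-tissue differences into a design whose premise is "no tissue signal".
  With signal-bearing (bimodal) data the mixture method is the default and
  is what the end-to-end recovery analyses use.
* Analysis problem sizes in the tests and the acceptance script: the
  default design (5 tissues, ~55 datasets, 600 genes) for end-to-end
  recovery; 3-tissue, 120–150-gene collections for the null calibrations;
  500 replicates for p-value uniformity checks; oracle checks on fixtures
  of ≤ 50 genes. These sizes give Monte-Carlo error comfortably inside the
  asserted tolerances while keeping the full suite under a minute of
  compute.

## Known limitations

* TSS treats all non-target tissues as one pool; a link specific to two of
  five tissues is (deliberately) filtered by the 0.4 ceiling, not modelled.
* The expression model is linear with two fixed regressors; nonlinear
  expression–correlation relationships count as "unexplained" and can
  inflate the pure class.
* Pseudo-tissues mix datasets across tissues and therefore null out
  tissue identity but not dataset-level technical structure.
* The enrichment nulls (gene sampling, degree-preserving rewiring) bracket
  but do not settle the question of the right null for link-based
  enrichment; results sensitive to the choice should be reported with both.
* Module-level (cluster-based) differential coexpression is out of scope:
  the method works at link resolution precisely so that expression-level
  effects on individual genes can be controlled.
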