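---
title: "Correlation versus accuracy in panel-based TMB estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation versus accuracy in panel-based TMB estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbpanel)
```

## The problem

Tumor mutational burden (TMB) — somatic coding mutations per megabase —
predicts benefit from immune checkpoint inhibition, and whole-exome
sequencing (WES) is its gold-standard substrate. Because WES is costly,
targeted gene panels are marketed as TMB estimators, usually validated by
the Pearson correlation (R²) between panel- and WES-based TMB. That
validation is fragile: nearly every cancer type harbours a few relatively
ultra-high-TMB cases (hypermutators, e.g. POLE-mutant or MSI tumors), and a
single such case can prop up R² across an otherwise discordant cohort. A
dichotomous view — was a patient correctly classified as TMB-high or
TMB-low at a clinically motivated cutpoint? — is insensitive to those
outliers. `tmbpanel` implements both views and the analyses that contrast
them, plus a random virtual-panel experiment that asks how many genes a
panel needs before dichotomous accuracy is adequate.

## The model and its pieces

**TMB definitions.** WES TMB is the per-sample count of non-synonymous
coding mutations (base substitutions and indels) divided by a 38 Mb exome.
Panel TMB divides the mutations falling in the panel's gene set — plus
synonymous calls when the panel's counting rule includes them, as two
commercial assays do to reduce sampling noise — by the panel's captured
size in Mb. Membership is by gene symbol; no interval arithmetic is
attempted, and the WES reference never counts synonymous calls regardless
of any panel's rule.

**Dichotomization.** Within each cancer type, samples are ranked by WES TMB
(descending, ties broken by sample barcode) and the top `floor(f · n)` are
TMB-high truth at fraction `f` (default 0.20, sweepable 0.10–0.50). "Top
20%" is treated as a rank statement rather than an interpolated percentile,
because interpolation schemes differ across software while ranks do not.
The panel side can be thresholded two ways, and the choice matters:

* **value transfer** — predicted high iff panel TMB ≥ the WES TMB value at
  the cutpoint rank. Panels whose genes are mutation-enriched overestimate
  TMB, so this mode reproduces the clinically important asymmetry in which
  misclassification is dominated by false TMB-high calls. It is the default
  for evaluating named panels.
* **quantile** — predicted high iff the sample ranks in the top fraction of
  panel TMB. Predicted and true high sets then have equal size, forcing
  equal false-positive and false-negative counts; the suite uses this
  structural fact to tell the modes apart.

One deterministic total order (TMB descending, barcode ascending) governs
every stage — cutpoints, subgroups, removals, and exact value-ties at a
transferred threshold — so no two stages can disagree about what "top k"
means.

**Metrics.** Per cancer type and panel: R² (squared Pearson correlation of
raw, untransformed TMB — outlier sensitivity is the object of study, and a
log transform would suppress it), accuracy, false positive rate, false
negative rate (written as the exact complement so accuracy + FPR + FNR = 1
to the last bit), and positive/negative percentage agreement, with
undefined agreements reported missing rather than zero.

**Robustness analyses.** `removal_sweep()` drops the top 1–5% of cases by
WES TMB rank and recomputes everything, recomputing the quantile cutpoint
on the reduced cohort (labels are statements about the analyzed set; the
frozen-cutpoint variant is available behind a flag for sensitivity
analysis). `subgroup_correlations()` instead retains all cases and computes
R² within the top 5%, top 5–20%, and bottom 80% rank strata. A reliable
panel should show stable accuracy under removal and subgroup correlations
comparable to the overall one; an outlier-propped panel shows a collapsing
R² and an overall correlation exceeding its bottom-80% stratum.

**The design experiment.** `minimal_panel_size()` draws random gene sets of
increasing size (grid, default 150–1000 genes) from a user-supplied length
table, sizes each virtual panel by its summed coding length, and reports
the smallest size whose mean accuracy over the draws reaches a target
(default 90%), truncating at the grid maximum when never reached. Gene
draws are uniform (no length weighting) and a grid with first-crossing is
used rather than bisection because accuracy is stochastic and only
approximately monotone in size. The designer defaults to quantile
classification: a random in-silico panel has no externally calibrated
threshold to transfer, and at small sizes a transferred value-threshold
interacts with the granularity of panel TMB (a single captured mutation can
clear it), making value-transfer accuracy visibly non-monotone at the
low-TMB end. Rank-based classification removes that artifact and leaves the
substantive result — minimal size falls as a cancer type's TMB level rises
— unchanged.

## The synthetic cohort generator

Every analysis is testable without any external download because the
package generates cohorts with the statistical structure the analyses
assume:

* **WES TMB per cancer type**: a log-normal body (`tmb_log_mean`,
  `tmb_log_sd`) plus a hypermutator tail — with probability
  `hyper_fraction` (≤ 10%) a sample's TMB is multiplied by
  `hyper_multiplier` (> 5). The log-normal body matches the right skew of
  real per-cancer TMB distributions; the multiplicative tail supplies the
  relatively ultra-high outliers under study.
* **Counts**: non-synonymous count = `round(TMB × 38)`, so `tmb_wes()`
  inverts the generator exactly up to rounding; synonymous count is Poisson
  with mean `syn_ratio` × non-synonymous. The default `syn_ratio` of 0.45
  reflects the roughly 2:1 non-synonymous:synonymous ratio of coding point
  mutations.
* **Gene placement**: multinomial over a synthetic gene universe with
  probability proportional to coding length × enrichment. The default
  universe — 20,000 genes with log-normal coding lengths averaging ≈ 1.9 kb
  — sums to ≈ 38 Mb, so exome-wide mutation density matches the WES
  denominator and a random sub-panel's TMB is an approximately unbiased
  estimate of WES TMB. An optional hotspot stratum with an elevated
  per-base rate emulates the cancer-gene enrichment through which real
  panels overestimate TMB.
* A PAAD-like fixture (`inst/extdata/specs/paad_like.yaml`) calibrates a
  177-sample cohort to median ≈ 0.92 Mut/Mb with IQR ≈ 0.60–1.23; a
  log-normal with `sdlog = 0.53` reproduces the quartile ratio, though not
  the mild asymmetry of the real distribution about its median.
* `inject_outlier()` scales one uniformly chosen sample's counts to create
  a single extreme hypermutator, re-drawing gene assignments for the added
  mutations.

What the generator does **not** emulate: positional or trinucleotide
mutation spectra (the pipeline only consumes gene-level membership),
driver-gene selection, copy number, purity or sequencing noise, and any
per-cancer parameter values beyond the single PAAD-like calibration.
Passing tests therefore demonstrate that the *analyses* behave as claimed
on data with the assumed structure, not that any particular commercial
panel performs well or badly on real tumors.

## Numerical and design choices

* All counts are exact integers; TMB values are unrounded doubles, rounded
  only for display.
* `floor(f · n)` (with a minimum of 1 for cutpoints, and 0 permitted for
  removals) is used everywhere a "top f%" set is formed; ceil/round
  variants would disagree between stages.
* Removal leaving fewer than 10 samples yields a row with missing metrics
  and a warning; subgroups under 3 samples report missing R²; zero-variance
  vectors yield missing R² with a warning rather than an error, so one
  degenerate cancer type cannot halt a multi-type report.
* Samples present in the type map with no called mutations are retained
  with TMB 0 — dropping them would bias every quantile cutpoint.
* Unrecognized variant classifications are never counted: they map to
  `excluded` with a warning, and the vocabulary ships as an editable TSV so
  the non-synonymous/synonymous partition is auditable.
* Randomness: the designer re-seeds each draw from `seed + draw index`, so
  results are invariant to batching; the pipeline derives every stage's
  seed from one master seed, and two runs with the same config are
  byte-identical.

## Problem sizes used in the test-suite

The shipped tests and the acceptance script run entirely on synthetic
cohorts sized for a desk machine: cohorts of 40–300 samples (2,000 for
parameter-recovery checks, 177 for the PAAD-like calibration), gene
universes of 400–20,000 genes, 100 random draws per panel size on a
150–1000-gene grid, and 10 replicate cohorts for the outlier analyses.
Monte-Carlo draw counts, not the mechanisms, are what shrink relative to a
full-scale analysis; the report tables record `n_draws` so any user can
scale them back up.

## Worked example

```{r example, eval = FALSE}
universe <- generate_gene_universe(gene_universe_spec(), seed = 1)
cohort <- generate_cohort(list(
  cancer_type_spec("LOW", 150, tmb_log_mean = log(2), tmb_log_sd = 0.5,
                   hyper_fraction = 0),
  cancer_type_spec("HIGH", 150, tmb_log_mean = log(10), tmb_log_sd = 0.5,
                   hyper_fraction = 0.02)
), universe, seed = 2)

set.seed(3)
panel <- make_virtual_panel(sample(universe$gene, 300), universe,
                            name = "rand300")
tmb <- build_tmb_table(cohort, panel)
metric_report(tmb, cutpoint_fraction = 0.2)
removal_sweep(tmb, "rand300")
subgroup_correlations(tmb, "rand300")
minimal_panel_size(cohort, universe, sizes = seq(150, 1000, 170),
                   n_draws = 100, seed = 4)
```

## Limitations

Real vendor panels differ from anything simulated here in gene content,
capture chemistry, and scoring filters the package deliberately does not
model (germline subtraction, driver exclusion, allele-frequency cutoffs).
The package evaluates *in-silico* panel TMB — mutations restricted by gene
symbol — which is the upper bound of what a wet-lab assay of the same genes
could recover. Conclusions about specific commercial panels require their
actual manifests, supplied by the user as panel configs, and ideally the
real cohort MAF rather than synthetic data.
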