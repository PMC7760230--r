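---
title: "Analysing DSP protein counts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing DSP protein counts: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dspforge)
```

## The measurement and its problems

Digital spatial profiling (DSP) counts UV-cleavable DNA barcodes conjugated
to antibodies, per user-drawn region of interest (ROI) on a tissue section.
Each ROI yields a vector of counts over a probe panel that mixes three probe
classes: *targets* (the biology), *isotype IgG controls* (antibodies with no
specific target, measuring nonspecific background), and *housekeepers*
(Histone H3, S6, GAPDH, assumed biologically invariant). Two systematic
problems dominate the raw data:

1. **Per-ROI capture efficiency.** ROIs differ in area, cellularity and
   collection efficiency, which scales every probe's counts in that ROI by a
   common factor. Quantification across ROIs requires dividing this factor
   out.
2. **Low signal-to-noise probes.** Many targets sit at or barely above the
   IgG background; their "signal" is mostly nonspecific binding, and
   downstream statistics on them are noise.

The package implements the analysis stages in the order a DSP study runs
them: raw-count QC, IgG-relative probe filtering, empirical normalizer
selection, normalization, differential expression, clustering, and
univariate survival screening. A calibrated simulator with a ground-truth
ledger makes every stage testable.

## Quality control and the signal-to-noise filter

Per ROI, the background is the arithmetic mean of the IgG-control counts;
each probe's SNR in that ROI is `count / background`. A probe's robustness
summary is the **median** (default) of its SNR over ROIs, and a probe is
robust when the summary reaches the threshold, default **1.0** — i.e. the
probe's typical signal must at least match the isotype background. The mean
summary is also provided (`summary_method = "mean"`) because both summaries
are in circulation for this assay; the choice is recorded in the output. We
default to the median as the more outlier-resistant of the two and take no
position on which a given vendor suite uses.

Housekeepers and IgG controls are exempt from filtering: normalization and
background assessment need them regardless of their own SNR. ROIs whose
median raw count falls below `flag_threshold` (default 50 counts; the
low-count regime where barcode sampling noise dominates) are *flagged,
never dropped automatically* — dropping is a config option, because a low
median can be biology (sparse tissue) rather than failure.

Background *subtraction* is deliberately absent: for targets within a
factor of ~2 of background, subtracting a noisy background estimate
produces negative or wildly unstable values; ratio-based flagging plus
cautious interpretation is the safer treatment.

## Choosing and applying a normalizer

A good scaling factor must track the per-ROI capture factor and be blind to
biology. The package tabulates, per ROI: GAPDH, Histone H3 and S6 counts,
the Histone H3/S6 mean (`hk_mean`), the IgG mean, ROI area and nuclei
count; `assess_normalizers()` computes all pairwise Pearson correlations
and recommends the housekeeper-derived factor whose *minimum* correlation
with the non-biological references (IgG mean, area, nuclei) is highest.
Constant factors — e.g. area when every ROI was drawn at the maximum
geometry — are excluded with a warning, since correlation is undefined and
a capped factor carries no size information anyway.

`normalize_hk()` uses the arithmetic mean of Histone H3 and S6 by default
(geometric mean available; assay conventions differ and nothing in the data
distinguishes them at these count levels). Counts are rescaled by
`anchor / factor_r` with the anchor set to the grand geometric mean of the
factors, so output stays on the raw-count scale and renormalizing an
already-normalized matrix is the identity.

Two global scaling alternatives are provided for the situation where one
tissue class (normal adjacent tissue in particular) is systematically
dimmer than the rest, which housekeeper scaling silently inflates:

* **TMM**: each ROI's factor is the precision-weighted mean of log2
  count-fraction ratios against a reference ROI (the one whose
  upper-quartile fraction is closest to the mean), after trimming the most
  extreme 30% of log-ratios and 5% of average intensities.
* **RLE**: each ROI's factor is the median ratio of its counts to the
  per-probe geometric mean; probes containing zeros are excluded.

Both factor sets are rescaled to multiply to 1. For normalization, TMM
factors are applied on top of the ROI's total count (they are composition
corrections), RLE factors directly. Both implementations are checked in the
test suite against the independent reference implementations in `edgeR` and
`DESeq2`.

`log2_transform()` adds a pseudo-count (default 1, the conventional choice
that maps 0 to 0) before taking logs; the flag and pseudo-count are
recorded in the object so downstream stages know the scale they are on.

## Differential expression

Matched compartments from the same patient are compared by **paired t-tests**
on log2 normalized values; unmatched groups by **Mann-Whitney** tests
(midranks for ties; exact distribution when both groups have at most 8
observations and no ties, otherwise the tie- and continuity-corrected
normal approximation). Benjamini-Hochberg adjustment is applied **within
each comparison panel**, not across panels — each contrast is its own
discovery family. Design choices the data could not settle, and what we
chose:

* *Scale entering the t-test*: log2 normalized values (displays of this
  assay are log2; differences are fold changes). A linear option remains.
* *Multiple ROIs per patient per compartment*: averaged before pairing —
  the patient is the experimental unit, and averaging is the simplest
  defensible reduction.
* *Effect size for the rank test*: difference of group medians, the natural
  companion to a rank statistic.

Per-compartment probe-probe Pearson correlation matrices are provided with
t-transform p-values and a significance mask at p <= 0.001. Note that
correlations among low-SNR probes largely reflect shared background and
should be read with the SNR table at hand.

## Clustering

"Relative expression" is the per-probe z-score across ROIs of log2
normalized values. ROIs are clustered by Ward's minimum-variance criterion
in the squared-distance (D2) formulation on Euclidean distances, heights
reported as the square root of the criterion; k-means (best of 25 restarts
under a fixed seed) assigns discrete classes. `k` defaults to 3 — the
coarse structure such data shows (a normal-tissue-dominated class, a
low-expression tumour/TME class, a heterogeneous class) — and is
configurable, since no criterion in the package selects it automatically.

## Survival screening

For each probe and compartment, the per-patient covariate is the mean log2
normalized expression over that patient's ROIs of the compartment, entered
**continuously** into an unadjusted univariate Cox proportional-hazards
model (a median-split binary mode can be emulated by dichotomizing the
matrix first; continuous is the default because it does not discard
information). Ties are handled by the **Efron** approximation — follow-up
on tissue-microarray cohorts is coarsely recorded, producing many ties, and
Efron is the more accurate of the standard choices there. Results are
ranked by hazard ratio; no multiplicity adjustment is applied by default
(screens of this kind are reported unadjusted; a BH column is optional).
Fits with fewer than 2 events, constant covariates, or monotone-likelihood
divergence (|beta| > 20) are flagged, never silently reported.

## The simulator and what it does (not) emulate

`simulate_counts()` draws `count(r, p) ~ NB(mu, size)` with

```
mu = sf_r * mu_p * 2^effect(p, c_r) * nat(p, c_r) * bio(patient_r, p)
```

* `sf_r`: log-normal per-ROI size factor (sd 0.20 on the log scale),
  shared by all probes of an ROI — the capture-efficiency confounder that
  normalization must remove. Area and nuclei are emitted as noisy monotone
  transforms of it (area capped at the 600 um circular maximum), so the
  normalizer assessment has realistic structure to find.
* `mu_p`: probe baseline at size factor 1. Targets are drawn log-uniformly
  on [50, 3000] counts from the design seed, so a subset of targets sits at
  or below background; housekeepers are fixed at 600/450/500; IgG controls
  at `background_mean = 95`.
* `effect`: compartment-specific log2 enrichments of chosen targets — the
  ground truth for differential expression.
* `nat`: a multiplicative depression (default 0.6) of *target* signal in
  normal adjacent tissue, reproducing the systematically dimmer normal
  tissue that motivates global scaling; housekeepers and IgG are untouched.
* `bio`: per-patient, per-target log-normal heterogeneity (log2-sd 0.5,
  mean one on the linear scale), shared across a patient's compartments.
  This is what survival signal and patient-level correlation live on.
* `size = 150`: negative-binomial size; barcode counting is technically
  precise, so overdispersion beyond Poisson is modest at these settings.

The defaults were calibrated once, by simulation, to the published count
regime for this assay: per-ROI IgG means concentrated within 50-150 counts
(central 90%), per-ROI median counts between 1e2 and 1e3, housekeeper and
IgG factors correlating at r > 0.8, and housekeeper factors recovering true
size factors at r > 0.9. The default cohort pattern reproduces the study
layout exactly: 64 patients contributing 96 ROIs (45 tumour, 32 TME, 19
NAT) with 18 tumour-TME, 14 tumour-NAT and 8 TME-NAT matched pairs.

`simulate_survival()` draws exponential event times with rate
`base_hazard * exp(sum_p beta_p * log2(true expression))` (centred), and
independent exponential censoring calibrated so the expected censored
fraction equals `censor_rate` under the null.

What the simulator does **not** emulate: spatial coordinates or
morphology-channel imagery, probe-specific antibody affinities, saturation
of the counting chemistry, batch or slide effects, and any dependence
structure between probes beyond the shared size factor and patient effect.
Tests passing on this generator therefore certify the *statistical
machinery* (normalization recovery, error control, power, parameter
recovery), not performance on any particular real tissue.

## Numerical and reproducibility choices

* One master seed per design; sub-streams (baselines, size factors,
  counts, geometry, biology, survival) derive fixed sub-seeds below 2^31
  from it, so stages are independently reproducible and one extra draw in
  one stage cannot shift another.
* Ward tie-breaks follow the deterministic lowest-index convention of the
  underlying implementation; k-means is best-of-restarts under a set seed.
* SNR ratios are undefined in ROIs with zero IgG mean; such ROIs are
  excluded from SNR with a warning, never imputed.
* Stage outputs are written at 6 significant digits (the normalized matrix
  at 8 so it round-trips within 1e-6 relative); all writers emit
  tab-delimited UTF-8 with a header.
* Validation is total: malformed inputs produce a hard error naming the
  offending column, label or cell; nothing is silently dropped.

## Problem sizes used in the validation suite

The shipped tests run the cohort-scale pipeline (96 ROIs x 58 probes), a
200-ROI calibration check, 200 null replicates of an 18-pair x 30-probe
paired analysis for type-I error, 100 replicates for power of a +2 log2
enrichment at 18 pairs, Cox recovery at n = 500 (10 replicates) and null
coverage at n = 200 (50 replicates). These sizes give binomial error small
enough for the stated bounds while keeping the suite fast.

## Known limitations

* The robust-probe count depends on the median-vs-mean summary choice near
  the threshold; both are reported, neither is "the" answer.
* Housekeeper normalization inflates systematically dimmer tissue classes
  (the reason TMM/RLE are provided); the default remains housekeeper
  scaling for comparability with standard practice.
* Mixed-effects differential models (patient as random effect) are out of
  scope; the paired t-test conditions on complete pairs only.
* The Cox screen is univariate and unadjusted by design; its p-values are
  screening diagnostics, not confirmatory inference.
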