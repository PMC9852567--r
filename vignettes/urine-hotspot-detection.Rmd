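---
title: "Detecting bladder cancer from urine hotspot mutations: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bladder cancer from urine hotspot mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urovaf)
```

## The measurement problem

Bladder tumours shed cells into urine, and most of them (about 74%) carry a
mutation at one of a small set of non-coding single-nucleotide hotspots in
*ADGRG6*, *PLEKHS1*, *WDR74*, *TBC1D12* and *LEPROTL1*. These hotspots sit
in palindromic sequence contexts favoured by APOBEC cytidine deaminases —
which is also the problem: APOBEC-mutated cell clones expand in the normal
urothelium of people *without* cancer, more often with age, so a sensitive
assay will find these mutations at low allele fractions in disease-free
urine too. The analysis therefore has three statistical layers:

1. suppress sequencing/PCR error far below the biological background
   (UMI consensus calling);
2. summarise each sample by a score robust to panel size (the maximum VAF
   over hotspots);
3. choose an operating threshold on disease-free training data so that
   background clones rarely cross it, and quantify the resulting
   sensitivity/specificity honestly (exact intervals, ROC, stratified and
   age-banded views, recurrence risk).

## Consensus calling model

Reads sharing a UMI, fragment start and chromosome derive from one input
molecule. `call_consensus()` implements deliberately simple, auditable
rules:

* families with fewer than `min_family_size = 3` raw reads are discarded —
  below that, a single polymerase error is indistinguishable from signal;
* the consensus base must be carried by a *strict majority* of the family;
  an exact tie yields `N`, never a guess, and `N` calls are excluded from
  depth downstream;
* the consensus quality is the mean Phred quality of the supporting reads,
  rounded half-up and capped at 40. This is a simplification of the full
  Bayesian quality model used by production consensus tools; it is adequate
  here because the only downstream use of quality is the ≥ 30 filter, which
  the cap dominates.

UMI grouping is exact-match by default. Real UMIs acquire sequencing
errors; an optional directional Hamming-distance-1 merge
(`umi_merge_distance = 1`) pools a rare UMI into a more abundant neighbour
at the same fragment start. Deeper UMI error-network deduplication, duplex
consensus and indel consensus are out of scope.

## VAF quantification

`pileup_vaf()` counts, at each panel coordinate, the consensus calls with
quality ≥ `min_baseq` (default 30) and base ≠ `N`; the VAF is the fraction
matching the panel alt base, with *all* quality-passing calls in the
denominator (pileup semantics — ref, alt and third-allele calls all count).
Two conventions matter and are pinned by tests:

* a site with zero quality-passing depth is *undefined* (`NA`), not 0 —
  missing coverage must not manufacture a negative call. A sample with no
  defined VAF at any usable site raises an unevaluable-sample error.
* the per-sample score `max_vaf()` maximises over *defined, non-excluded*
  sites, tie-breaking by panel order. Exclusion exists because one panel
  site (*WDR74* chr11:62609254 G>A) is prone to germline-like noise:
  dropping it is a configuration choice (`exclude_sites()`), default off,
  since results are reported both ways.

The score is alt-specific: only the panel's designated alt base at each
coordinate is scanned, not any non-reference base.

## Classification and calibration

A sample is positive iff `max_vaf > t`, strictly: a sample exactly at the
threshold is negative. `calibrate_threshold()` computes the training
specificity of each candidate threshold on disease-free training samples
and selects the *smallest* candidate meeting the target — smaller
thresholds preserve sensitivity, so the smallest qualifying one is the
sensitivity-optimal choice at the required specificity. Thresholds are
plain numerics compared with `>`; the boundary behaviour at 0.02 is pinned
by a dedicated test rather than by decimal arithmetic tricks.

## Diagnostic statistics

* **Exact intervals.** `exact_binomial_ci()` is Clopper–Pearson from beta
  quantiles. This method reproduces, at integer printing precision, every
  published interval of the study this analysis follows (58–73% for
  109/165, 88–95% for 261/284, 36–74% for 16/29, 80–89% for 225/264);
  Wilson and Wald do not. For the study's sample-size calculation (135/150)
  the exact interval prints as 84.0–94.3% at one decimal.
* **ROC/AUC.** `roc_auc()` sweeps the threshold over every distinct
  observed score under the strict-> rule and integrates by trapezoid; this
  equals the Mann–Whitney U statistic scaled by the number of
  (disease, control) pairs, with tied pairs given half credit — verified
  against a brute-force pairwise oracle and against `pROC`. The AUC
  interval is DeLong's, and is labelled as such.
* **Relative risk.** `relative_risk()` is the plain risk ratio with a Katz
  log-normal interval, clearly labelled. Zero event cells give a flagged
  infinite/zero estimate, or a flagged 0.5 continuity correction on
  request. The published interval for the recurrence risk ratio (3.75–5.48
  for RR 4.62 from 8/39 vs 10/225) is far narrower than Katz or bootstrap
  intervals on those counts; its method is unknown, so this package
  reports the point estimate as the comparable quantity and its own
  clearly-labelled Katz interval, rather than imitating an unreproducible
  CI.
* **Group comparisons.** `compare_groups()` reports group medians plus a
  two-sided Mann–Whitney rank-sum p-value (normal approximation with tie
  correction, via `stats::wilcox.test`). The published comparison did not
  state its test; medians are reported independently of the test choice so
  the headline quantities never depend on it.
* **Stratified reporting.** `stratified_table()` groups incident disease
  into G1pTa, G2pTa, G3pTa, G2pT1, G3pT1, MIBC (stage ≥ T2) and "Other BC"
  (unrecorded stage/grade, carcinoma in situ, or G1pT1), with per-gene
  positive counts, an "Any" row identical to the sample-level call, and
  per-stratum sensitivity.
* **Rounding.** Percentages print half-away-from-zero to integer percent
  (one decimal in sample-size mode), matching clinical reporting
  conventions; base R's half-to-even `round()` is not used for printing.

## The synthetic-data generator

The generator exists so that every stage — and every published contingency
statistic — can be exercised end to end at desk scale. Its defaults are the
study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| consensus depth | Poisson, mean 2,400 | reported average consensus depth |
| raw reads per family | 1 + Poisson(13.75), mean 14.75 | 2,400 × 14.75 = 35,400 raw depth |
| consensus base error | 1e-3 per base, /3 per alt | post-suppression substitution rate; yields sub-0.1% noise VAFs |
| background clone probability | 0.01 / 0.09 / 0.14 for ages <50 / 50–64 / ≥65 | observed age-band false-positive rates |
| background clone VAF | log-normal, median 3%, log-sd 0.25 | clones cluster above the 2% threshold (see below) |
| tumour mutation prevalence | 0.74 | fraction of BCs carrying ≥1 hotspot mutation |
| tumour VAF median | 6% incident / 3.3% recurrence / 1.7% pre-recurrence | observed max-VAF medians per setting |
| tumour VAF log-sd | 1.0 | reproduces the wide observed dynamic range; implies P(V > 2%) ≈ 0.86 at median 6%, hence ~64% sensitivity at 74% prevalence — coherent with the observed 66% |

Counts are drawn as `depth ~ Poisson(2400)` and
`alt ~ Binomial(depth, v + e/3·(1 − v))` where `v` is the true somatic VAF
and `e` the consensus error rate; a per-site error override models the
germline-noise-prone *WDR74* site (0.3% when enabled; off by default).
Read-level simulation (`simulate_reads()`) exists to exercise the consensus
module: UMI families of size `1 + Poisson(13.75)`, raw substitution errors,
and a configurable fraction of sub-30 qualities; collapsing and
quantifying these reads recovers the generating VAF within binomial error.

Design choices worth stating explicitly:

* **Background error is modelled per consensus base**, not per raw read,
  because every analysis-level quantity is consensus-level; this keeps
  cohort simulation fast and the noise model identifiable.
* **At most one clonal hotspot per disease-free sample** (multi-site
  background is a config option, off by default), and **exactly one mutated
  hotspot per mutation-positive tumour**: the max-VAF statistic is driven
  by the dominant clone, and a single-site truth keeps the generating
  model's detection probability analytically computable for recovery
  tests.
* **Band probabilities are probabilities of a *detectable* expansion.**
  The age-band rates (1/9/14%) were observed as false-positive rates at the
  2% threshold, so the generator interprets them as the probability that a
  disease-free sample carries a clone whose VAF distribution (median 3%,
  log-sd 0.25) lies almost entirely above 2%. Consequence: the age-band
  false-positive estimator recovers the generating probabilities, but the
  synthetic training set does *not* reproduce the published 1/1.5/2%
  specificity sweep (68/86/90%), which requires substantial background
  mass between 1 and 2%; that calibration contract is exercised on an
  engineered training vector instead. The distributional form of
  background VAFs is unpublished; log-normal is a modelling choice exposed
  in the parameters.
* **Pre-recurrence samples** (cystoscopy-negative, recurrence at the next
  visit; 18/264 of the surveillance arm) all carry signal at VAF median
  1.7%. With log-sd 1.0 this implies P(V > 2%) ≈ 0.44, matching the
  observed 8/18 positive fraction without an extra carrier-probability
  parameter.
* **Determinism.** Every sample draws from a seed derived from the root
  seed and its index, so cohorts are bit-reproducible and enlarging an arm
  never perturbs earlier samples.

What the generator does **not** emulate: fragment-length biology, GC and
strand bias, UMI collisions, sub-threshold polyclonal biological background
(real disease-free urine shows median max VAFs around 0.7%, driven by
low-level clones this generator only produces via its clonal component),
germline contamination, and tumour multi-site mutation patterns. Passing
tests therefore demonstrate the correctness of the *analysis* under the
stated generative model, not assay performance on real urine.

## Numerical and degenerate-input conventions

* Thresholds, VAFs and probabilities are plain doubles; all boundary rules
  are strict inequalities pinned by tests (score = threshold ⇒ negative).
* `max_vaf` on an all-undefined sample and `roc_auc` with one class absent
  raise typed errors (`urovaf_unevaluable_error`, `urovaf_roc_error`)
  rather than returning sentinels.
* Calibration failure carries the best achievable threshold/specificity in
  the error condition for programmatic recovery.
* Empty age bands and zero 2x2 denominators return `NA` with explicit
  defined-ness flags, never silent zeros.
* Problem sizes in the test suite: oracle equivalences run 10⁴ random
  cases per statistic; parameter recovery uses 5,000 samples per arm at
  full 2,400× depth; read-level end-to-end checks use one site at 2,400
  families. These sizes give 3-binomial-SE margins that are both strict
  and stable.

## Known limitations

* Only 2 of the 19 hotspot coordinates are published in the primary source;
  the bundled panel fills the rest with clearly-labelled synthetic
  placeholders, so real analyses must supply the true panel.
* The consensus quality model is intentionally simpler than fgbio's;
  grouping options beyond the ≥ 3-read rule (per-base error filters,
  masking) are unpublished and therefore implemented as explicit defaults,
  not reconstructions.
* The exact interval does not reproduce the published sample-size interval
  83.8–94.1% for 135/150 (it prints 84.0–94.3%); no standard interval
  (Wilson, Wald, Agresti–Coull, Jeffreys, mid-P, logit, arcsine) matches
  both endpoints, so the discrepancy is documented rather than imitated.
* Real-cohort medians, AUCs and per-stratum cell counts require the
  original patient data and are out of scope; the package reproduces the
  statistics computable from published contingency counts and validates
  everything else by oracle equivalence and parameter recovery.
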