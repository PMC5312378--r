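---
title: "Methods: paired miRNA differential expression and cancer-specific survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired miRNA differential expression and cancer-specific survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsurv)
```

## The analysis problem

mirsurv implements a site- and stage-specific survival analysis for paired
tumor / normal-mucosa miRNA array data in colorectal cancer.  The question
it answers, per miRNA, is whether the *differential expression* of that
miRNA — the per-subject difference of log2 carcinoma signal minus log2
paired normal signal — is associated with cancer-specific survival, after
adjusting for age at diagnosis, sex, AJCC stage, and tumor MSI status, and
separately within colon and rectal cancers (and within early or late
stage).  Differential expression, rather than absolute carcinoma
expression, is the exposure because it is markedly more stable across
population subsamples.

The pipeline stages are:

1. **Normalization.** Each sample (array) is multiplied by the scaling
   factor `median(P75 of all samples) / P75 of that sample`, where P75 is
   the 75th percentile of the sample's total-gene-signal values.  After
   scaling, every sample's P75 equals the shared median exactly; this is
   the package's one normalization invariant and is tested to 1e-9.
2. **Imputation of unpaired normals.** Subjects with no normal-mucosa
   measurement receive, per miRNA, the median of observed normal values
   within the same site stratum (colon vs rectal) — gated by the paired
   carcinoma detection mask: where the subject's carcinoma shows no
   expression the normal is imputed as 0 (undetected), since paired
   detection is strongly concordant and an ungated median would
   manufacture a large artificial negative differential for such cells.
3. **log2 transform.** Detected cells map to `log2(value)`; undetected
   cells (raw signal exactly 0) stay at 0 and remain flagged undetected.
4. **Differential expression.** Cell-wise tumor minus normal on the log2
   scale, with per-cell provenance (both detected / tumor-only /
   normal-only / neither / normal-imputed).
5. **Prevalence classification.** miRNAs expressed (detected in carcinoma)
   in at least 50% of the analysis population are *common* and analyzed on
   the continuous differential scale; those below 50% but with at least 5
   expressors are *rare* and analyzed as any-vs-no expression; fewer than
   5 expressors excludes the miRNA.
6. **Survival models.** Cox proportional hazards with Efron's tie
   approximation, maximized by Newton–Raphson with step-halving.  For
   common miRNAs the p-value comes from a permutation distribution of the
   likelihood-ratio statistic (default B = 10,000), and the hazard ratio
   is rescaled to the interquartile range of differential expression,
   `HR = exp(beta * (Q3 - Q1))`.  Rare miRNAs get a Wald p-value for the
   binary any-expression coefficient, with no permutation or IQR scaling.
7. **FDR.** Benjamini–Hochberg q-values, computed within each
   expression-class group of each analysis stratum, pooling the discovery
   and replication study components inside a group (a `separate` mode
   adjusts components on their own; the pooled reading is the default).
8. **Descriptive survival.** Kaplan–Meier curves for colon versus rectal
   cases within each AJCC stage, compared by the Mantel–Haenszel/log-rank
   test, with display curves truncated at 60 months.

## The Cox and permutation machinery

The Efron log partial likelihood, its score, and its observed information
are implemented in compiled code; Newton–Raphson uses step-halving and
declares convergence when the largest score component is below 1e-8 or the
relative log-likelihood change is below 1e-10.  Monotone likelihood
(perfect separation) is detected by a coefficient cap at |beta| = 20 and
flagged (`monotone`) rather than iterated forever; the information matrix
is checked for rank deficiency before fitting (constant or collinear
covariates raise a rank error).  Covariates are mean-centered internally —
the partial likelihood is invariant, and conditioning improves.  Breslow's
approximation is available via `ties = "breslow"`; with no tied event
times the two coincide, which the tests verify numerically.

**What is permuted.** The focal miRNA's exposure vector is permuted across
subjects; survival times, events, and the adjustment covariates stay
fixed, and the full-vs-reduced likelihood-ratio statistic is recomputed for
each permutation.  Permuting the exposure (rather than the outcomes)
preserves the covariate–outcome association, so the test targets exactly
the miRNA's conditional effect.  The p-value uses the add-one estimator
`(1 + #{permuted LRT >= observed}) / (1 + B)`, which is strictly positive
and gives an exact level-alpha test under exchangeability.  With B = 1,000
the smallest attainable p is about 0.001; this floor interacts with BH
adjustment when many tests are run, so B should grow with the number of
miRNAs if very small q-values are needed.

Stage-restricted analyses (`stage-1-2`, `stage-3-4`) adjust for age, sex,
and MSI only; all other strata add the three stage indicator contrasts
(versus stage 1).  Contrasts constant within a subset are dropped.  Wald
95% intervals use z = 1.96 throughout.

The exposure-by-site interaction test for colon tumors takes an ordinal
subsite coding (cecum through sigmoid as consecutive integers) and
compares the adjusted model with exposure and site against the same model
plus their product, a 1-df likelihood-ratio test for a linear trend of the
exposure effect along the colon.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
subject-level data, which are restricted.  Its defaults are fixed once to
emulate the study conditions and are not tuning knobs:

* **Cohort** (`cohort_spec`): n = 1855; site mix 30.1 / 30.9 / 39.0
  percent proximal / distal / rectal; stage mix 30.0 / 26.3 / 29.4 / 14.3
  percent; age 64.2 (SD 10.2) years truncated to 30–79; 54.1 percent male.
  MSI prevalence is not reported in the cohort description; 15 percent is
  used, a typical figure for population-based colorectal cancer series.
* **Expression** (`expression_spec`): per-miRNA detection probabilities
  from a mixture (60% Beta(8,1), 40% Beta(0.8,4), floored at 0.005) chosen
  so that roughly 60 percent of miRNAs are expressed in at least half the
  population, matching the observed split between commonly and rarely
  expressed miRNAs (about 970 of 1616).  Detected log2 signal is
  `mu_j + N(0, 1)` with `mu_j ~ N(7, 2)`; the paired tumor value adds the
  planted shift plus N(0, 0.5) noise.  Detection is drawn once per
  subject–miRNA pair and shared by both tissues, so planted shifts are
  recoverable from detected paired means.  Ten percent of subjects lack a
  normal sample entirely (the imputation path is always exercised).
* **Survival** (`survival_spec`): Weibull baseline (shape 1 by default,
  the exponential special case — Cox inference is baseline-free, so any
  positive baseline is valid for testing); cause-specific death follows
  the proportional-hazards model on age, sex, stage, MSI, and the planted
  per-miRNA log-hazards; an independent exponential clock (rate
  0.0035/month) generates other-cause death, which the analysis treats as
  censoring — independence makes that censoring non-informative by
  construction.  Administrative censoring emulates staggered enrollment
  with a common analysis date: per-subject horizons uniform on 44–128
  months.  The defaults (stage contrasts 0.5 / 1.6 / 3.0, age 0.03 per
  year, sex 0.15, MSI −0.3, baseline scale 830 months, the follow-up
  range, and the other-cause rate) were calibrated once so that five-year
  cancer-specific survival is roughly 93 / 89 / 70 / 23 percent across
  stages and the cohort's observed follow-up matches the emulated study:
  mean survival time ≈ 60 months (SD ≈ 34) with just under half of
  subjects dead of any cause at last contact.  Five-year reporting
  (Kaplan–Meier display truncation at 60 months) is a display choice, not
  a data-generation cap.

What the generator does **not** emulate: probe-level array structure
(multiple probes per miRNA, replicate spots), scanner QC failures, batch
effects, correlation between miRNAs, non-proportional hazards, or
informative censoring.  Passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to those
real-data features.

## Numerical choices and conventions

* **Quantiles** use the linear-interpolation convention
  (`stats::quantile` type 7) everywhere — scaling factors, differential
  quartiles, IQR scaling.  The P75-equality invariant holds under any one
  consistent convention.
* **P75 is computed over all of a sample's values including zeros**; the
  total-gene-signal framing is sample-level and no exclusion rule is
  declared.  A sample whose P75 is 0 (possible only at very small probe
  counts or pathological inputs) raises a degenerate-sample error naming
  the subject.
* **Undetected = 0 at every stage.** Published result tables show
  differential-expression quartiles of exactly 0.00 for miRNAs expressed
  in far fewer than 100% of subjects, which is consistent with undetected
  values entering the differential distribution as 0; the package encodes
  detection explicitly so a detected log2 value of 0 (signal exactly 1) is
  never confused with absence.
* **Normalization is computed within tissue type** (carcinoma and normal
  scaled independently).  Pooling is not stated in the source analysis;
  separate scaling avoids tumor signal leaking into normal factors.
* **The imputation rule** (site-stratified per-miRNA median, gated by
  paired carcinoma detection) is a declared stand-in — the original study
  cites an external imputation procedure whose algorithm is not given —
  and is isolated behind `impute_missing_normals()` so an alternative can
  be swapped in.
* **Planted effects in validation experiments** are defined on the
  analysis scale: the planted log hazard per IQR refers to the measured
  differential expression the pipeline analyzes (the same scale on which
  IQR-scaled hazard ratios are reported), and the exposure is
  mean-centered when generating hazards so a planted expression *shift*
  moves individual risk rather than the cohort-wide event rate.
* **Prevalence is carcinoma-tissue detection.** The tissue is not named in
  the prevalence definition; carcinoma is used because the rare-miRNA
  hazard ratios are explicitly for any expression *in carcinoma tissue*.
* **Ties method** defaults to Efron (the convention of the R survival
  ecosystem in which the original analysis was run) and is switchable to
  Breslow; the choice is recorded in the run log.
* **Eligibility before prevalence.** Subjects lacking survival or stage
  information are dropped before any prevalence or expressor counting, per
  the "at least 5 individuals who had both survival and stage information"
  rule.
* The KM site-by-stage comparison reports the log-rank test both on full
  follow-up and with follow-up capped at 60 months, since the five-year
  restriction is only stated for the displayed curves.

## Problem sizes used in the tests

The test suite validates the machinery at sizes chosen to balance
statistical resolution against runtime: the end-to-end recovery experiment
uses 20 seeded cohorts of 700 subjects with 205 miRNAs (5 planted effects
of |log HR per IQR| = ln 1.5) at B = 1,000 permutations; permutation-test
size uses 1,000 null cohorts of n = 200 at B = 200; Wald coverage uses 500
replicates at n = 700; oracle equivalences (brute-force partial-likelihood
maximization, exhaustive 120-permutation enumeration, hypergeometric
log-rank, step-up FDR) run at small n where enumeration is exact.

## Known limitations

* The permutation test assumes exchangeability of the exposure across
  subjects under the null *given* that covariates are held fixed; strong
  exposure–covariate dependence makes the permutation null only
  approximately conditional.
* Rare-miRNA Wald inference can be anti-conservative when the number of
  expressor deaths is very small; the 5-expressor floor is a pragmatic
  guard, not a fix.
* With B permutations the attainable p-value floor is 1/(B+1); q-values
  near that floor are resolution-limited.
* The IQR-scaled hazard ratio inherits the quartiles of the analysis
  subset, so the same per-unit coefficient yields different reported HRs
  in different strata.
* Imputed normal rows shrink differential-expression variance toward the
  stratum median, slightly biasing per-IQR effect sizes toward the null as
  the missing fraction grows.
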