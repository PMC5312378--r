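# mirsurv

Site- and stage-specific survival analysis of paired tumor–normal miRNA
differential expression.

## What it does

In population-based colorectal cancer cohorts, the question of whether a
miRNA's dysregulation carries prognostic information is best asked on the
*differential expression* scale — the per-subject difference of log2
carcinoma signal minus log2 paired normal-mucosa signal — and separately by
tumor site (colon vs rectum) and AJCC stage, because the same dysregulation
can matter differently in different sites.  `mirsurv` implements that
analysis end to end:

* per-sample **75th-percentile scaling normalization**
  (`factor_s = median(P75) / P75_s`, making every sample's P75 equal the
  shared median), log2 transform with an undetected-as-zero convention, and
  site-stratified median **imputation** of unpaired normal samples;
* **prevalence classification**: miRNAs detected in ≥ 50% of the analysis
  population are modeled on their continuous differential expression;
  less common miRNAs (but with ≥ 5 expressors) as any-vs-no expression;
* **Cox proportional hazards** inference built from the Efron partial
  likelihood (Newton–Raphson with step-halving, compiled inner loops),
  with p-values from **permutations of the likelihood-ratio test**
  (default B = 10,000; the focal exposure is permuted, covariates and
  outcomes stay fixed; add-one estimator `p = (1 + #{LRT* ≥ LRT}) / (1 + B)`),
  adjusted for age, sex, AJCC stage, and MSI status;
* hazard ratios rescaled to the **interquartile range** of differential
  expression, `HR = exp(β (Q3 − Q1))`, with Wald 95% intervals;
* **Benjamini–Hochberg FDR** q-values pooled within expression-class
  groups of each analysis stratum (discovery and replication components
  combined);
* **Kaplan–Meier / log-rank** comparison of colon and rectal survival
  within each stage, truncated at 60 months for display;
* a seeded **synthetic-cohort generator** (clinical covariates, paired
  expression with prevalence classes and planted log2 shifts, Weibull
  baseline hazards, competing other-cause death, administrative
  censoring) so the whole pipeline is testable without restricted
  subject-level data.

The Cox, Kaplan–Meier, log-rank, and permutation machinery are implemented
in the package itself; the `survival` package is used only as an
independent cross-check in the test suite.

## Worked example

Simulate a 600-subject cohort with 50 miRNAs, one of which (mir-0001,
commonly expressed) carries a planted log-hazard of ln 2 per unit
differential expression, then run the full pipeline in colon and rectal
strata with B = 1000 permutations:

```r
library(mirsurv)

sim <- simulate_study(
  cohort_spec(n_subjects = 600),
  expression_spec(n_mirnas = 50,
                  prevalence = function(k) c(0.95, runif(k - 1, 0.05, 1))),
  survival_spec(beta_mirna = c(log(2), rep(0, 49))),
  seed = 42)

an <- analyze_cohort(sim$clinical, sim$carcinoma, sim$normal,
                     strata = c("colon", "rectal"), B = 1000, seed = 42)
an
#> <mirsurv_analysis>
#>   mirsurv 0.1.0
#>   seed=42 B=1000 ties=efron pooling=pooled q_threshold=0.05
#>   permutation target: focal exposure vector (times, events, covariates fixed)
#>   analysis population: 600 subjects (0 dropped for missing survival/stage)
#>   miRNAs: 28 common, 22 rare, 0 excluded (<5 expressors)
#>   stratum colon: 50 miRNAs analyzed, 1 with q < 0.05
#>   stratum rectal: 50 miRNAs analyzed, 1 with q < 0.05
```

Top of the colon result table (columns mirror the standard reporting
layout: % expressing, differential-expression quartiles, IQR-scaled hazard
ratio with 95% CI, raw permutation p, FDR q):

```r
res <- subset(an$results, stratum == "colon" & analysis_class == "common")
head(res[order(res$raw_p),
         c("mirna_id", "pct_expressing", "q1", "q3", "hr",
           "ci_low", "ci_high", "raw_p", "q")], 5)
#>  mirna_id pct_expressing     q1    q3    hr ci_low ci_high    raw_p     q
#>  mir-0001           95.0 -0.396 0.309 1.700  1.380    2.09 0.000999 0.028
#>  mir-0033           76.2 -0.263 0.167 0.882  0.778    1.00 0.052947 0.741
#>  mir-0041           73.2 -0.208 0.304 0.878  0.754    1.02 0.088911 0.783
#>  mir-0024           50.7  0.000 0.000 1.000  1.000    1.00 0.131868 0.783
#>  mir-0010           80.0 -0.291 0.250 1.148  0.959    1.37 0.139860 0.783
```

The planted miRNA is recovered: hazard ratio 1.70 per interquartile range
of differential expression, permutation p at the B = 1000 floor
(1/1001 ≈ 0.001), q = 0.028.  The raw p-values of the null miRNAs are
approximately uniform.  The one rectal hit (a null miRNA expressed in
12.8% of subjects, analyzed as any-vs-no expression, Wald q = 0.001) is a
false discovery — rare-class Wald inference is unstable at small
expressor counts, a known limitation discussed in the methods vignette.
A miRNA detected in barely half the population (mir-0024) has both
differential quartiles exactly 0.00 — the undetected-as-zero convention —
so its IQR-scaled hazard ratio is 1 by construction.

Stage-stratified colon-vs-rectal survival (log-rank on full follow-up and
capped at 60 months):

```r
an$km$summary
#>  stage n_colon n_rectal surv5y_colon surv5y_rectal  chisq     p  p_60
#>      1     112       60        0.862         0.918 0.3673 0.545 0.250
#>      2      96       69        0.888         0.888 0.1423 0.706 0.945
#>      3     115       58        0.648         0.669 0.1656 0.684 0.495
#>      4      54       36        0.343         0.306 0.0292 0.864 0.534
```

No site effect was planted here, so the per-stage p-values are null.
`write_analysis(an, "out/")` writes the result tables, KM step tables,
scaling factors, imputation report, and run log as TSV/text;
`inst/scripts/mirsurv-cli.R` exposes `simulate`, `run`, and `km`
subcommands over the same functions.

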