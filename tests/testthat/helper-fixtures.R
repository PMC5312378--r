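# Small programmatic fixtures shared across test files.

make_raw_em <- function(values, tissue = "carcinoma",
                        subjects = sprintf("S%03d", seq_len(nrow(values))),
                        mirnas = sprintf("mir-%03d", seq_len(ncol(values)))) {
  dimnames(values) <- list(subjects, mirnas)
  expression_matrix(values, tissue = tissue, state = "raw")
}

# Quick exponential survival data with one continuous exposure effect.
sim_surv <- function(n, beta = 0, rate0 = 0.02, censor = 60,
                     exposure = rnorm(n)) {
  t_ev <- rexp(n, rate0 * exp(beta * exposure))
  time <- pmin(t_ev, censor) + runif(n, 0, 1e-3)  # break ties
  event <- as.integer(t_ev <= censor)
  list(time = time, event = event, exposure = exposure)
}

# Fully processed small paired study for pipeline tests.  The prevalence
# floor keeps every subject's 75th percentile positive at small miRNA counts.
small_study <- function(n = 150, m = 12, seed = 11, shifts = NULL,
                        beta_mirna = 0,
                        prevalence = function(k) runif(k, 0.35, 1)) {
  es <- expression_spec(
    n_mirnas = m,
    prevalence = prevalence,
    tumor_shift_effects = shifts)
  simulate_study(cohort_spec(n_subjects = n), es,
                 survival_spec(beta_mirna = beta_mirna), seed = seed)
}
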