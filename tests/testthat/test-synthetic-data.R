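test_that("cohort generation is deterministic and respects degenerate probabilities", {
  spec <- cohort_spec(n_subjects = 4, site_probs = c(proximal = 0, distal = 0,
                                                     rectal = 1), seed = 5)
  cohort <- generate_cohort(spec)
  expect_equal(as.character(cohort$site), rep("rectal", 4))
  expect_true(all(is.na(cohort$subsite)))

  spec2 <- cohort_spec(n_subjects = 200, seed = 42)
  expect_identical(generate_cohort(spec2), generate_cohort(spec2))
})

test_that("invalid probability vectors raise configuration errors", {
  expect_error(cohort_spec(site_probs = c(0.5, 0.5, 0.1)),
               class = "mirsurv_config_error")
  expect_error(cohort_spec(stage_probs = c(0.5, 0.5)),
               class = "mirsurv_config_error")
  expect_error(expression_spec(signal_scale = -1),
               class = "mirsurv_config_error")
  expect_error(survival_spec(baseline_scale = 0),
               class = "mirsurv_config_error")
})

test_that("empirical stage frequencies converge to the spec probabilities", {
  spec <- cohort_spec(n_subjects = 10000,
                      stage_probs = c(0.30, 0.26, 0.29, 0.15), seed = 9)
  cohort <- generate_cohort(spec)
  # binomial 99.9% half-width at n = 10000, p = 0.30 is ~0.015 < 0.02
  expect_lt(abs(mean(cohort$stage == 1) - 0.30), 0.02)
  expect_lt(abs(mean(cohort$site == "rectal") - 0.390), 0.02)
  expect_lt(abs(mean(cohort$sex) - 0.541), 0.02)
})

test_that("expression generation honors prevalence, shifts, and missingness", {
  set.seed(21)
  cohort <- generate_cohort(cohort_spec(n_subjects = 2000))
  es <- expression_spec(n_mirnas = 4, prevalence = c(1, 1, 0.5, 0.2),
                        tumor_shift_effects = c(0, 1.5, 0, 0),
                        normal_missing_prob = 0.25)
  expr <- generate_expression(cohort, es)

  # degenerate prevalence: every carcinoma cell detected
  expect_true(all(expr$carcinoma$detected[, 1]))
  expect_true(all(expr$carcinoma$values[, 1] > 0))

  # missing-normal fraction within its binomial 99% interval at n = 2000
  frac_missing <- mean(expr$truth$missing_normal)
  expect_gt(frac_missing, 0.22)
  expect_lt(frac_missing, 0.28)

  # planted zero shift: paired log2 difference centered at 0 (3-SE interval)
  d1 <- expr$truth$true_differential[, 1]
  expect_lt(abs(mean(d1)), 3 * sd(d1) / sqrt(length(d1)))
  # planted 1.5 shift recoverable from detected paired means
  det2 <- expr$carcinoma$detected[, 2]
  d2 <- expr$truth$true_differential[det2, 2]
  expect_lt(abs(mean(d2) - 1.5), 3 * sd(d2) / sqrt(length(d2)))
})

test_that("survival generation respects the censoring cutoff and cause flags", {
  set.seed(3)
  cohort <- generate_cohort(cohort_spec(n_subjects = 500))
  sv <- survival_spec(other_cause_rate = 0, admin_censor_months = 60)
  out <- generate_survival(cohort, NULL, sv)
  expect_true(all(out$survival_months > 0))
  expect_true(all(out$survival_months <= 60))
  expect_true(all(out$cause[out$crc_death] == "crc"))
  expect_true(all(is.na(out$cause[out$vital_status == "alive"])))
})

test_that("Weibull shape 1 reduces to the exponential with mean = scale", {
  set.seed(14)
  cohort <- generate_cohort(cohort_spec(n_subjects = 20000))
  sv <- survival_spec(baseline_shape = 1, baseline_scale = 50,
                      beta_covariates = list(), other_cause_rate = 0,
                      admin_censor_months = 1e6)
  out <- generate_survival(cohort, NULL, sv)
  expect_true(all(out$crc_death))
  expect_lt(abs(mean(out$survival_months) - 50), 3 * 50 / sqrt(20000))
})

test_that("a planted log-hazard of ln(2) per unit is recovered by the Cox fit", {
  set.seed(8)
  cohort <- generate_cohort(cohort_spec(n_subjects = 2000))
  diff <- matrix(rnorm(2000), ncol = 1,
                 dimnames = list(cohort$subject_id, "mir-0001"))
  sv <- survival_spec(beta_mirna = log(2), beta_covariates = list(),
                      baseline_scale = 120)
  out <- generate_survival(cohort, diff, sv)
  fit <- cox_fit(out$survival_months, out$crc_death, diff[, 1])
  hr <- exp(fit$beta[[1]])
  expect_gt(hr, 1.7)
  expect_lt(hr, 2.35)
})

test_that("misaligned differential-expression rows raise an alignment error", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 10, seed = 2))
  diff <- matrix(0, 10, 1, dimnames = list(rev(cohort$subject_id), "m"))
  expect_error(generate_survival(cohort, diff, survival_spec()),
               class = "mirsurv_alignment_error")
})

test_that("simulated studies are byte-identical for a fixed seed", {
  sim1 <- small_study(n = 60, m = 5, seed = 77)
  sim2 <- small_study(n = 60, m = 5, seed = 77)
  expect_identical(sim1, sim2)

  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(sim1, d1); write_simulation(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("permutation p-values for a planted-null miRNA are uniform", {
  set.seed(1234)
  B <- 99
  pvals <- replicate(300, {
    s <- sim_surv(100, beta = 0)
    permutation_pvalue(s$time, s$event, s$exposure, B = B)$p
  })
  # add-one estimator: uniform on {1/(B+1), ..., 1}
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(pvals) - 0.5), 0.06)
})
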