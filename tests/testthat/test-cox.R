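test_that("Newton-Raphson matches a brute-force partial-likelihood maximizer", {
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    s <- sim_surv(n, beta = 0, exposure = rbinom(n, 1, 0.5) + 0)
    if (sd(s$exposure) == 0) next
    fit <- try(suppressWarnings(cox_fit(s$time, s$event, s$exposure)),
               silent = TRUE)
    if (inherits(fit, "try-error") || fit$monotone ||
        abs(fit$beta[[1]]) > 5) next
    expect_equal(fit$beta[[1]], brute_cox_beta(s$time, s$event, s$exposure),
                 tolerance = 1e-4)
  }
})

test_that("fit agrees with an independent Cox implementation, tied and untied", {
  set.seed(12)
  n <- 150
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  s <- sim_surv(n, beta = 0.5, exposure = x[, 1])
  for (ties in c("efron", "breslow")) {
    for (tied in c(FALSE, TRUE)) {
      tm <- if (tied) ceiling(s$time) else s$time
      f <- cox_fit(tm, s$event, x, ties = ties)
      g <- survival::coxph(survival::Surv(tm, s$event) ~ x, ties = ties)
      expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-7)
      expect_equal(f$loglik, g$loglik[2], tolerance = 1e-7)
      expect_equal(f$loglik_null, g$loglik[1], tolerance = 1e-7)
      expect_equal(unname(diag(f$var)), unname(diag(g$var)),
                   tolerance = 1e-6)
    }
  }
})

test_that("the fitted partial likelihood never falls below its null value", {
  set.seed(19)
  for (rep in 1:20) {
    n <- 40
    s <- sim_surv(n, beta = runif(1, -1, 1))
    fit <- cox_fit(s$time, s$event, s$exposure)
    expect_gte(fit$loglik, fit$loglik_null)
  }
})

test_that("Efron and Breslow coincide on untied data", {
  set.seed(23)
  s <- sim_surv(60, beta = 0.4)
  fe <- cox_fit(s$time, s$event, s$exposure, ties = "efron")
  fb <- cox_fit(s$time, s$event, s$exposure, ties = "breslow")
  expect_equal(fe$beta, fb$beta, tolerance = 1e-9)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-9)
})

test_that("score test at beta = 0 equals the two-group log-rank chi-square", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 50
    g <- rbinom(n, 1, 0.5)
    s <- sim_surv(n, beta = 0.5, exposure = g)  # untied by construction
    sc <- cox_score_test(s$time, s$event, g)
    lr <- logrank_test(s$time, s$event, g)
    expect_equal(sc$statistic, lr$statistic, tolerance = 1e-9)
  }
})

test_that("degenerate covariates raise rank errors", {
  s <- sim_surv(30, beta = 0)
  expect_error(cox_fit(s$time, s$event, rep(1, 30)),
               class = "mirsurv_rank_error")
  x <- cbind(a = s$exposure, b = 2 * s$exposure)
  expect_error(cox_fit(s$time, s$event, x), class = "mirsurv_rank_error")
  expect_error(cox_fit(s$time, rep(0, 30), s$exposure),
               class = "mirsurv_inference_error")
})

test_that("monotone likelihood is flagged rather than iterated forever", {
  # perfect separation: the expressor dies first, always
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)
  expect_warning(fit <- cox_fit(time, event, x), "monotone")
  expect_true(fit$monotone)
})

test_that("likelihood-ratio statistic is a floored difference of log-likelihoods", {
  set.seed(41)
  n <- 80
  x <- cbind(a = rnorm(n), b = rnorm(n))
  s <- sim_surv(n, beta = 0.6, exposure = x[, 1])
  full <- cox_fit(s$time, s$event, x)
  red <- cox_fit(s$time, s$event, x[, 1, drop = FALSE])
  expect_equal(lrt_statistic(full, full), 0)
  expect_gte(lrt_statistic(full, red), 0)
  strong <- cox_fit(s$time, s$event, x[, 1, drop = FALSE])
  weak <- cox_fit(s$time, s$event, x[, 2, drop = FALSE])
  expect_gt(2 * (strong$loglik - weak$loglik), 0)
  other <- sim_surv(79, beta = 0)
  expect_error(lrt_statistic(full, cox_fit(other$time, other$event,
                                           other$exposure)),
               class = "mirsurv_alignment_error")
})

test_that("the null LRT statistic has a chi-square(1) mean", {
  set.seed(52)
  stats <- replicate(400, {
    s <- sim_surv(120, beta = 0)
    full <- cox_fit(s$time, s$event, s$exposure)
    max(0, 2 * (full$loglik - full$loglik_null))
  })
  expect_gt(mean(stats), 0.85)
  expect_lt(mean(stats), 1.15)
})

test_that("IQR-scaled hazard ratios follow exp(beta * span)", {
  s <- sim_surv(60, beta = 0.5)
  fit <- cox_fit(s$time, s$event, s$exposure)
  b <- fit$beta[[1]]; se <- sqrt(fit$var[1, 1])
  hr <- iqr_hazard_ratio(fit, q1 = -1, q3 = 1)
  expect_equal(hr[["hr"]], exp(2 * b))
  expect_equal(hr[["ci_low"]], exp(2 * (b - 1.96 * se)))
  # zero span: HR = 1 with a degenerate interval
  hr0 <- iqr_hazard_ratio(fit, q1 = 0.3, q3 = 0.3)
  expect_equal(unname(hr0), c(1, 1, 1))
  expect_error(iqr_hazard_ratio(fit, q1 = 1, q3 = -1),
               class = "mirsurv_input_error")
})

test_that("rare-miRNA any-vs-no expression fits report Wald inference", {
  set.seed(61)
  n <- 800
  expo <- rbinom(n, 1, 0.1)
  s <- sim_surv(n, beta = log(2.2), exposure = expo)
  rr <- rare_mirna_fit(s$time, s$event, expo)
  se <- abs(log(rr$ci_high) - log(rr$hr)) / 1.96
  # estimate within 3.3 SE of the planted log hazard ratio
  expect_lt(abs(log(rr$hr) - log(2.2)), 3.3 * se)
  expect_true(rr$ci_low < rr$hr && rr$hr < rr$ci_high)
  expect_error(rare_mirna_fit(s$time, s$event, rep(0, n)),
               class = "mirsurv_floor_error")
  expect_error(rare_mirna_fit(s$time, s$event, c(rep(1, 4), rep(0, n - 4))),
               class = "mirsurv_floor_error")
})

test_that("rare-miRNA Wald p-values are uniform under the null", {
  set.seed(71)
  pvals <- replicate(300, {
    expo <- rbinom(200, 1, 0.2)
    s <- sim_surv(200, beta = 0, exposure = expo)
    rare_mirna_fit(s$time, s$event, expo)$p
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("Wald confidence intervals cover the focal coefficient about 95% of the time", {
  set.seed(81)
  beta_true <- 0.4
  cover <- replicate(300, {
    s <- sim_surv(150, beta = beta_true)
    f <- cox_fit(s$time, s$event, s$exposure)
    se <- sqrt(f$var[1, 1])
    (f$beta[[1]] - 1.96 * se) <= beta_true &&
      beta_true <= (f$beta[[1]] + 1.96 * se)
  })
  # binomial 99.9% interval around 0.95 at 300 replicates
  expect_gt(mean(cover), 0.95 - 3.3 * sqrt(0.95 * 0.05 / 300))
  expect_lt(mean(cover), 0.95 + 3.3 * sqrt(0.95 * 0.05 / 300))
})

test_that("the site-interaction LRT detects a planted trend and flags collinearity", {
  set.seed(92)
  n <- 1200
  site <- sample(1:5, n, replace = TRUE)
  expo <- rnorm(n)
  inter <- log(1.5)
  t_ev <- rexp(n, 0.02 * exp(0.1 * expo + inter * expo * (site - 3)))
  time <- pmin(t_ev, 60) + runif(n, 0, 1e-3)
  event <- as.integer(t_ev <= 60)
  res <- site_interaction_test(time, event, expo, site)
  expect_lt(res$p, 0.05)
  expect_equal(res$df, 1L)

  # interaction column duplicating an existing column -> rank error
  expect_error(site_interaction_test(time, event, rep(1, n), site),
               class = "mirsurv_rank_error")
  expect_error(site_interaction_test(time, event, expo, rep(2, n)),
               class = "mirsurv_rank_error")
})

test_that("the site-interaction LRT is calibrated under no interaction", {
  set.seed(93)
  stats <- replicate(200, {
    n <- 150
    site <- sample(1:5, n, replace = TRUE)
    expo <- rnorm(n)
    s <- sim_surv(n, beta = 0.2, exposure = expo)
    site_interaction_test(s$time, s$event, expo, site)$statistic
  })
  expect_gt(mean(stats), 0.8)
  expect_lt(mean(stats), 1.2)
})
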