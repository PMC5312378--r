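test_that("scaling factors follow the median-over-P75 rule", {
  # three samples whose 75th percentiles are 2, 4, 8 -> factors 2, 1, 0.5
  v <- rbind(rep(2, 8), rep(4, 8), rep(8, 8))
  em <- make_raw_em(v)
  expect_equal(unname(compute_scaling_factors(em)), c(2, 1, 0.5))

  # identical samples -> all factors 1
  em2 <- make_raw_em(matrix(rep(c(1, 3, 5, 7), 4), 4, 4, byrow = TRUE))
  expect_equal(unname(compute_scaling_factors(em2)), rep(1, 4))
})

test_that("a sample with zero 75th percentile is reported by name", {
  v <- rbind(c(0, 0, 0, 0, 1), c(1, 2, 3, 4, 5))
  em <- make_raw_em(v, subjects = c("BAD", "OK"))
  expect_error(compute_scaling_factors(em),
               class = "mirsurv_degenerate_sample_error")
  expect_error(compute_scaling_factors(em), "BAD")
})

test_that("scaling equalizes every sample's 75th percentile to the shared median", {
  set.seed(4)
  em <- make_raw_em(matrix(rexp(20 * 50, 0.1), 20, 50))
  target <- median(apply(em$values, 1, quantile, 0.75))
  norm <- apply_normalization(em, compute_scaling_factors(em))
  p75_after <- apply(norm$values, 1, quantile, 0.75)
  expect_lt(max(abs(p75_after - target)), 1e-9)

  # idempotence: factors on an already-normalized matrix are all ~1
  refac <- compute_scaling_factors(norm)
  expect_lt(max(abs(refac - 1)), 1e-9)
})

test_that("apply_normalization preserves zeros and validates factors", {
  em <- make_raw_em(rbind(c(10, 0), c(6, 2)))
  out <- apply_normalization(em, c(0.5, 1))
  expect_equal(unname(out$values[1, ]), c(5, 0))
  expect_identical(out$detected, em$detected)
  expect_error(apply_normalization(em, c(1, 2, 3)),
               class = "mirsurv_alignment_error")
  expect_error(apply_normalization(em, c(-1, 1)),
               class = "mirsurv_input_error")
})

test_that("log2 transform maps detected cells only and is strictly monotone", {
  em <- make_raw_em(rbind(c(8, 1, 0), c(2, 4, 16)))
  lg <- log2_transform(apply_normalization(em, c(1, 1)))
  expect_equal(unname(lg$values[1, ]), c(3, 0, 0))
  expect_false(lg$detected[1, 3])
  expect_true(lg$detected[1, 2])  # value 1 -> log2 0 but still detected
  expect_error(log2_transform(em), class = "mirsurv_state_error")

  set.seed(1)
  v <- matrix(sort(rexp(40, 0.2) + 0.01), 4, 10)
  lg2 <- log2_transform(apply_normalization(make_raw_em(v), rep(1, 4)))
  expect_true(all(diff(lg2$values[order(v)]) > 0))
})

test_that("missing normals get the site-stratified per-miRNA median", {
  v <- rbind(c(1, 5), c(3, 6), c(10, 7), c(NA, NA), c(2, 2), c(4, 4),
             c(NA, NA))
  em <- make_raw_em(v, tissue = "normal")
  site <- c("rectal", "rectal", "rectal", "rectal", "distal", "proximal",
            "proximal")
  out <- impute_missing_normals(em, site)
  expect_equal(unname(out$values[4, ]), c(3, 6))    # rectal medians
  expect_equal(unname(out$values[7, ]), c(3, 3))    # colon medians
  expect_true(all(out$imputed[4, ]))
  expect_false(any(out$imputed[1, ]))
  expect_equal(imputation_report(out)$n_cells_imputed, c(2, 2))

  # no missing rows -> unchanged, mask all FALSE
  em2 <- make_raw_em(v[1:3, , drop = FALSE], tissue = "normal")
  out2 <- impute_missing_normals(em2, rep("rectal", 3))
  expect_identical(out2, em2)
})

test_that("imputation respects paired carcinoma detection when supplied", {
  v <- rbind(c(2, 4), c(6, 8), c(NA, NA))
  nrm <- make_raw_em(v, tissue = "normal")
  tum <- make_raw_em(rbind(c(1, 2), c(3, 4), c(5, 0)))  # miRNA 2 undetected
  out <- impute_missing_normals(nrm, rep("rectal", 3), tumor = tum)
  expect_equal(unname(out$values[3, ]), c(4, 0))  # median where detected, 0 else
  expect_false(out$detected[3, 2])
  expect_true(all(out$imputed[3, ]))
})

test_that("imputation fails when a stratum lacks observed normals", {
  v <- rbind(c(1, 2), c(NA, NA), c(3, 4))
  em <- make_raw_em(v, tissue = "normal")
  expect_error(impute_missing_normals(em, c("rectal", "distal", "rectal")),
               class = "mirsurv_imputation_error")
})

test_that("imputation error is bounded by the observed residual scale", {
  set.seed(33)
  n <- 400
  cohort <- generate_cohort(cohort_spec(n_subjects = n))
  es <- expression_spec(n_mirnas = 30, prevalence = rep(1, 30),
                        subject_sd = 1, normal_missing_prob = 0.3)
  expr <- generate_expression(cohort, es)
  nrm <- impute_missing_normals(expr$normal, as.character(cohort$site))
  truth_log2 <- outer(rep(1, n), expr$truth$normal_mu)  # per-miRNA true mean
  miss <- expr$truth$missing_normal
  mae_imputed <- mean(abs(log2(nrm$values[miss, ]) - truth_log2[miss, ]))
  resid_obs <- mean(abs(log2(expr$normal$values[!miss, ]) -
                          truth_log2[!miss, ]))
  expect_lt(mae_imputed, 1.5 * resid_obs)
})
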