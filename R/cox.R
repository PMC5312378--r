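#' Cox proportional hazards fit from the partial likelihood
#'
#' Maximizes the Efron-approximation (or Breslow) log partial likelihood by
#' Newton-Raphson with step-halving.  Convergence is declared when the
#' largest score component falls below `tol_grad` or the relative
#' log-likelihood change falls below `tol_ll`.  Monotone likelihood
#' (perfect separation) is detected by a coefficient cap and flagged rather
#' than iterated forever.
#'
#' @param time positive event/censoring times.
#' @param event event indicator (1 = cause-specific death, 0 = censored).
#' @param x covariate matrix (or vector) with the covariates of interest;
#'   column names are kept on the coefficients.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param init optional starting coefficient vector.
#' @param max_iter,tol_grad,tol_ll Newton-Raphson controls.
#' @return object of class `cox_fit` with elements `beta`, `var`
#'   (inverse observed information), `loglik`, `loglik_null`, `score`,
#'   `info`, `n`, `n_events`, `iterations`, `converged`, `monotone`,
#'   `ties`.
#' @export
cox_fit <- function(time, event, x, ties = c("efron", "breslow"),
                    init = NULL, max_iter = 50L, tol_grad = 1e-8,
                    tol_ll = 1e-10) {
  ties <- match.arg(ties)
  x <- as_covariate_matrix(x)
  n <- length(time)
  if (nrow(x) != n || length(event) != n)
    alignment_error("time, event, and covariate rows must align")
  if (any(!is.finite(time)) || any(time <= 0))
    input_error("times must be finite and strictly positive")
  event <- as.integer(event)
  if (sum(event) < 1L) inference_error("no events in the data")
  check_full_rank(x)

  # center columns: the partial likelihood is invariant but conditioning improves
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  ord <- order(time)
  b0 <- if (is.null(init)) numeric(ncol(x)) else as.numeric(init)
  fit <- cox_fit_cpp(xc[ord, , drop = FALSE], event[ord], time[ord],
                     ties_code(ties), b0, as.integer(max_iter),
                     tol_grad, tol_ll)
  if (fit$singular && !fit$monotone)
    rank_error("information matrix is singular; covariates may be collinear")
  if (fit$monotone)
    warning("monotone partial likelihood (possible separation); coefficient capped",
            call. = FALSE)
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(x)
  var <- fit$var
  dimnames(var) <- list(colnames(x), colnames(x))
  structure(list(beta = beta, var = var, loglik = fit$loglik,
                 loglik_null = fit$loglik_null,
                 score = as.numeric(fit$score), info = fit$info,
                 n = n, n_events = sum(event),
                 iterations = fit$iter, converged = fit$converged,
                 monotone = fit$monotone, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, loglik = %.4f%s\n",
              x$n, x$n_events, x$ties, x$loglik,
              if (x$monotone) " [monotone likelihood: coefficient capped]" else ""))
  se <- sqrt(diag(x$var))
  tab <- data.frame(coef = x$beta, `exp(coef)` = exp(x$beta), se = se,
                    z = x$beta / se,
                    p = 2 * pnorm(-abs(x$beta / se)), check.names = FALSE)
  print(tab, digits = 4)
  invisible(x)
}

as_covariate_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L,
                                   dimnames = list(NULL, "x"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  x
}

ties_code <- function(ties) if (ties == "breslow") 1L else 0L

check_full_rank <- function(x) {
  if (ncol(x) == 0L) return(invisible(TRUE))
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    rank_error(sprintf("constant covariate(s): %s",
                       paste(colnames(x)[sds == 0], collapse = ", ")))
  if (qr(sweep(x, 2L, colMeans(x)))$rank < ncol(x))
    rank_error("covariate matrix is rank deficient (collinear columns)")
  invisible(TRUE)
}

#' Partial-likelihood evaluation, score, and information
#'
#' Evaluates the log partial likelihood and its derivatives at an arbitrary
#' coefficient vector; the score test at `beta = 0` for a single binary
#' covariate reproduces the two-group log-rank chi-square.
#'
#' @inheritParams cox_fit
#' @param beta coefficient vector at which to evaluate.
#' @return list with `loglik`, `score`, `info`.
#' @export
cox_eval <- function(time, event, x, beta, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as_covariate_matrix(x)
  ord <- order(time)
  cox_eval_cpp(x[ord, , drop = FALSE], as.integer(event)[ord], time[ord],
               as.numeric(beta), ties_code(ties))
}

#' Score test at beta = 0
#'
#' @inheritParams cox_eval
#' @return list with `statistic` (U' I^-1 U), `df`, `p`.
#' @export
cox_score_test <- function(time, event, x, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as_covariate_matrix(x)
  ev <- cox_eval(time, event, x, beta = numeric(ncol(x)), ties = ties)
  stat <- as.numeric(t(ev$score) %*% solve(ev$info, ev$score))
  list(statistic = stat, df = ncol(x),
       p = pchisq(stat, df = ncol(x), lower.tail = FALSE))
}

#' Likelihood-ratio statistic between nested Cox fits
#'
#' @param full,reduced `cox_fit` objects on the same data with nested
#'   covariate sets.
#' @return `2 * (loglik_full - loglik_reduced)`, floored at 0.
#' @export
lrt_statistic <- function(full, reduced) {
  if (!inherits(full, "cox_fit") || !inherits(reduced, "cox_fit"))
    input_error("inputs must be cox_fit objects")
  if (full$n != reduced$n || full$n_events != reduced$n_events)
    alignment_error("fits do not come from the same data")
  max(0, 2 * (full$loglik - reduced$loglik))
}

#' Permutation likelihood-ratio p-value for a focal exposure
#'
#' Fits the full model (adjustment covariates plus the focal exposure) and
#' the reduced model (covariates only), then permutes the exposure values
#' across subjects `B` times -- holding times, events, and covariates fixed --
#' refitting the full model each time.  The p-value uses the add-one
#' estimator `(1 + #\{permuted LRT >= observed LRT\}) / (1 + B)`, so it is
#' always strictly positive.  Results are reproducible under `set.seed()`
#' (or via the `seed` argument).
#'
#' @inheritParams cox_fit
#' @param exposure numeric focal exposure vector (non-constant).
#' @param covariates adjustment covariate matrix or `NULL`.
#' @param B number of permutations (default 10000).
#' @param seed optional integer seed.
#' @param return_stats keep the permuted statistics?
#' @return list with `p`, `lrt_obs`, `count_ge`, `B`, `fit_full`,
#'   `fit_reduced`, and optionally `stats`.
#' @export
permutation_pvalue <- function(time, event, exposure, covariates = NULL,
                               B = 10000L, ties = c("efron", "breslow"),
                               seed = NULL, return_stats = FALSE,
                               max_iter = 25L, tol_grad = 1e-8,
                               tol_ll = 1e-10) {
  ties <- match.arg(ties)
  if (!is.null(seed)) set.seed(seed)
  if (B < 1L) config_error("B must be at least 1")
  exposure <- as.numeric(exposure)
  if (sd(exposure) == 0) inference_error("focal exposure is constant")
  n <- length(time)
  if (length(exposure) != n)
    alignment_error("exposure length does not match the data")

  if (is.null(covariates) || NCOL(covariates) == 0L) {
    xcov <- matrix(numeric(0), nrow = n, ncol = 0L)
    fit_reduced <- NULL
    ll_reduced <- cox_eval(time, event, matrix(0, n, 1L,
                                               dimnames = list(NULL, "z")),
                           beta = 0, ties = ties)$loglik
    beta_red <- numeric(0)
  } else {
    xcov <- as_covariate_matrix(covariates)
    fit_reduced <- cox_fit(time, event, xcov, ties = ties,
                           max_iter = max_iter, tol_grad = tol_grad,
                           tol_ll = tol_ll)
    ll_reduced <- fit_reduced$loglik
    beta_red <- fit_reduced$beta
  }
  xfull <- cbind(xcov, exposure = exposure)
  fit_full <- cox_fit(time, event, xfull, ties = ties,
                      init = c(beta_red, 0),
                      max_iter = max_iter, tol_grad = tol_grad,
                      tol_ll = tol_ll)
  lrt_obs <- max(0, 2 * (fit_full$loglik - ll_reduced))

  ctr <- colMeans(xfull)
  xc <- sweep(xfull, 2L, ctr)
  ord <- order(time)
  res <- cox_perm_lrt_cpp(xc[ord, , drop = FALSE], as.integer(event)[ord],
                          time[ord], ties_code(ties), as.integer(B),
                          lrt_obs, ll_reduced, c(beta_red, 0),
                          as.integer(max_iter), tol_grad, tol_ll,
                          return_stats)
  out <- list(p = (1 + res$count_ge) / (1 + B), lrt_obs = lrt_obs,
              count_ge = res$count_ge, B = B,
              fit_full = fit_full, fit_reduced = fit_reduced)
  if (return_stats) out$stats <- as.numeric(res$stats)
  out
}

#' Interquartile-range-scaled hazard ratio
#'
#' Rescales a fitted log-hazard coefficient to the interquartile span of the
#' exposure: `HR = exp(beta * (q3 - q1))` with the Wald 95% interval
#' `exp((beta +/- 1.96 se) * (q3 - q1))`.
#'
#' @param fit a `cox_fit`.
#' @param q1,q3 25th and 75th percentiles of the exposure (`q3 >= q1`).
#' @param coef name or index of the focal coefficient (default: last).
#' @return named numeric vector `c(hr, ci_low, ci_high)`.
#' @export
iqr_hazard_ratio <- function(fit, q1, q3, coef = length(fit$beta)) {
  if (!inherits(fit, "cox_fit")) input_error("'fit' must be a cox_fit")
  if (q3 < q1) input_error("q3 must be >= q1")
  b <- fit$beta[[coef]]
  se <- sqrt(diag(fit$var))[[coef]]
  span <- q3 - q1
  c(hr = exp(b * span),
    ci_low = exp((b - 1.96 * se) * span),
    ci_high = exp((b + 1.96 * se) * span))
}

#' Any-versus-no expression Cox fit for rarely expressed miRNAs
#'
#' Fits the adjusted Cox model with a binary any-expression exposure and
#' reports the per-unit hazard ratio with its Wald p-value (no permutation,
#' no IQR scaling).
#'
#' @inheritParams permutation_pvalue
#' @param any_expression binary (0/1 or logical) exposure; at least 5
#'   expressors are required.
#' @return list with `hr`, `ci_low`, `ci_high`, `p`, `n_expressors`, `fit`.
#' @export
rare_mirna_fit <- function(time, event, any_expression, covariates = NULL,
                           ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  any_expression <- as.numeric(any_expression != 0)
  n_exp <- sum(any_expression)
  if (n_exp < 5)
    floor_error(sprintf("only %d expressors; at least 5 required", n_exp))
  xfull <- if (is.null(covariates)) {
    matrix(any_expression, ncol = 1L, dimnames = list(NULL, "any_expression"))
  } else {
    cbind(as_covariate_matrix(covariates), any_expression = any_expression)
  }
  fit <- cox_fit(time, event, xfull, ties = ties)
  b <- fit$beta[["any_expression"]]
  se <- sqrt(diag(fit$var))[["any_expression"]]
  list(hr = exp(b), ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
       p = 2 * pnorm(-abs(b / se)), n_expressors = n_exp, fit = fit)
}

#' Exposure-by-site interaction test within the colon
#'
#' Likelihood-ratio test (1 df) comparing the adjusted model with the focal
#' exposure and an ordinal site term against the same model plus their
#' product, targeting a linear trend in the exposure effect along the
#' ordinal site axis (e.g. cecum through sigmoid).
#'
#' @inheritParams permutation_pvalue
#' @param ordinal_site consecutive-integer site coding for colon subjects.
#' @return list with `statistic`, `df`, `p`, `interaction_beta`.
#' @export
site_interaction_test <- function(time, event, exposure, ordinal_site,
                                  covariates = NULL,
                                  ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  ordinal_site <- as.numeric(ordinal_site)
  if (sd(ordinal_site) == 0) rank_error("ordinal site variable is constant")
  base <- cbind(exposure = as.numeric(exposure), site = ordinal_site)
  if (!is.null(covariates)) base <- cbind(base, as_covariate_matrix(covariates))
  xfull <- cbind(base, exposure_x_site = as.numeric(exposure) * ordinal_site)
  check_full_rank(xfull)
  fit_red <- cox_fit(time, event, base, ties = ties)
  fit_full <- cox_fit(time, event, xfull, ties = ties,
                      init = c(fit_red$beta, 0))
  stat <- lrt_statistic(fit_full, fit_red)
  list(statistic = stat, df = 1L,
       p = pchisq(stat, df = 1L, lower.tail = FALSE),
       interaction_beta = fit_full$beta[["exposure_x_site"]])
}
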