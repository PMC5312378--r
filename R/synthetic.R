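#' Specification of a synthetic clinical cohort
#'
#' Defaults mirror the marginal composition of a large population-based
#' colorectal cancer cohort: roughly 30/31/39 percent proximal colon /
#' distal colon / rectal tumors, AJCC stage mix 30/26/29/14 percent, mean
#' age at diagnosis 64.2 (SD 10.2) years, 54 percent male, and 15 percent
#' microsatellite-unstable tumors.
#'
#' @param n_subjects cohort size.
#' @param site_probs probabilities over proximal / distal / rectal
#'   (must sum to 1 within 1e-12).
#' @param stage_probs probabilities over AJCC stages 1-4.
#' @param msi_prob fraction microsatellite unstable.
#' @param age_mean,age_sd age-at-diagnosis distribution in years
#'   (truncated to 30-79).
#' @param sex_prob fraction male.
#' @param seed optional integer seed consumed by [generate_cohort()].
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 1855,
                        site_probs = c(proximal = 0.301, distal = 0.309,
                                       rectal = 0.390),
                        stage_probs = c(0.300, 0.263, 0.294, 0.143),
                        msi_prob = 0.15, age_mean = 64.2, age_sd = 10.2,
                        sex_prob = 0.541, seed = NULL) {
  if (n_subjects < 1) config_error("n_subjects must be >= 1")
  check_probs(site_probs, 3L, "site_probs")
  check_probs(stage_probs, 4L, "stage_probs")
  if (msi_prob < 0 || msi_prob > 1 || sex_prob < 0 || sex_prob > 1)
    config_error("msi_prob and sex_prob must lie in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 site_probs = site_probs, stage_probs = stage_probs,
                 msi_prob = msi_prob, age_mean = age_mean, age_sd = age_sd,
                 sex_prob = sex_prob, seed = seed),
            class = "cohort_spec")
}

check_probs <- function(p, len, what) {
  if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-12)
    config_error(sprintf("%s must be %d non-negative probabilities summing to 1",
                         what, len))
}

#' Generate a synthetic clinical cohort
#'
#' Draws subject-level covariates (age, sex, tumor site with an ordinal
#' colon subsite, AJCC stage, MSI status) from the marginals in the spec.
#' Deterministic for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with one row per subject: `subject_id`, `age`, `sex`
#'   (1 = male), `site` (factor proximal/distal/rectal), `subsite` (ordinal
#'   1-5 cecum through sigmoid for colon subjects, `NA` for rectal),
#'   `stage` (integer 1-4), `msi` (0/1).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) config_error("'spec' must be a cohort_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_subjects
  age <- pmin(pmax(rnorm(n, spec$age_mean, spec$age_sd), 30), 79)
  sex <- rbinom(n, 1L, spec$sex_prob)
  site <- factor(sample(c("proximal", "distal", "rectal"), n, replace = TRUE,
                        prob = spec$site_probs),
                 levels = c("proximal", "distal", "rectal"))
  # ordinal colon subsite: 1 cecum .. 3 transverse (proximal), 4-5 (distal)
  subsite <- rep(NA_integer_, n)
  subsite[site == "proximal"] <- sample(1:3, sum(site == "proximal"),
                                        replace = TRUE)
  subsite[site == "distal"] <- sample(4:5, sum(site == "distal"),
                                      replace = TRUE)
  stage <- sample(1:4, n, replace = TRUE, prob = spec$stage_probs)
  msi <- rbinom(n, 1L, spec$msi_prob)
  data.frame(subject_id = sprintf("S%05d", seq_len(n)), age = age, sex = sex,
             site = site, subsite = subsite, stage = stage, msi = msi,
             stringsAsFactors = FALSE)
}

#' Specification of synthetic paired expression data
#'
#' Each miRNA gets a detection probability (its prevalence) from
#' `prevalence`; each subject-miRNA pair is detected with that probability,
#' jointly for the carcinoma and normal tissue.  Detected normal-tissue
#' log2 signal is `mu_j + N(0, subject_sd)` with per-miRNA level
#' `mu_j ~ N(signal_location, signal_scale)`; the paired carcinoma log2
#' signal adds the planted differential-expression shift plus
#' `N(0, tumor_noise_sd)` noise.  Raw signal is `2^log2` for detected cells
#' and exactly 0 otherwise.  A random subset of subjects has an all-missing
#' normal row, emulating unpaired samples.
#'
#' The default prevalence distribution is a mixture -- 60 percent of miRNAs
#' from Beta(8, 1) (commonly expressed) and 40 percent from Beta(0.8, 4)
#' (rarely expressed), floored at 0.005 -- so that roughly 60 percent of
#' miRNAs end up expressed in at least half the population.
#'
#' @param n_mirnas number of miRNAs.
#' @param prevalence either a function of `m` returning detection
#'   probabilities in `(0, 1]`, or a fixed numeric vector of length
#'   `n_mirnas`.
#' @param signal_location,signal_scale mean and SD of per-miRNA log2 signal
#'   level (raw signal `2^location` is strictly positive).
#' @param subject_sd within-miRNA between-subject SD on the log2 scale.
#' @param tumor_noise_sd SD of the paired carcinoma-minus-normal noise.
#' @param tumor_shift_effects per-miRNA true mean log2 differential
#'   expression (default all 0).
#' @param normal_missing_prob fraction of subjects with no normal sample.
#' @param seed optional integer seed consumed by [generate_expression()].
#' @return an `expression_spec` list.
#' @export
expression_spec <- function(n_mirnas = 1616,
                            prevalence = default_prevalence_fn,
                            signal_location = 7, signal_scale = 2,
                            subject_sd = 1, tumor_noise_sd = 0.5,
                            tumor_shift_effects = NULL,
                            normal_missing_prob = 0.10, seed = NULL) {
  if (n_mirnas < 1) config_error("n_mirnas must be >= 1")
  if (signal_scale <= 0 || subject_sd <= 0 || tumor_noise_sd < 0)
    config_error("signal scale parameters must be strictly positive")
  if (normal_missing_prob < 0 || normal_missing_prob > 1)
    config_error("normal_missing_prob must lie in [0, 1]")
  if (is.null(tumor_shift_effects)) tumor_shift_effects <- numeric(n_mirnas)
  if (length(tumor_shift_effects) != n_mirnas)
    config_error("tumor_shift_effects must have one entry per miRNA")
  if (is.numeric(prevalence) && length(prevalence) != n_mirnas)
    config_error("fixed prevalence vector must have one entry per miRNA")
  structure(list(n_mirnas = as.integer(n_mirnas), prevalence = prevalence,
                 signal_location = signal_location,
                 signal_scale = signal_scale, subject_sd = subject_sd,
                 tumor_noise_sd = tumor_noise_sd,
                 tumor_shift_effects = tumor_shift_effects,
                 normal_missing_prob = normal_missing_prob, seed = seed),
            class = "expression_spec")
}

#' @rdname expression_spec
#' @param m number of draws.
#' @export
default_prevalence_fn <- function(m) {
  hi <- runif(m) < 0.6
  pmax(ifelse(hi, rbeta(m, 8, 1), rbeta(m, 0.8, 4)), 0.005)
}

#' Generate paired carcinoma / normal expression matrices
#'
#' @param cohort data frame from [generate_cohort()].
#' @param spec an [expression_spec()].
#' @return list with `carcinoma` and `normal` (`expression_matrix` objects,
#'   raw state) and `truth` (list with `prevalence`, `shifts`, and
#'   `true_differential`, the planted log2 tumor-minus-normal matrix under
#'   the undetected-as-zero convention).
#' @export
generate_expression <- function(cohort, spec) {
  if (!inherits(spec, "expression_spec"))
    config_error("'spec' must be an expression_spec")
  n <- nrow(cohort)
  if (n == 0L) input_error("cohort is empty")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  m <- spec$n_mirnas
  prev <- if (is.function(spec$prevalence)) spec$prevalence(m) else spec$prevalence
  if (any(prev <= 0 | prev > 1))
    config_error("prevalence draws must lie in (0, 1]")
  mirna_ids <- sprintf("mir-%04d", seq_len(m))
  subj <- cohort$subject_id

  detected <- matrix(runif(n * m) < rep(prev, each = n), n, m)
  mu <- rnorm(m, spec$signal_location, spec$signal_scale)
  normal_log2 <- matrix(rep(mu, each = n), n, m) +
    matrix(rnorm(n * m, 0, spec$subject_sd), n, m)
  tumor_log2 <- normal_log2 +
    matrix(rep(spec$tumor_shift_effects, each = n), n, m) +
    matrix(rnorm(n * m, 0, spec$tumor_noise_sd), n, m)

  carcinoma <- ifelse(detected, 2^tumor_log2, 0)
  normal <- ifelse(detected, 2^normal_log2, 0)
  dimnames(carcinoma) <- dimnames(normal) <- list(subj, mirna_ids)

  true_diff <- ifelse(detected, tumor_log2 - normal_log2, 0)
  dimnames(true_diff) <- list(subj, mirna_ids)

  miss <- runif(n) < spec$normal_missing_prob
  normal[miss, ] <- NA_real_

  list(carcinoma = expression_matrix(carcinoma, tissue = "carcinoma",
                                     state = "raw"),
       normal = expression_matrix(normal, tissue = "normal", state = "raw"),
       truth = list(prevalence = setNames(prev, mirna_ids),
                    shifts = setNames(spec$tumor_shift_effects, mirna_ids),
                    true_differential = true_diff,
                    normal_mu = setNames(mu, mirna_ids),
                    missing_normal = setNames(miss, subj)))
}

#' Specification of the synthetic survival mechanism
#'
#' Cause-specific death times follow a proportional-hazards model with a
#' Weibull baseline (shape 1 gives the exponential special case): the
#' linear predictor combines age (per year, centered at 65), sex, AJCC
#' stage indicator contrasts versus stage 1, MSI status, optional
#' site terms, and the planted per-miRNA log-hazards applied to the
#' differential-expression matrix.  An independent exponential clock
#' generates competing other-cause death (treated downstream as
#' non-informative censoring).  Administrative censoring emulates the
#' staggered enrollment of a multi-year study with a common analysis date:
#' each subject's horizon is drawn uniformly from the
#' `admin_censor_months` range (a scalar gives a fixed horizon).
#'
#' Default covariate effects are calibrated so that five-year
#' cancer-specific survival is roughly 93 / 89 / 70 / 23 percent across
#' stages 1-4; the default 44-128-month follow-up horizon and other-cause
#' rate give a cohort with mean observed survival of about 60 months
#' (SD ~34) and just under half of subjects dead of any cause at last
#' contact.
#'
#' @param baseline_shape,baseline_scale Weibull baseline parameters
#'   (months; both strictly positive).
#' @param beta_mirna per-miRNA log-hazard per unit differential expression
#'   (default all 0; recycled to the matrix width if length 1).
#' @param beta_covariates named list of log-hazards: `age` (per year vs 65),
#'   `sex`, `stage2`, `stage3`, `stage4`, `msi`, and optional `rectal` and
#'   `rectal_low_stage` (extra hazard for rectal tumors at stages 1-2, for
#'   planting site-by-stage survival differences).
#' @param other_cause_rate exponential rate of other-cause death per month.
#' @param admin_censor_months administrative censoring horizon: a scalar
#'   (fixed horizon) or an ascending length-2 range for per-subject uniform
#'   horizons.
#' @param seed optional integer seed consumed by [generate_survival()].
#' @return a `survival_spec` list.
#' @export
survival_spec <- function(baseline_shape = 1, baseline_scale = 830,
                          beta_mirna = 0,
                          beta_covariates = list(age = 0.03, sex = 0.15,
                                                 stage2 = 0.5, stage3 = 1.6,
                                                 stage4 = 3.0, msi = -0.3),
                          other_cause_rate = 0.0035,
                          admin_censor_months = c(44, 128), seed = NULL) {
  if (baseline_shape <= 0 || baseline_scale <= 0)
    config_error("Weibull baseline parameters must be strictly positive")
  if (other_cause_rate < 0) config_error("other_cause_rate must be >= 0")
  if (!length(admin_censor_months) %in% 1:2 || any(admin_censor_months <= 0) ||
      is.unsorted(admin_censor_months))
    config_error("admin_censor_months must be a positive scalar or ascending range")
  defaults <- list(age = 0, sex = 0, stage2 = 0, stage3 = 0, stage4 = 0,
                   msi = 0, rectal = 0, rectal_low_stage = 0)
  defaults[names(beta_covariates)] <- beta_covariates
  structure(list(baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale, beta_mirna = beta_mirna,
                 beta_covariates = defaults,
                 other_cause_rate = other_cause_rate,
                 admin_censor_months = admin_censor_months, seed = seed),
            class = "survival_spec")
}

#' Generate survival outcomes for a synthetic cohort
#'
#' @param cohort data frame from [generate_cohort()].
#' @param diff_expression subjects x miRNAs matrix of (true) differential
#'   expression whose rownames match `cohort$subject_id`, or `NULL` for no
#'   miRNA effect.
#' @param spec a [survival_spec()].
#' @return `cohort` with columns `survival_months` (> 0), `vital_status`
#'   (`"dead"`/`"alive"`), `crc_death` (logical: cancer-specific death, the
#'   analysis event), and `cause` (`"crc"`, `"other"`, or `NA`).
#' @export
generate_survival <- function(cohort, diff_expression = NULL, spec) {
  if (!inherits(spec, "survival_spec"))
    config_error("'spec' must be a survival_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- nrow(cohort)
  b <- spec$beta_covariates
  lp <- b$age * (cohort$age - 65) + b$sex * cohort$sex +
    b$stage2 * (cohort$stage == 2) + b$stage3 * (cohort$stage == 3) +
    b$stage4 * (cohort$stage == 4) + b$msi * cohort$msi +
    b$rectal * (cohort$site == "rectal") +
    b$rectal_low_stage * (cohort$site == "rectal" & cohort$stage <= 2)
  if (!is.null(diff_expression)) {
    if (!identical(rownames(diff_expression), cohort$subject_id))
      alignment_error("diff_expression rows do not align with the cohort")
    beta <- rep_len(spec$beta_mirna, ncol(diff_expression))
    lp <- lp + as.numeric(diff_expression %*% beta)
  }
  u <- runif(n)
  t_crc <- spec$baseline_scale *
    (-log(u) / exp(lp))^(1 / spec$baseline_shape)
  t_other <- if (spec$other_cause_rate > 0) {
    rexp(n, spec$other_cause_rate)
  } else {
    rep(Inf, n)
  }
  adm <- if (length(spec$admin_censor_months) == 2L) {
    runif(n, spec$admin_censor_months[1], spec$admin_censor_months[2])
  } else {
    rep(spec$admin_censor_months, n)
  }
  obs <- pmin(t_crc, t_other, adm)
  crc_death <- t_crc <= pmin(t_other, adm)
  other_death <- !crc_death & t_other <= adm
  cohort$survival_months <- obs
  cohort$vital_status <- ifelse(crc_death | other_death, "dead", "alive")
  cohort$crc_death <- crc_death
  cohort$cause <- ifelse(crc_death, "crc", ifelse(other_death, "other", NA))
  cohort
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: one master seed drives cohort, expression, and
#' survival generation in sequence (per-spec seeds, if set, are ignored in
#' favor of the single stream so the whole study is reproducible from one
#' integer).
#'
#' @param cohort a [cohort_spec()].
#' @param expression an [expression_spec()].
#' @param survival a [survival_spec()].
#' @param seed master integer seed.
#' @return list with `clinical` (cohort + survival columns), `carcinoma`,
#'   `normal` (raw `expression_matrix` objects), and `truth`.
#' @export
simulate_study <- function(cohort = cohort_spec(),
                           expression = expression_spec(),
                           survival = survival_spec(), seed = 1L) {
  set.seed(seed)
  cohort$seed <- expression$seed <- survival$seed <- NULL
  subjects <- generate_cohort(cohort)
  expr <- generate_expression(subjects, expression)
  clinical <- generate_survival(subjects, expr$truth$true_differential,
                                survival)
  list(clinical = clinical, carcinoma = expr$carcinoma,
       normal = expr$normal, truth = expr$truth, seed = seed)
}

#' Write a simulated study to disk
#'
#' Writes the clinical table and the two expression matrices as TSV files
#' with one-line headers (subject ids in the first column), plus a YAML
#' sidecar recording the generator parameters and seed.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @param specs optional list of the three specs to record in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, specs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(sim$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_expression_matrix(sim$carcinoma, file.path(dir, "carcinoma.tsv"))
  write_expression_matrix(sim$normal, file.path(dir, "normal.tsv"))
  meta <- list(seed = sim$seed,
               n_subjects = nrow(sim$clinical),
               n_mirnas = ncol(sim$carcinoma$values))
  if (!is.null(specs))
    meta$specs <- lapply(specs, function(s)
      lapply(unclass(s), function(f) if (is.function(f)) "<function>" else f))
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}
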