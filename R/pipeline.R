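STRATA_VOCAB <- c("overall", "colon", "rectal", "proximal", "distal",
                  "stage-1-2", "stage-3-4")

#' Analysis configuration
#'
#' @param clinical,carcinoma,normal input file paths (TSV).
#' @param literature_mirnas optional path to a plain-text file listing the
#'   previously reported miRNAs (one id per line); membership routes result
#'   rows to the replication component, model fitting is identical.
#' @param strata analysis strata to run, from `overall`, `colon`, `rectal`,
#'   `proximal`, `distal`, `stage-1-2`, `stage-3-4`.
#' @param B permutations for the likelihood-ratio p-values (default 10000).
#' @param seed integer seed for every random draw.
#' @param ties `"efron"` or `"breslow"`.
#' @param q_threshold FDR significance threshold (default 0.05).
#' @param pooling `"pooled"` or `"separate"` component pooling for FDR.
#' @param output_dir directory for the result tables and run log.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(clinical, carcinoma, normal,
                            literature_mirnas = NULL,
                            strata = c("colon", "rectal"), B = 10000L,
                            seed = 1L, ties = "efron", q_threshold = 0.05,
                            pooling = "pooled", output_dir = "mirsurv-output") {
  bad <- setdiff(strata, STRATA_VOCAB)
  if (length(bad))
    config_error(paste0("unknown strata: ", paste(bad, collapse = ", ")))
  for (f in c(clinical, carcinoma, normal, literature_mirnas)) {
    if (!is.null(f) && !file.exists(f))
      config_error(paste0("input file does not exist: ", f))
  }
  if (!ties %in% c("efron", "breslow"))
    config_error("ties must be 'efron' or 'breslow'")
  structure(list(clinical = clinical, carcinoma = carcinoma, normal = normal,
                 literature_mirnas = literature_mirnas, strata = strata,
                 B = as.integer(B), seed = as.integer(seed), ties = ties,
                 q_threshold = q_threshold, pooling = pooling,
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Read a clinical table
#'
#' TSV with columns `subject_id`, `age`, `sex`, `site`, `stage`, `msi`,
#' `survival_months`, `vital_status`, `crc_death` (and optionally
#' `subsite`, `cause`).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_clinical_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "age", "sex", "site", "stage", "msi",
              "survival_months", "crc_death")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    input_error(paste0("clinical table lacks column(s): ",
                       paste(missing_cols, collapse = ", ")))
  df$site <- factor(df$site, levels = c("proximal", "distal", "rectal"))
  df$crc_death <- as.logical(df$crc_death)
  df
}

stratum_mask <- function(clinical, stratum) {
  switch(stratum,
         "overall" = rep(TRUE, nrow(clinical)),
         "colon" = clinical$site %in% c("proximal", "distal"),
         "rectal" = clinical$site == "rectal",
         "proximal" = clinical$site == "proximal",
         "distal" = clinical$site == "distal",
         "stage-1-2" = clinical$stage <= 2,
         "stage-3-4" = clinical$stage >= 3,
         config_error(paste0("unknown stratum: ", stratum)))
}

# Adjustment covariates for a stratum.  Stage-restricted analyses adjust for
# age, sex, and MSI only; all others add the stage indicator contrasts.
# Contrasts constant within the subset are dropped.
stratum_covariates <- function(clinical, stratum) {
  x <- cbind(age = clinical$age, sex = clinical$sex)
  if (!stratum %in% c("stage-1-2", "stage-3-4")) {
    x <- cbind(x, stage2 = as.numeric(clinical$stage == 2),
               stage3 = as.numeric(clinical$stage == 3),
               stage4 = as.numeric(clinical$stage == 4))
  }
  x <- cbind(x, msi = clinical$msi)
  keep <- apply(x, 2L, sd) > 0
  x[, keep, drop = FALSE]
}

#' Run the full miRNA-survival analysis on in-memory inputs
#'
#' Executes normalize -> impute -> log2 -> differential -> prevalence
#' classification -> per-stratum survival models -> FDR, plus the
#' stage-stratified Kaplan-Meier comparison of colon and rectal survival.
#' Commonly expressed miRNAs are analyzed on continuous differential
#' expression with permutation likelihood-ratio p-values and
#' interquartile-range-scaled hazard ratios; rarely expressed miRNAs on
#' any-versus-no expression with Wald p-values.  Subjects lacking survival
#' or stage data are dropped before any prevalence computation.
#'
#' @param clinical clinical data frame (see [read_clinical_table()]).
#' @param carcinoma,normal raw `expression_matrix` objects aligned with
#'   `clinical$subject_id`.
#' @param literature_mirnas character vector of previously reported miRNA
#'   ids (the replication component); all other miRNAs form the discovery
#'   component.
#' @inheritParams analysis_config
#' @param verbose print progress?
#' @return object of class `mirsurv_analysis`: list with `results` (one row
#'   per analyzed miRNA per stratum, mirroring the standard result-table
#'   columns `pct_expressing`, `q1`, `q3`, `hr`, `ci_low`, `ci_high`,
#'   `raw_p`, `q`), `excluded`, `classification`, `factors`,
#'   `imputation`, `km`, `config`, and `log` (run-log lines).
#' @export
analyze_cohort <- function(clinical, carcinoma, normal,
                           literature_mirnas = character(),
                           strata = c("colon", "rectal"), B = 10000L,
                           seed = 1L, ties = "efron", q_threshold = 0.05,
                           pooling = "pooled", verbose = FALSE) {
  bad <- setdiff(strata, STRATA_VOCAB)
  if (length(bad))
    config_error(paste0("unknown strata: ", paste(bad, collapse = ", ")))

  ids <- clinical$subject_id
  for (em in list(carcinoma, normal)) {
    off <- union(setdiff(ids, em_subjects(em)), setdiff(em_subjects(em), ids))
    if (length(off))
      alignment_error(paste0(
        "subject ids differ between clinical and ", em$tissue,
        " expression files: ", paste(utils::head(off, 10), collapse = ", ")))
  }
  if (!identical(em_subjects(carcinoma), ids) ||
      !identical(em_subjects(normal), ids))
    alignment_error("expression rows must be ordered as in the clinical table")

  # analysis population: survival and stage information present
  eligible <- !is.na(clinical$survival_months) & clinical$survival_months > 0 &
    !is.na(clinical$stage)
  clinical <- clinical[eligible, , drop = FALSE]
  carcinoma <- em_subset(carcinoma, eligible)
  normal <- em_subset(normal, eligible)

  proc <- process_expression(carcinoma, normal, clinical$site)
  nrm <- proc$normal
  diff <- proc$diff
  fac_c <- proc$factors$carcinoma
  fac_n <- proc$factors$normal

  prevalence <- compute_prevalence(carcinoma)
  n_expr <- colSums(carcinoma$detected)
  classification <- classify_mirnas(prevalence, n_expr)
  classification$component <- ifelse(
    classification$mirna_id %in% literature_mirnas, "replication", "discovery")

  set.seed(seed)
  rows <- list()
  excluded <- list()
  log_lines <- c(
    sprintf("mirsurv %s", as.character(packageVersion("mirsurv"))),
    sprintf("seed=%d B=%d ties=%s pooling=%s q_threshold=%g", seed, B, ties,
            pooling, q_threshold),
    "permutation target: focal exposure vector (times, events, covariates fixed)",
    sprintf("analysis population: %d subjects (%d dropped for missing survival/stage)",
            nrow(clinical), sum(!eligible)),
    sprintf("miRNAs: %d common, %d rare, %d excluded (<5 expressors)",
            sum(classification$analysis_class == "common"),
            sum(classification$analysis_class == "rare"),
            sum(classification$analysis_class == "excluded")))

  for (st in strata) {
    mask <- stratum_mask(clinical, st)
    sub <- clinical[mask, , drop = FALSE]
    if (nrow(sub) == 0L || sum(sub$crc_death) == 0L) {
      warning(sprintf("stratum '%s' has no events; skipped", st))
      log_lines <- c(log_lines, sprintf("stratum %s: skipped (no events)", st))
      next
    }
    covs <- stratum_covariates(sub, st)
    time <- sub$survival_months
    event <- as.integer(sub$crc_death)
    quart <- differential_quartiles(diff, mask)
    if (verbose)
      message(sprintf("stratum %s: n=%d events=%d", st, nrow(sub), sum(event)))

    for (k in seq_len(nrow(classification))) {
      mid <- classification$mirna_id[k]
      cls <- classification$analysis_class[k]
      comp <- classification$component[k]
      pct <- classification$pct_expressing[k]
      if (cls == "excluded") {
        excluded[[length(excluded) + 1L]] <- data.frame(
          stratum = st, mirna_id = mid, reason = "fewer than 5 expressors",
          stringsAsFactors = FALSE)
        next
      }
      if (cls == "common") {
        expo <- diff$values[mask, mid]
        if (sd(expo) == 0) {
          excluded[[length(excluded) + 1L]] <- data.frame(
            stratum = st, mirna_id = mid,
            reason = "constant differential expression in stratum",
            stringsAsFactors = FALSE)
          next
        }
        q1 <- quart$q1[quart$mirna_id == mid]
        q3 <- quart$q3[quart$mirna_id == mid]
        perm <- quiet_monotone(
          permutation_pvalue(time, event, expo, covariates = covs,
                             B = B, ties = ties))
        hr <- iqr_hazard_ratio(perm$fit_full, q1, q3, coef = "exposure")
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = st, mirna_id = mid, component = comp,
          analysis_class = "common", pct_expressing = pct, q1 = q1, q3 = q3,
          hr = hr[["hr"]], ci_low = hr[["ci_low"]],
          ci_high = hr[["ci_high"]], raw_p = perm$p,
          monotone = perm$fit_full$monotone, stringsAsFactors = FALSE)
      } else {
        any_expr <- as.numeric(carcinoma$detected[mask, mid])
        if (sum(any_expr) < 5) {
          excluded[[length(excluded) + 1L]] <- data.frame(
            stratum = st, mirna_id = mid,
            reason = "fewer than 5 expressors in stratum",
            stringsAsFactors = FALSE)
          next
        }
        rr <- quiet_monotone(
          rare_mirna_fit(time, event, any_expr, covariates = covs,
                         ties = ties))
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = st, mirna_id = mid, component = comp,
          analysis_class = "rare", pct_expressing = pct,
          q1 = NA_real_, q3 = NA_real_, hr = rr$hr, ci_low = rr$ci_low,
          ci_high = rr$ci_high, raw_p = rr$p, monotone = rr$fit$monotone,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(results))
    results <- pool_and_assign(results, pooling = pooling,
                               q_threshold = q_threshold)
  km <- compare_site_survival_by_stage(clinical)

  structure(list(results = results,
                 excluded = if (length(excluded)) do.call(rbind, excluded)
                            else data.frame(),
                 classification = classification,
                 factors = list(carcinoma = fac_c, normal = fac_n),
                 imputation = imputation_report(nrm), km = km,
                 config = list(strata = strata, B = B, seed = seed,
                               ties = ties, q_threshold = q_threshold,
                               pooling = pooling),
                 log = log_lines),
            class = "mirsurv_analysis")
}

#' Run the expression-processing chain
#'
#' Normalizes each tissue (75th-percentile scaling), imputes unpaired normal
#' samples by the site-stratified per-miRNA median, log2-transforms, and
#' computes the paired differential-expression matrix.  This is exactly the
#' processing [analyze_cohort()] applies, exposed so simulation experiments
#' can work with the measured analysis-scale differential.
#'
#' @param carcinoma,normal raw `expression_matrix` objects on aligned
#'   subjects.
#' @param site per-subject site labels (for the imputation strata).
#' @return list with `tumor` and `normal` (normalized-log2 matrices),
#'   `diff` (the `differential_matrix`), and `factors` (per-tissue scaling
#'   factors).
#' @export
process_expression <- function(carcinoma, normal, site) {
  fac_c <- compute_scaling_factors(carcinoma)
  fac_n <- compute_scaling_factors(normal)
  tum <- log2_transform(apply_normalization(carcinoma, fac_c))
  nrm <- apply_normalization(normal, replace_na(fac_n, 1))
  nrm <- impute_missing_normals(nrm, site, tumor = tum)
  nrm <- log2_transform(nrm)
  list(tumor = tum, normal = nrm, diff = compute_differential(tum, nrm),
       factors = list(carcinoma = fac_c, normal = fac_n))
}

# scanning hundreds of miRNAs at modest n hits occasional separation; the
# per-fit warning is muffled here and surfaced as the `monotone` flag column
quiet_monotone <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("monotone", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

em_subset <- function(x, idx) {
  x$values <- x$values[idx, , drop = FALSE]
  x$detected <- x$detected[idx, , drop = FALSE]
  x$imputed <- x$imputed[idx, , drop = FALSE]
  x
}

replace_na <- function(x, value) { x[is.na(x)] <- value; x }

#' @export
print.mirsurv_analysis <- function(x, ...) {
  cat("<mirsurv_analysis>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  if (nrow(x$results)) {
    for (st in unique(x$results$stratum)) {
      r <- x$results[x$results$stratum == st, ]
      cat(sprintf("  stratum %s: %d miRNAs analyzed, %d with q < %g\n",
                  st, nrow(r), sum(r$sig_q), x$config$q_threshold))
    }
  }
  invisible(x)
}

#' Run the full analysis from an on-disk configuration
#'
#' Reads the clinical and expression tables named in the config, runs
#' [analyze_cohort()], and writes the result tables, KM step tables, and a
#' run log into `config$output_dir`.  Fixed seeds give byte-identical
#' output files.
#'
#' @param config an [analysis_config()].
#' @return the `mirsurv_analysis` object, invisibly.
#' @export
run_full_analysis <- function(config) {
  if (!inherits(config, "analysis_config"))
    config_error("'config' must be an analysis_config")
  clinical <- read_clinical_table(config$clinical)
  carcinoma <- read_expression_matrix(config$carcinoma, tissue = "carcinoma")
  normal <- read_expression_matrix(config$normal, tissue = "normal")
  lit <- if (is.null(config$literature_mirnas)) character() else
    readLines(config$literature_mirnas, warn = FALSE)
  lit <- trimws(lit[nzchar(trimws(lit))])
  res <- analyze_cohort(clinical, carcinoma, normal,
                        literature_mirnas = lit, strata = config$strata,
                        B = config$B, seed = config$seed, ties = config$ties,
                        q_threshold = config$q_threshold,
                        pooling = config$pooling)
  write_analysis(res, config$output_dir)
  invisible(res)
}

#' Write analysis outputs as tab-separated tables
#'
#' @param x a `mirsurv_analysis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) write.table(df, file.path(dir, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  if (nrow(x$results)) {
    for (st in unique(x$results$stratum)) {
      r <- x$results[x$results$stratum == st, , drop = FALSE]
      wt(r, sprintf("results_%s.tsv", gsub("-", "_", st)))
    }
  }
  wt(x$classification, "classification.tsv")
  if (nrow(x$excluded)) wt(x$excluded, "excluded.tsv")
  wt(data.frame(subject_id = names(x$factors$carcinoma),
                factor_carcinoma = unname(x$factors$carcinoma),
                factor_normal = unname(x$factors$normal)),
     "scaling_factors.tsv")
  if (nrow(x$imputation)) wt(x$imputation, "imputation_report.tsv")
  if (!is.null(x$km) && nrow(x$km$summary)) {
    wt(x$km$summary, "km_site_by_stage.tsv")
    for (nm in names(x$km$curves)) {
      wt(x$km$curves[[nm]], sprintf("km_%s.tsv", nm))
    }
  }
  writeLines(x$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Compare colon and rectal survival within each AJCC stage
#'
#' For every stage, computes Kaplan-Meier curves for colon and rectal cases
#' (displayed curves truncated at `truncate_months`) and the log-rank test
#' for equal survival functions.  The test is reported both on full
#' follow-up (`p`) and on follow-up capped at the truncation time (`p_60`).
#'
#' @param clinical clinical data frame with `site`, `stage`,
#'   `survival_months`, `crc_death`.
#' @param truncate_months display/truncation horizon (default 60).
#' @return list with `summary` (per-stage data frame: ns, five-year
#'   survival per site, chi-square, p-values) and `curves` (named list of
#'   KM step tables).
#' @export
compare_site_survival_by_stage <- function(clinical, truncate_months = 60) {
  site2 <- ifelse(clinical$site == "rectal", "rectal", "colon")
  out <- list(); curves <- list()
  for (st in sort(unique(clinical$stage))) {
    sel <- clinical$stage == st
    sub_site <- site2[sel]
    if (length(unique(sub_site)) < 2L) {
      warning(sprintf("stage %s present for only one site; skipped", st))
      next
    }
    time <- clinical$survival_months[sel]
    event <- as.integer(clinical$crc_death[sel])
    lr <- logrank_test(time, event, sub_site)
    t60 <- pmin(time, truncate_months)
    e60 <- ifelse(time > truncate_months, 0L, event)
    lr60 <- logrank_test(t60, e60, sub_site)
    s5 <- c(colon = NA_real_, rectal = NA_real_)
    for (s in c("colon", "rectal")) {
      g <- sub_site == s
      km <- km_estimate(time[g], event[g])
      kmt <- km[km$time <= truncate_months, , drop = FALSE]
      curves[[sprintf("stage%d_%s", st, s)]] <- kmt
      s5[s] <- km_survival_at(km, truncate_months)
    }
    out[[length(out) + 1L]] <- data.frame(
      stage = st, n_colon = sum(sub_site == "colon"),
      n_rectal = sum(sub_site == "rectal"),
      surv5y_colon = s5[["colon"]], surv5y_rectal = s5[["rectal"]],
      chisq = lr$statistic, p = lr$p, p_60 = lr60$p,
      stringsAsFactors = FALSE)
  }
  list(summary = if (length(out)) do.call(rbind, out) else
         data.frame(stage = integer(), n_colon = integer(),
                    n_rectal = integer(), surv5y_colon = numeric(),
                    surv5y_rectal = numeric(), chisq = numeric(),
                    p = numeric(), p_60 = numeric()),
       curves = curves)
}
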