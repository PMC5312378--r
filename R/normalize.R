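#' Per-sample 75th-percentile scaling factors
#'
#' Computes, for every observed sample, the scaling factor
#' `median(P75 of all samples) / P75 of the sample`, where P75 is the 75th
#' percentile of the sample's signal values (all probes, zeros included;
#' linear-interpolation quantile).  Multiplying each sample by its factor
#' makes every sample's 75th percentile equal to the shared median, the
#' standard total-gene-signal scaling used for this array platform.
#'
#' @param x an `expression_matrix` in the `"raw"` (or, for idempotence
#'   checks, `"normalized"`) state.  All-`NA` rows (unpaired samples) get an
#'   `NA` factor and are excluded from the median.
#' @return named numeric vector of per-subject factors.
#' @export
compute_scaling_factors <- function(x) {
  if (!inherits(x, "expression_matrix"))
    input_error("'x' must be an expression_matrix")
  if (x$state == "normalized-log2")
    state_error("scaling factors are computed on the signal scale, not log2")
  p75 <- apply(x$values, 1L, function(r) {
    if (all(is.na(r))) NA_real_ else quantile(r, 0.75, na.rm = TRUE, names = FALSE)
  })
  obs <- !is.na(p75)
  bad <- obs & p75 <= 0
  if (any(bad))
    degenerate_sample_error(sprintf(
      "sample(s) with non-positive 75th percentile: %s",
      paste(rownames(x$values)[bad], collapse = ", ")))
  ref <- median(p75[obs])
  factors <- ref / p75
  names(factors) <- rownames(x$values)
  factors
}

#' Apply per-sample scaling factors
#'
#' Cell-wise multiplication of each sample (row) by its factor.  Zeros stay
#' zero, so detection status is unchanged; the detected and imputed masks are
#' preserved.
#'
#' @param x an `expression_matrix` in state `"raw"` or `"normalized"`.
#' @param factors strictly positive numeric vector, one per subject, in row
#'   order (names, if present, must match the subject ids).
#' @return the matrix in state `"normalized"`.
#' @export
apply_normalization <- function(x, factors) {
  if (!inherits(x, "expression_matrix"))
    input_error("'x' must be an expression_matrix")
  if (x$state == "normalized-log2")
    state_error("cannot scale a log2-transformed matrix")
  if (length(factors) != nrow(x$values))
    alignment_error(sprintf("%d factors supplied for %d subjects",
                            length(factors), nrow(x$values)))
  if (!is.null(names(factors)) &&
      !identical(names(factors), rownames(x$values)))
    alignment_error("factor names do not match subject ids")
  obs <- !is.na(factors)
  if (any(factors[obs] <= 0))
    input_error("scaling factors must be strictly positive")
  out <- x
  out$values <- x$values * as.numeric(factors)
  out$state <- "normalized"
  out
}

#' Log2 transform of normalized signal
#'
#' Detected cells (signal > 0) map to `log2(value)`; undetected cells stay at
#' exactly 0 and keep their undetected flag.  This preserves the convention
#' that absence of expression enters downstream differential-expression
#' distributions as 0.
#'
#' @param x an `expression_matrix` in state `"normalized"`.
#' @return the matrix in state `"normalized-log2"`.
#' @export
log2_transform <- function(x) {
  if (!inherits(x, "expression_matrix"))
    input_error("'x' must be an expression_matrix")
  if (x$state != "normalized")
    state_error(sprintf("log2 transform requires state 'normalized', got '%s'",
                        x$state))
  if (any(x$values < 0, na.rm = TRUE))
    state_error("negative values in a normalized signal matrix")
  out <- x
  v <- x$values
  pos <- !is.na(v) & v > 0
  v[pos] <- log2(v[pos])
  v[!is.na(v) & !pos] <- 0
  out$values <- v
  out$state <- "normalized-log2"
  out
}

#' Impute unpaired normal-mucosa samples
#'
#' Subjects with an all-missing normal row receive, for every miRNA, the
#' median of the observed normal values within the same site stratum (colon
#' versus rectal); imputed cells are flagged in the imputation mask, and a
#' cell is marked detected when its imputed value is positive.  When the
#' paired carcinoma matrix is supplied, imputation respects the pairing of
#' detection between tissues: cells whose carcinoma signal is undetected are
#' imputed as 0 (undetected) rather than the stratum median, since detection
#' is strongly concordant between paired tissues (the differential
#' distribution otherwise acquires large artificial negative values for
#' tumor-undetected cells).  The rule is a declared stand-in isolated behind
#' this one function so an alternative imputation can be swapped in.
#'
#' @param x the normal-tissue `expression_matrix` (any signal-scale state).
#' @param site per-subject site labels (`"proximal"`/`"distal"`/`"colon"`
#'   collapse to the colon stratum; `"rectal"` is its own stratum), in row
#'   order.
#' @param tumor optional paired carcinoma `expression_matrix`; its detection
#'   mask gates the imputed values as described above.
#' @return the matrix with missing rows filled and the imputation mask set;
#'   unchanged (mask all `FALSE`) when nothing is missing.
#' @export
impute_missing_normals <- function(x, site, tumor = NULL) {
  if (!inherits(x, "expression_matrix"))
    input_error("'x' must be an expression_matrix")
  if (length(site) != nrow(x$values))
    alignment_error("'site' must have one label per subject")
  if (!is.null(tumor) && !identical(dim(tumor$values), dim(x$values)))
    alignment_error("paired carcinoma matrix does not align with the normals")
  stratum <- ifelse(as.character(site) == "rectal", "rectal", "colon")
  miss <- em_missing_rows(x)
  if (!any(miss)) return(x)
  out <- x
  for (s in unique(stratum[miss])) {
    in_s <- stratum == s
    obs_rows <- which(in_s & !miss)
    if (length(obs_rows) < 2L)
      imputation_error(sprintf(
        "site stratum '%s' has %d observed normal sample(s); need >= 2 to impute",
        s, length(obs_rows)))
    med <- apply(x$values[obs_rows, , drop = FALSE], 2L, median)
    for (r in which(in_s & miss)) {
      fill <- med
      if (!is.null(tumor)) fill[!tumor$detected[r, ]] <- 0
      out$values[r, ] <- fill
      out$detected[r, ] <- fill > 0
      out$imputed[r, ] <- TRUE
    }
  }
  out
}

#' Imputation report
#'
#' Summarizes which subjects received imputed normal values.
#'
#' @param x an `expression_matrix` after [impute_missing_normals()].
#' @return data frame with `subject_id` and `n_cells_imputed`.
#' @export
imputation_report <- function(x) {
  n_imp <- rowSums(x$imputed)
  data.frame(subject_id = rownames(x$values), n_cells_imputed = n_imp,
             row.names = NULL, stringsAsFactors = FALSE)[n_imp > 0, , drop = FALSE]
}
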