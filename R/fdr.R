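#' Benjamini-Hochberg FDR q-values
#'
#' Step-up adjusted p-values `q_(i) = min_{j >= i} m p_(j) / j`, clipped to
#' 1 and returned in the input order (computed via [stats::p.adjust()]).
#'
#' @param p raw p-values in `(0, 1]`.
#' @return q-values in input order.
#' @export
bh_qvalues <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p <= 0 | p > 1))
    input_error("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Assign q-values within pooling groups
#'
#' Computes FDR q-values within each expression-class group of each analysis
#' stratum.  In the default `"pooled"` mode the discovery and replication
#' study components are combined inside a group before adjustment; in
#' `"separate"` mode each component is adjusted on its own (the two modes
#' reflect the two readings of per-table q-value reporting).
#'
#' @param results data frame with columns `raw_p`, `analysis_class`,
#'   `stratum`, and `component` (`discovery` / `replication`).
#' @param pooling `"pooled"` (default) or `"separate"`.
#' @param q_threshold primary significance threshold (default 0.05); a
#'   secondary flag at 0.1 is always added.
#' @return `results` with columns `q`, `sig_q` (q < `q_threshold`) and
#'   `sig_q10` (q < 0.1) appended.
#' @export
pool_and_assign <- function(results, pooling = c("pooled", "separate"),
                            q_threshold = 0.05) {
  pooling <- match.arg(pooling)
  needed <- c("raw_p", "analysis_class", "stratum", "component")
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols))
    config_error(paste0("results lack required label column(s): ",
                        paste(missing_cols, collapse = ", ")))
  if (anyNA(results$component) || anyNA(results$analysis_class))
    config_error("every result row must carry component and analysis_class labels")
  key <- paste(results$stratum, results$analysis_class,
               if (pooling == "separate") results$component else "",
               sep = "\r")
  results$q <- NA_real_
  for (g in unique(key)) {
    idx <- which(key == g)
    results$q[idx] <- bh_qvalues(results$raw_p[idx])
  }
  results$sig_q <- results$q < q_threshold
  results$sig_q10 <- results$q < 0.1
  results
}
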