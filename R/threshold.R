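#' Calibrate the high-ratio threshold from pseudoautosomal variants
#'
#' Pseudoautosomal (PAR) variants are diploid in both sexes, so no
#' sex-specific allele depletion is expected there: their ratio
#' distribution is an empirical null. The default method takes the maximum
#' observed PAR ratio and rounds it up to the next integer (the smallest
#' integer strictly greater than the maximum), giving a round empiric
#' threshold that no PAR variant exceeds.
#'
#' @param records Variant record tibble with `ratio` and `region` columns
#'   (see [score_variants()]).
#' @param method `"par_max"` (default), `"par_quantile"`, or `"fixed"`.
#' @param quantile Upper quantile of PAR ratios for `"par_quantile"`
#'   (type-1, i.e. order-statistic, quantile).
#' @param fixed_value Threshold to echo for `"fixed"`.
#' @param integer_ceiling For `"par_max"`: round up to the next integer
#'   (default `TRUE`); set `FALSE` for the raw PAR maximum.
#' @return A list of class `threshold_result` with elements `threshold`,
#'   `n_par`, `max_par_ratio`, `method`.
#' @export
calibrate_threshold <- function(records,
                                method = c("par_max", "par_quantile", "fixed"),
                                quantile = 0.999, fixed_value = NULL,
                                integer_ceiling = TRUE) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_value) || fixed_value <= 0) {
      stop("fixed method requires a positive fixed_value", call. = FALSE)
    }
    return(structure(list(threshold = fixed_value, n_par = 0L,
                          max_par_ratio = NA_real_, method = "FIXED"),
                     class = "threshold_result"))
  }
  if (!"ratio" %in% names(records)) {
    stop("records carry no ratio column; run score_variants() first",
         call. = FALSE)
  }
  par_ratios <- records$ratio[records$region %in% c("PAR1", "PAR2")]
  par_ratios <- par_ratios[!is.na(par_ratios)]
  if (length(par_ratios) == 0) {
    stop("no pseudoautosomal records available; use method = \"fixed\" ",
         "with an externally chosen threshold", call. = FALSE)
  }
  mx <- max(par_ratios)
  if (method == "par_max") {
    thr <- if (integer_ceiling) floor(mx) + 1 else mx
    meth <- "PAR_MAX"
  } else {
    stopifnot(quantile > 0, quantile <= 1)
    thr <- as.numeric(stats::quantile(par_ratios, quantile, type = 1))
    meth <- "PAR_QUANTILE"
  }
  structure(list(threshold = thr, n_par = length(par_ratios),
                 max_par_ratio = mx, method = meth),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("High-ratio threshold:", x$threshold,
      sprintf("(method %s", x$method))
  if (x$method != "FIXED") {
    cat(sprintf("; %d PAR variants, max PAR ratio %.4g", x$n_par,
                x$max_par_ratio))
  }
  cat(")\n")
  invisible(x)
}

#' Flag variants exceeding the high-ratio threshold
#'
#' A variant is flagged when its ratio is strictly greater than the
#' threshold ("above" is strict: a ratio exactly equal to the threshold is
#' not flagged) and it lies on the non-pseudoautosomal X. PAR variants are
#' never flagged under the default policy; autosomal flagging can be
#' enabled for exploratory use, since sex-differential effects may also
#' occur on autosomes but autosomal thresholds are less established.
#'
#' @param records Variant record tibble with `ratio` and `region`.
#' @param threshold Positive threshold, or a `threshold_result` from
#'   [calibrate_threshold()].
#' @param include_autosomes Also flag autosomal records exceeding the
#'   threshold (default `FALSE`).
#' @return `records` with a logical `high_ratio` column set.
#' @export
flag_high_ratio <- function(records, threshold, include_autosomes = FALSE) {
  if (inherits(threshold, "threshold_result")) threshold <- threshold$threshold
  stopifnot(is.numeric(threshold), threshold > 0)
  if (!"ratio" %in% names(records)) {
    stop("records carry no ratio column; run score_variants() first",
         call. = FALSE)
  }
  eligible <- records$region == "NONPAR_X"
  if (include_autosomes) eligible <- eligible | records$region == "AUTOSOME"
  records$high_ratio <- eligible & !is.na(records$ratio) &
    records$ratio > threshold
  records
}
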