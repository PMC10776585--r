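#' Run the full high-ratio analysis pipeline
#'
#' Orchestrates read -> filter -> ratio -> calibrate -> flag -> annotate ->
#' summarize:
#' 1. read sex-stratified counts (delimited table or gnomAD-dialect VCF);
#' 2. drop variants with combined minor allele count below `min_ac`;
#' 3. compute ratios, log2 ratios and carrier profiles;
#' 4. calibrate the high-ratio threshold (pseudoautosomal null by default);
#' 5. flag non-PAR X variants strictly above the threshold;
#' 6. optionally join annotation evidence for the flagged variants and
#'    apply the findings counting rules;
#' 7. summarize ratios per chromosome.
#'
#' @param input Path to the input file, or an already-loaded variant record
#'   tibble.
#' @param format `"table"` or `"vcf"` (ignored when `input` is a tibble).
#' @param build Genome build for PAR classification, or a [region_map()].
#' @param min_ac Minimum combined minor allele count (default 5).
#' @param threshold_method,threshold_quantile,threshold_value Passed to
#'   [calibrate_threshold()].
#' @param include_autosomes Passed to [flag_high_ratio()].
#' @param annotations Optional path to (or tibble of) clinical annotation
#'   evidence for the flagged variants.
#' @param regulome Optional path to (or tibble of) RegulomeDB evidence.
#' @param out Optional output directory; when given, the per-variant
#'   results table, threshold report, per-chromosome summary, findings
#'   summary and run log are written there as tab-separated/JSON files.
#' @return A list of class `fmratio_run` with elements `results`
#'   (per-variant table with ratio, flags and carrier profile),
#'   `threshold` (a `threshold_result`), `summary_by_chrom`, `findings`
#'   (or `NULL`), `flagged` (annotated flagged variants), and `log`
#'   (record counts at each stage).
#' @export
run_pipeline <- function(input, format = c("table", "vcf"),
                         build = "GRCh38", min_ac = 5,
                         threshold_method = c("par_max", "par_quantile",
                                              "fixed"),
                         threshold_quantile = 0.999,
                         threshold_value = NULL,
                         include_autosomes = FALSE,
                         annotations = NULL, regulome = NULL,
                         out = NULL) {
  format <- match.arg(format)
  threshold_method <- match.arg(threshold_method)
  map <- if (inherits(build, "region_map")) build else region_map(build)

  records <- if (is.data.frame(input)) {
    inp <- input
    if (!"region" %in% names(inp)) {
      inp$region <- classify_region(inp$chrom, inp$pos, map)
    }
    inp
  } else if (format == "table") {
    read_count_table(input, map = map)
  } else {
    read_vcf_counts(input, map = map)
  }
  n_read <- nrow(records)

  records <- filter_by_allele_count(records, min_ac = min_ac)
  n_pass <- nrow(records)

  if (n_pass == 0) {
    warning("no variants pass the allele-count filter (min_ac = ", min_ac,
            ")", call. = FALSE)
    empty <- score_variants(records)
    return(structure(list(results = empty, threshold = NULL,
                          summary_by_chrom = NULL, findings = NULL,
                          flagged = empty,
                          log = c(n_read = n_read, n_pass_ac = 0,
                                  n_flagged = 0)),
                     class = "fmratio_run"))
  }

  records <- score_variants(records)

  thr <- calibrate_threshold(records, method = threshold_method,
                             quantile = threshold_quantile,
                             fixed_value = threshold_value)
  records <- flag_high_ratio(records, thr,
                             include_autosomes = include_autosomes)
  flagged <- records[records$high_ratio, , drop = FALSE]

  summary_by_chrom <- dplyr::group_by(records, .data$chrom) |>
    dplyr::group_modify(~ summarize_ratios(.x$ratio)) |>
    dplyr::ungroup()

  findings <- NULL
  if (!is.null(annotations) && nrow(flagged) > 0) {
    ann <- if (is.data.frame(annotations)) annotations else {
      read_annotation_table(annotations)
    }
    if (!is.null(regulome)) {
      reg <- if (is.data.frame(regulome)) regulome else {
        read_regulome_table(regulome)
      }
      ann <- dplyr::left_join(ann, reg, by = "variant_id")
    }
    flagged <- join_annotations(flagged, ann)
    findings <- summarize_findings(flagged)
  }

  run <- structure(list(
    results = records, threshold = thr, summary_by_chrom = summary_by_chrom,
    findings = findings, flagged = flagged,
    log = c(n_read = n_read, n_pass_ac = n_pass, n_flagged = nrow(flagged))
  ), class = "fmratio_run")

  if (!is.null(out)) write_run(run, out)
  run
}

#' Write a pipeline run to an output directory
#'
#' Emits `results.tsv` (per-variant table), `summary_by_chrom.tsv`
#' (full-precision and one-decimal report columns), `flagged.tsv`,
#' `findings.tsv` when computed, and `run.json` carrying the threshold,
#' stage record counts and summary-convention metadata (sample standard
#' deviation, n - 1 denominator) for provenance.
#'
#' @param run An `fmratio_run` from [run_pipeline()].
#' @param out Output directory (created if needed).
#' @return `out`, invisibly.
#' @export
write_run <- function(run, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$results, file.path(out, "results.tsv"),
                   progress = FALSE)
  if (!is.null(run$summary_by_chrom)) {
    readr::write_tsv(run$summary_by_chrom,
                     file.path(out, "summary_by_chrom.tsv"),
                     progress = FALSE)
  }
  if (!is.null(run$flagged) && nrow(run$flagged) > 0) {
    readr::write_tsv(run$flagged, file.path(out, "flagged.tsv"),
                     progress = FALSE)
  }
  if (!is.null(run$findings)) {
    readr::write_tsv(run$findings, file.path(out, "findings.tsv"),
                     progress = FALSE)
  }
  meta <- list(
    threshold = if (!is.null(run$threshold)) {
      run$threshold[c("threshold", "n_par", "max_par_ratio", "method")]
    },
    log = as.list(run$log),
    conventions = list(sd = "sample (n-1)",
                       ratio_boundary = "flagging is strict (> threshold)",
                       ac_filter = "inclusive (>= min_ac), sex-combined")
  )
  jsonlite::write_json(meta, file.path(out, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

#' @export
print.fmratio_run <- function(x, ...) {
  cat("fmratio pipeline run\n")
  cat(sprintf("  records read:        %d\n", x$log[["n_read"]]))
  cat(sprintf("  pass AC filter:      %d\n", x$log[["n_pass_ac"]]))
  if (!is.null(x$threshold)) {
    cat(sprintf("  threshold:           %.4g (%s)\n",
                x$threshold$threshold, x$threshold$method))
  }
  cat(sprintf("  flagged high-ratio:  %d\n", x$log[["n_flagged"]]))
  if (!is.null(x$findings)) {
    f <- x$findings
    cat(sprintf(paste0("  findings: %d/%d benign-or-likely, %d/%d QC-fail,",
                       " %d/%d OMIM-specific,\n            %d/%d",
                       " structural call, %s/%d regulatory evidence\n"),
                f$n_benign_or_likely, f$n_variants,
                f$n_qc_fail, f$n_variants,
                f$n_omim_specific, f$n_variants,
                f$n_structural_predictable, f$n_variants,
                ifelse(is.na(f$n_regulatory_evidence), "NA",
                       f$n_regulatory_evidence), f$n_variants))
  }
  invisible(x)
}
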