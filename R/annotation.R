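#' RegulomeDB rank categories
#'
#' The fifteen rank categories of the RegulomeDB evidence ranking, from
#' strongest (1a: eQTL/caQTL plus TF binding, matched motif, footprint and
#' accessibility peak) to weakest (7: other). The integer part is the
#' stratum; the letter is the sub-rank.
#'
#' @return Character vector of the categories in decreasing evidence order.
#' @export
regulome_rank_levels <- function() {
  c("1a", "1b", "1c", "1d", "1e", "1f",
    "2a", "2b", "2c", "3a", "3b", "4", "5", "6", "7")
}

#' Parse RegulomeDB rank strings
#'
#' Normalizes case and whitespace and maps each string onto the ordered
#' rank scale `1a < 1b < ... < 7`.
#'
#' @param text Character vector of rank strings (e.g. `"2b"`, `" 1A "`).
#' @return An ordered factor over [regulome_rank_levels()].
#' @export
parse_regulome_rank <- function(text) {
  norm <- tolower(gsub("\\s+", "", as.character(text)))
  bad <- !is.na(norm) & !(norm %in% regulome_rank_levels())
  if (any(bad)) {
    stop("unmappable RegulomeDB rank(s): ",
         paste(unique(text[bad]), collapse = ", "),
         "; valid categories: ",
         paste(regulome_rank_levels(), collapse = ", "), call. = FALSE)
  }
  factor(norm, levels = regulome_rank_levels(), ordered = TRUE)
}

#' Numeric stratum of a RegulomeDB rank
#'
#' @param rank Rank strings or an ordered factor from
#'   [parse_regulome_rank()].
#' @return Integer vector of strata (1-7).
#' @export
regulome_rank_stratum <- function(rank) {
  rank <- parse_regulome_rank(as.character(rank))
  as.integer(substr(as.character(rank), 1, 1))
}

#' Regulatory-evidence flag
#'
#' A variant shows some indication of regulatory function when its
#' RegulomeDB rank stratum is less than three (any of 1a-1f, 2a-2c: at
#' least two strong pieces of experimental evidence) or its probabilistic
#' score is strictly greater than 0.5 (top half of the transcription-factor
#' binding model's scale).
#'
#' @param rank Rank strings or parsed ranks.
#' @param score Numeric scores in `[0, 1]`.
#' @param rank_cutoff Strata strictly below this qualify (default 3).
#' @param score_cutoff Scores strictly above this qualify (default 0.5).
#' @return Logical vector.
#' @export
regulatory_evidence_flag <- function(rank, score,
                                     rank_cutoff = 3, score_cutoff = 0.5) {
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    stop("regulome_score must lie in [0, 1]", call. = FALSE)
  }
  stratum <- regulome_rank_stratum(rank)
  out <- (stratum < rank_cutoff) | (score > score_cutoff)
  out[is.na(stratum) & is.na(score)] <- NA
  out[is.na(stratum) & !is.na(score)] <- score[is.na(stratum) & !is.na(score)] > score_cutoff
  out[!is.na(stratum) & is.na(score)] <- stratum[!is.na(stratum) & is.na(score)] < rank_cutoff
  out
}

clinvar_levels <- c("BENIGN", "LIKELY_BENIGN", "BENIGN_OR_LIKELY_BENIGN",
                    "UNCERTAIN", "CONFLICTING", "LIKELY_PATHOGENIC",
                    "PATHOGENIC", "ABSENT")
structural_levels <- c("NEUTRAL", "STABILIZING", "DESTABILIZING", "UNCLEAR",
                       "NOT_APPLICABLE")
omim_levels <- c("SPECIFIC", "TENTATIVE", "NONE")
qc_levels <- c("yes", "no", "not_assessed")

#' Read a clinical/structural annotation evidence table
#'
#' Tab-separated table with columns `variant_id`, `clinvar_class`
#' (`BENIGN`, `LIKELY_BENIGN`, `BENIGN_OR_LIKELY_BENIGN`, `UNCERTAIN`,
#' `CONFLICTING`, `LIKELY_PATHOGENIC`, `PATHOGENIC`, `ABSENT`),
#' `qc_fail_genomes` (`yes`/`no`/`not_assessed`), `omim_link`
#' (`SPECIFIC`/`TENTATIVE`/`NONE`) and `structural_prediction`
#' (`NEUTRAL`/`STABILIZING`/`DESTABILIZING`/`UNCLEAR`/`NOT_APPLICABLE`).
#'
#' @param path Path to the table.
#' @return A validated tibble.
#' @export
read_annotation_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("variant_id", "clinvar_class", "qc_fail_genomes",
                "omim_link", "structural_prediction")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("annotation table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_enum <- function(x, levels, col) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      stop("invalid ", col, " value(s): ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
  }
  check_enum(tab$clinvar_class, clinvar_levels, "clinvar_class")
  check_enum(tab$qc_fail_genomes, qc_levels, "qc_fail_genomes")
  check_enum(tab$omim_link, omim_levels, "omim_link")
  check_enum(tab$structural_prediction, structural_levels,
             "structural_prediction")
  tibble::as_tibble(tab)
}

#' Read a RegulomeDB evidence table
#'
#' Tab-separated table with columns `variant_id`, `regulome_rank` (one of
#' [regulome_rank_levels()]) and `regulome_score` in `[0, 1]`.
#'
#' @param path Path to the table.
#' @return A validated tibble with the rank normalized.
#' @export
read_regulome_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(c("variant_id", "regulome_rank", "regulome_score"),
                     names(tab))
  if (length(missing) > 0) {
    stop("regulome table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$regulome_rank <- as.character(parse_regulome_rank(tab$regulome_rank))
  tab$regulome_score <- as.numeric(tab$regulome_score)
  if (any(!is.na(tab$regulome_score) &
          (tab$regulome_score < 0 | tab$regulome_score > 1))) {
    stop("regulome_score must lie in [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Join annotation evidence onto variant records
#'
#' Left join on `variant_id`. Unmatched records carry placeholders
#' (`clinvar_class = "ABSENT"`, `qc_fail_genomes = "not_assessed"`,
#' `omim_link` and `structural_prediction` `NA`) and their count is
#' attached as attribute `n_unmatched`.
#'
#' @param records Variant record tibble (typically flagged high-ratio
#'   records).
#' @param annotations Annotation tibble from [read_annotation_table()],
#'   optionally already merged with regulome evidence.
#' @return The joined tibble, one row per input record.
#' @export
join_annotations <- function(records, annotations) {
  dup <- unique(annotations$variant_id[duplicated(annotations$variant_id)])
  if (length(dup) > 0) {
    stop("duplicate annotation id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::left_join(records, annotations, by = "variant_id")
  unmatched <- !(records$variant_id %in% annotations$variant_id)
  if ("clinvar_class" %in% names(out)) {
    out$clinvar_class[unmatched] <- "ABSENT"
  }
  if ("qc_fail_genomes" %in% names(out)) {
    out$qc_fail_genomes[unmatched] <- "not_assessed"
  }
  attr(out, "n_unmatched") <- sum(unmatched)
  out
}

#' Summarize annotation findings for a set of flagged variants
#'
#' Applies the counting rules used to reconcile high-ratio variants with
#' annotation evidence:
#' * `n_benign_or_likely` — ClinVar class in
#'   `{BENIGN, LIKELY_BENIGN, BENIGN_OR_LIKELY_BENIGN}` (variants that look
#'   harmless to sex-averaged annotation);
#' * `n_qc_fail` — failed QC filters in a second (genomes) dataset,
#'   `qc_fail_genomes == "yes"`;
#' * `n_omim_specific` — gene has a specific OMIM phenotype link
#'   (tentative/putative links and genes without noted phenotypes are
#'   excluded);
#' * `n_structural_predictable` — an explicit structural-effect call
#'   (`NEUTRAL`, `STABILIZING` or `DESTABILIZING`; `UNCLEAR` and
#'   `NOT_APPLICABLE` are excluded);
#' * `n_regulatory_evidence` — [regulatory_evidence_flag()] true.
#'
#' @param annotations Non-empty annotation tibble; regulome columns
#'   (`regulome_rank`, `regulome_score`) are optional — without them the
#'   regulatory tally is `NA`.
#' @return A one-row tibble with `n_variants`, the five tallies, and a
#'   `frac_*` column for each tally.
#' @export
summarize_findings <- function(annotations) {
  if (nrow(annotations) == 0) {
    stop("empty annotation collection", call. = FALSE)
  }
  n <- nrow(annotations)
  tally <- function(x) sum(x, na.rm = TRUE)
  n_benign <- tally(annotations$clinvar_class %in%
                      c("BENIGN", "LIKELY_BENIGN", "BENIGN_OR_LIKELY_BENIGN"))
  n_qc <- tally(annotations$qc_fail_genomes == "yes")
  n_omim <- tally(annotations$omim_link == "SPECIFIC")
  n_struct <- tally(annotations$structural_prediction %in%
                      c("NEUTRAL", "STABILIZING", "DESTABILIZING"))
  n_reg <- if (all(c("regulome_rank", "regulome_score") %in%
                   names(annotations))) {
    tally(regulatory_evidence_flag(annotations$regulome_rank,
                                   annotations$regulome_score))
  } else NA_integer_
  tibble::tibble(
    n_variants = n,
    n_benign_or_likely = n_benign,
    n_qc_fail = n_qc,
    n_omim_specific = n_omim,
    n_structural_predictable = n_struct,
    n_regulatory_evidence = n_reg,
    frac_benign_or_likely = n_benign / n,
    frac_qc_fail = n_qc / n,
    frac_omim_specific = n_omim / n,
    frac_structural_predictable = n_struct / n,
    frac_regulatory_evidence = n_reg / n
  )
}

#' Path to a packaged example data file
#'
#' The package ships three small tab-separated datasets:
#' * `"high_ratio_clinvar_evidence.tsv"` — clinical-significance, QC,
#'   OMIM-link and structural-prediction evidence for 25 high-ratio
#'   non-pseudoautosomal X variants identified in gnomAD exomes;
#' * `"high_ratio_regulome_evidence.tsv"` — RegulomeDB rank and score for
#'   the same 25 variants;
#' * `"example_counts.tsv"` — a small sex-stratified count table, including
#'   the FMR1 variant rs201580891 (observed 18,736 times, all in
#'   heterozygous females, never in 38,527 genotyped male X chromosomes).
#'
#' @param file File name; with no argument, lists available files.
#' @return Full path to the file.
#' @export
fmratio_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "fmratio")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    stop("no packaged file '", file, "'; available: ",
         paste(list.files(dir), collapse = ", "), call. = FALSE)
  }
  path
}
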