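#' Validate sex-stratified allele counts
#'
#' Checks the internal consistency of the four allele-count terms and the
#' optional zygosity counts. All arguments are recycled to a common length.
#'
#' @param v_f Minor allele count in females.
#' @param a_f Total allele count in females.
#' @param v_m Minor allele count in males.
#' @param a_m Total allele count in males.
#' @param hom_f Optional count of homozygous-alt females.
#' @param hemi_m Optional count of alt-hemizygous males.
#' @param where Optional character vector of row labels used in error
#'   messages (e.g. file row numbers).
#'
#' @return Invisibly `TRUE`; aborts with a message naming the offending
#'   field (and row, when `where` is given) otherwise.
#' @export
validate_counts <- function(v_f, a_f, v_m, a_m,
                            hom_f = NULL, hemi_m = NULL, where = NULL) {
  n <- max(length(v_f), length(a_f), length(v_m), length(a_m))
  if (is.null(where)) where <- as.character(seq_len(n))

  fail <- function(field, bad, msg) {
    stop(sprintf("invalid counts: %s %s (rows: %s)",
                 field, msg, paste(head(where[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  check_nonneg <- function(x, field) {
    bad <- !is.na(x) & x < 0
    if (any(bad)) fail(field, bad, "is negative")
    bad <- !is.na(x) & x != trunc(x)
    if (any(bad)) fail(field, bad, "is not an integer")
  }
  check_nonneg(v_f, "v_f"); check_nonneg(a_f, "a_f")
  check_nonneg(v_m, "v_m"); check_nonneg(a_m, "a_m")

  bad <- !is.na(v_f) & !is.na(a_f) & v_f > a_f
  if (any(bad)) fail("v_f", bad, "exceeds a_f")
  bad <- !is.na(v_m) & !is.na(a_m) & v_m > a_m
  if (any(bad)) fail("v_m", bad, "exceeds a_m")

  if (!is.null(hom_f)) {
    check_nonneg(hom_f, "hom_f")
    bad <- !is.na(hom_f) & !is.na(v_f) & 2 * hom_f > v_f
    if (any(bad)) fail("hom_f", bad, "implies more than v_f alleles (2*hom_f > v_f)")
  }
  if (!is.null(hemi_m)) {
    check_nonneg(hemi_m, "hemi_m")
    bad <- !is.na(hemi_m) & !is.na(a_m) & hemi_m > a_m
    if (any(bad)) fail("hemi_m", bad, "exceeds a_m")
  }
  invisible(TRUE)
}

#' Female-to-male allele proportion ratio
#'
#' Computes the pseudocount-adjusted ratio of the female minor-allele
#' proportion to the male minor-allele proportion,
#' \deqn{R = \frac{(V_f + 1)/(A_f + 1)}{(V_m + 1)/(A_m + 1)}.}
#' One is added to each of the four terms, so the ratio is finite and
#' strictly positive for every valid input, including variants never
#' observed (or never genotyped) in males. The pseudocount placement is
#' fixed, not a tunable prior: it is what makes ratios comparable across
#' variants and what reproduces published values.
#'
#' @inheritParams validate_counts
#' @param validate Set `FALSE` to skip input validation (for hot loops on
#'   already-validated data).
#'
#' @return Numeric vector of ratios, one per input element.
#' @examples
#' # a variant observed 18736 times in females and never in males
#' compute_ratio(18736, 104056, 0, 38527) # ~ 6937.5
#' @export
compute_ratio <- function(v_f, a_f, v_m, a_m, validate = TRUE) {
  if (validate) validate_counts(v_f, a_f, v_m, a_m)
  ((v_f + 1) / (a_f + 1)) / ((v_m + 1) / (a_m + 1))
}

#' Base-2 logarithm of an allele proportion ratio
#'
#' @param ratio Positive numeric vector.
#' @return `log2(ratio)`.
#' @export
log2_ratio <- function(ratio) {
  if (any(!is.na(ratio) & ratio <= 0)) {
    stop("ratio must be strictly positive", call. = FALSE)
  }
  log2(ratio)
}

#' Carrier-profile levels
#'
#' Ordered set of categorical descriptions of who carries a variant,
#' inferred from sex-stratified allele and zygosity counts.
#' @return Character vector of the five profile labels.
#' @export
carrier_profile_levels <- function() {
  c("ONLY_HET_FEMALES", "NO_MALES", "MALES_AND_HOM_FEMALES_RARE",
    "UNRESTRICTED", "UNKNOWN")
}

#' Classify the carrier profile of a variant
#'
#' Summarizes which kinds of individuals carry the minor allele:
#' * `ONLY_HET_FEMALES` — no male carriers and zero homozygous females
#'   (requires `hom_f`), with at least one female carrier; the signature of
#'   a variant lethal in males and homozygous females.
#' * `NO_MALES` — no male carriers, but female zygosity unknown or
#'   homozygous females present.
#' * `MALES_AND_HOM_FEMALES_RARE` — male carriers and homozygous females
#'   both present at frequencies below `rarity`.
#' * `UNRESTRICTED` — carriers not restricted by sex or zygosity.
#' * `UNKNOWN` — no carriers at all, or male carriers present but zygosity
#'   data absent so rarity cannot be judged.
#'
#' @inheritParams validate_counts
#' @param rarity Rarity fraction: male carriers are "rare" when
#'   `v_m / a_m < rarity` and homozygous females when
#'   `hom_f / (a_f / 2) < rarity`. Default `1e-4`.
#' @param validate Set `FALSE` to skip input validation.
#'
#' @return Character vector of profile labels (see
#'   [carrier_profile_levels()]).
#' @export
classify_carrier_profile <- function(v_f, a_f, v_m, a_m,
                                     hom_f = NULL, hemi_m = NULL,
                                     rarity = 1e-4, validate = TRUE) {
  if (validate) validate_counts(v_f, a_f, v_m, a_m, hom_f, hemi_m)
  n <- max(length(v_f), length(a_f), length(v_m), length(a_m))
  v_f <- rep_len(v_f, n); a_f <- rep_len(a_f, n)
  v_m <- rep_len(v_m, n); a_m <- rep_len(a_m, n)
  hom_f <- if (is.null(hom_f)) rep_len(NA_real_, n) else rep_len(hom_f, n)

  out <- rep_len("UNRESTRICTED", n)

  no_carriers <- v_f == 0 & v_m == 0
  out[no_carriers] <- "UNKNOWN"

  fem_only <- v_m == 0 & v_f > 0
  out[fem_only & !is.na(hom_f) & hom_f == 0] <- "ONLY_HET_FEMALES"
  out[fem_only & (is.na(hom_f) | hom_f > 0)] <- "NO_MALES"

  males <- v_m > 0
  out[males & is.na(hom_f)] <- "UNKNOWN"
  male_freq <- ifelse(a_m > 0, v_m / a_m, 0)
  homf_freq <- ifelse(a_f > 0, hom_f / (a_f / 2), 0)
  rare <- males & !is.na(hom_f) & male_freq < rarity & homf_freq < rarity
  out[rare] <- "MALES_AND_HOM_FEMALES_RARE"
  out
}

#' Summary statistics for a collection of allele proportion ratios
#'
#' Computes n, mean, sample standard deviation (n - 1 denominator), min and
#' max on both the ratio scale and the log2-ratio scale. Values are kept at
#' full precision; use `digits` in [format_ratio_summary()] for the
#' one-decimal report layer.
#'
#' @param ratios Non-empty numeric vector of positive ratios.
#' @return A one-row tibble with columns `n`, `mean_ratio`, `sd_ratio`,
#'   `min_ratio`, `max_ratio`, `mean_log2`, `sd_log2`, `min_log2`,
#'   `max_log2`.
#' @export
summarize_ratios <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0) stop("empty ratio collection", call. = FALSE)
  if (any(ratios <= 0)) stop("ratios must be strictly positive", call. = FALSE)
  lr <- log2(ratios)
  tibble::tibble(
    n = length(ratios),
    mean_ratio = mean(ratios),
    sd_ratio = if (length(ratios) > 1) sd(ratios) else 0,
    min_ratio = min(ratios),
    max_ratio = max(ratios),
    mean_log2 = mean(lr),
    sd_log2 = if (length(lr) > 1) sd(lr) else 0,
    min_log2 = min(lr),
    max_log2 = max(lr)
  )
}

#' Format a ratio summary for reporting
#'
#' Report-layer rounding (default one decimal, matching how such summaries
#' are conventionally printed); the summary itself retains full precision.
#'
#' @param summary A one-row tibble from [summarize_ratios()].
#' @param digits Decimal places, default 1.
#' @return The summary with numeric columns rounded.
#' @export
format_ratio_summary <- function(summary, digits = 1) {
  num <- setdiff(names(summary), "n")
  summary[num] <- lapply(summary[num], round, digits = digits)
  summary
}

#' Add ratio columns to a variant record table
#'
#' Convenience wrapper that computes `ratio`, `log2_ratio` and
#' `carrier_profile` for every row of a variant record table (as returned
#' by [read_count_table()], [read_vcf_counts()] or [simulate_cohort()]).
#'
#' @param records Tibble with columns `v_f`, `a_f`, `v_m`, `a_m` and
#'   optionally `hom_f`, `hemi_m`.
#' @param rarity Passed to [classify_carrier_profile()].
#' @return `records` with `ratio`, `log2_ratio` and `carrier_profile`
#'   columns appended.
#' @export
score_variants <- function(records, rarity = 1e-4) {
  hom_f <- if ("hom_f" %in% names(records)) records$hom_f else NULL
  hemi_m <- if ("hemi_m" %in% names(records)) records$hemi_m else NULL
  validate_counts(records$v_f, records$a_f, records$v_m, records$a_m,
                  hom_f, hemi_m)
  records$ratio <- compute_ratio(records$v_f, records$a_f,
                                 records$v_m, records$a_m, validate = FALSE)
  records$log2_ratio <- log2(records$ratio)
  records$carrier_profile <- classify_carrier_profile(
    records$v_f, records$a_f, records$v_m, records$a_m,
    hom_f = hom_f, hemi_m = hemi_m, rarity = rarity, validate = FALSE
  )
  records
}
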