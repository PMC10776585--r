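#' Read a sex-stratified allele count table
#'
#' Reads a tab-separated table with header columns `variant_id`, `chrom`,
#' `pos`, `ref`, `alt`, `v_f`, `a_f`, `v_m`, `a_m` and optional `hom_f`,
#' `hemi_m`, `qc_fail`. Counts are parsed as integers; rows violating the
#' count invariants (negative counts, `v_f > a_f`, `v_m > a_m`,
#' `2*hom_f > v_f`) are rejected with row-numbered diagnostics. By default
#' bad rows are dropped with a warning; in strict mode any bad row aborts.
#'
#' @param path Path to the table.
#' @param map A [region_map()] used to classify each record's region.
#' @param strict If `TRUE`, any invalid row is an error; otherwise invalid
#'   rows are dropped with a warning naming them.
#' @return A tibble of variant records with a `region` column appended.
#' @export
read_count_table <- function(path, map = region_map(), strict = FALSE) {
  required <- c("variant_id", "chrom", "pos", "ref", "alt",
                "v_f", "a_f", "v_m", "a_m")
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("count table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  count_cols <- intersect(c("v_f", "a_f", "v_m", "a_m", "hom_f", "hemi_m"),
                          names(tab))
  for (cc in count_cols) {
    parsed <- suppressWarnings(as.integer(tab[[cc]]))
    bad <- !is.na(tab[[cc]]) & tab[[cc]] != "" & is.na(parsed)
    if (any(bad)) {
      msg <- sprintf("unparseable integer in column %s at row(s) %s", cc,
                     paste(head(which(bad), 5L), collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      parsed[bad] <- NA_integer_
    }
    tab[[cc]] <- parsed
  }
  tab$pos <- as.numeric(tab$pos)
  if ("qc_fail" %in% names(tab)) {
    tab$qc_fail <- tolower(tab$qc_fail) %in% c("true", "yes", "1")
  }

  hf <- if ("hom_f" %in% names(tab)) tab$hom_f else rep(NA_integer_, nrow(tab))
  hm <- if ("hemi_m" %in% names(tab)) tab$hemi_m else rep(NA_integer_, nrow(tab))
  ok <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    res <- tryCatch({
      validate_counts(tab$v_f[i], tab$a_f[i], tab$v_m[i], tab$a_m[i],
                      hom_f = hf[i], hemi_m = hm[i],
                      where = as.character(i))
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(res)) {
      if (strict) stop("row ", i, " (", tab$variant_id[i], "): ", res,
                       call. = FALSE)
      warning("dropping row ", i, " (", tab$variant_id[i], "): ", res,
              call. = FALSE)
      ok[i] <- FALSE
    }
  }
  tab <- tab[ok, , drop = FALSE]
  tab$chrom <- normalize_chrom(tab$chrom)
  tab$region <- classify_region(tab$chrom, tab$pos, map)
  tibble::as_tibble(tab)
}

#' Write a sex-stratified allele count table
#'
#' Inverse of [read_count_table()]: writes the standard tab-separated
#' layout, preserving all count fields exactly so that a read/write cycle
#' round-trips.
#'
#' @param records Variant record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(records, path) {
  cols <- intersect(c("variant_id", "chrom", "pos", "ref", "alt",
                      "v_f", "a_f", "v_m", "a_m", "hom_f", "hemi_m",
                      "qc_fail"), names(records))
  readr::write_tsv(records[cols], path, progress = FALSE)
  invisible(path)
}

#' Read sex-stratified counts from a gnomAD-dialect VCF
#'
#' Parses a VCF whose INFO fields carry per-sex allele counts (the gnomAD
#' convention), decomposing multiallelic sites into one record per
#' alternate allele. Per-allele fields (AC, nhomalt) are comma-separated
#' lists aligned with ALT; site-level totals (AN) are shared across the
#' alleles of a site.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param field_map Named list mapping the roles `ac_female`, `an_female`,
#'   `ac_male`, `an_male` and optionally `nhomalt_female`,
#'   `nhomalt_male` to INFO keys. Defaults follow gnomAD v2 naming.
#' @param map A [region_map()] for region classification.
#' @return A tibble of variant records. Sites missing a mapped INFO key are
#'   skipped; the number skipped is reported as a message.
#' @export
read_vcf_counts <- function(path,
                            field_map = list(ac_female = "AC_female",
                                             an_female = "AN_female",
                                             ac_male = "AC_male",
                                             an_male = "AN_male",
                                             nhomalt_female = "nhomalt_female",
                                             nhomalt_male = "nhomalt_male"),
                            map = region_map()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0) {
    return(empty_records())
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)

  info_field <- function(key) {
    if (is.null(key)) return(NULL)
    vals <- vcfR::extract.info(vcf, element = key)
    vals
  }
  ac_f <- info_field(field_map$ac_female)
  an_f <- info_field(field_map$an_female)
  ac_m <- info_field(field_map$ac_male)
  an_m <- info_field(field_map$an_male)
  hom_f <- info_field(field_map$nhomalt_female)
  hemi_m <- info_field(field_map$nhomalt_male)

  out <- vector("list", nrow(fix))
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    if (is.na(ac_f[i]) || is.na(an_f[i]) || is.na(ac_m[i]) || is.na(an_m[i])) {
      n_skipped <- n_skipped + 1L
      next
    }
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    acf <- as.integer(strsplit(ac_f[i], ",", fixed = TRUE)[[1]])
    acm <- as.integer(strsplit(ac_m[i], ",", fixed = TRUE)[[1]])
    hf <- if (!is.null(hom_f) && !is.na(hom_f[i])) {
      as.integer(strsplit(hom_f[i], ",", fixed = TRUE)[[1]])
    } else rep(NA_integer_, length(alts))
    hm <- if (!is.null(hemi_m) && !is.na(hemi_m[i])) {
      as.integer(strsplit(hemi_m[i], ",", fixed = TRUE)[[1]])
    } else rep(NA_integer_, length(alts))
    if (length(acf) != length(alts) || length(acm) != length(alts)) {
      n_skipped <- n_skipped + 1L
      next
    }
    id <- if (!is.na(fix$ID[i]) && fix$ID[i] != ".") fix$ID[i] else {
      paste(fix$CHROM[i], fix$POS[i], fix$REF[i], sep = "-")
    }
    out[[i]] <- tibble::tibble(
      variant_id = if (length(alts) == 1) id else paste(id, alts, sep = "-"),
      chrom = normalize_chrom(fix$CHROM[i]),
      pos = as.numeric(fix$POS[i]),
      ref = fix$REF[i],
      alt = alts,
      v_f = acf,
      a_f = as.integer(an_f[i]),
      v_m = acm,
      a_m = as.integer(an_m[i]),
      hom_f = rep_len(hf, length(alts)),
      hemi_m = rep_len(hm, length(alts))
    )
  }
  if (n_skipped > 0) {
    message(n_skipped, " site(s) skipped: missing or misaligned INFO fields")
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_records())
  records <- dplyr::bind_rows(out)
  validate_counts(records$v_f, records$a_f, records$v_m, records$a_m,
                  records$hom_f, records$hemi_m,
                  where = records$variant_id)
  records$region <- classify_region(records$chrom, records$pos, map)
  records
}

empty_records <- function() {
  tibble::tibble(
    variant_id = character(), chrom = character(), pos = numeric(),
    ref = character(), alt = character(),
    v_f = integer(), a_f = integer(), v_m = integer(), a_m = integer(),
    hom_f = integer(), hemi_m = integer(), region = character()
  )
}

#' Filter variants by minimum allele count
#'
#' Keeps records whose sex-combined minor allele count `v_f + v_m` is at
#' least `min_ac` (inclusive). The combined count is the gnomAD AC
#' convention; set `per_sex = TRUE` to require the minimum in each sex
#' separately instead.
#'
#' @param records Variant record tibble.
#' @param min_ac Minimum allele count, default 5.
#' @param per_sex Require `v_f >= min_ac` and `v_m >= min_ac` instead of
#'   the combined count.
#' @return The kept records, in input order, with attributes `n_in` and
#'   `n_dropped` recording the filter's effect.
#' @export
filter_by_allele_count <- function(records, min_ac = 5, per_sex = FALSE) {
  stopifnot(min_ac >= 0)
  keep <- if (per_sex) {
    records$v_f >= min_ac & records$v_m >= min_ac
  } else {
    (records$v_f + records$v_m) >= min_ac
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "n_in") <- nrow(records)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
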