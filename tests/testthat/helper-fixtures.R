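# Fixture builders shared across test files. All fixtures are generated in
# code at test time.

# a small well-formed count table; returns its path
write_test_count_table <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                   rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      variant_id = c("v1", "v2", "v3"),
      chrom = c("X", "X", "21"),
      pos = c(500000, 50000000, 1234567),
      ref = c("A", "C", "G"),
      alt = c("G", "T", "A"),
      v_f = c(10L, 3L, 100L),
      a_f = c(2000L, 1000L, 5000L),
      v_m = c(4L, 0L, 60L),
      a_m = c(1000L, 600L, 2500L),
      hom_f = c(0L, 0L, 2L),
      hemi_m = c(4L, 0L, NA)
    )
  }
  path <- file.path(dir, "counts.tsv")
  readr::write_tsv(rows, path, progress = FALSE)
  path
}

# a gnomAD-dialect VCF with per-sex INFO fields; body rows supplied as
# pre-formatted strings
write_test_vcf <- function(body,
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrX>",
    "##contig=<ID=chr21>",
    "##INFO=<ID=AC_female,Number=A,Type=Integer,Description=\"female alt AC\">",
    "##INFO=<ID=AN_female,Number=1,Type=Integer,Description=\"female AN\">",
    "##INFO=<ID=AC_male,Number=A,Type=Integer,Description=\"male alt AC\">",
    "##INFO=<ID=AN_male,Number=1,Type=Integer,Description=\"male AN\">",
    "##INFO=<ID=nhomalt_female,Number=A,Type=Integer,Description=\"female hom count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  path <- file.path(dir, "test.vcf")
  writeLines(c(header, body), path)
  path
}

# independent rational-arithmetic ratio oracle: integer numerator and
# denominator, one division
oracle_ratio <- function(v_f, a_f, v_m, a_m) {
  ((v_f + 1) * (a_m + 1)) / ((a_f + 1) * (v_m + 1))
}

packaged <- function(file) fmratio_example(file)
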