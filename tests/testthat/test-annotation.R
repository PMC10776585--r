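test_that("RegulomeDB ranks parse, normalize and order correctly", {
  expect_equal(as.character(parse_regulome_rank("2b")), "2b")
  expect_equal(as.character(parse_regulome_rank(" 1A ")), "1a")
  expect_equal(as.character(parse_regulome_rank("7")), "7")
  expect_true(parse_regulome_rank("1a") < parse_regulome_rank("1b"))
  expect_true(parse_regulome_rank("2c") < parse_regulome_rank("7"))
  expect_equal(regulome_rank_stratum(c("1f", "2b", "3a", "7")),
               c(1L, 2L, 3L, 7L))
  expect_error(parse_regulome_rank("8"), "valid categories")
  expect_error(parse_regulome_rank("2d"), "valid categories")
})

test_that("the regulatory-evidence rule is rank < 3 OR score > 0.5, strict", {
  expect_true(regulatory_evidence_flag("2b", 0.48))   # rank qualifies
  expect_true(regulatory_evidence_flag("5", 0.58955)) # score qualifies
  expect_false(regulatory_evidence_flag("7", 0.18412))
  expect_false(regulatory_evidence_flag("3a", 0.5))   # both boundaries strict
  expect_true(regulatory_evidence_flag("2c", 0))
  expect_error(regulatory_evidence_flag("5", 1.2), "\\[0, 1\\]")
})

test_that("regulatory evidence is monotone in rank and score", {
  levels <- regulome_rank_levels()
  for (s in c(0, 0.3, 0.7)) {
    flags <- vapply(levels, regulatory_evidence_flag, logical(1), score = s)
    # improving (lowering) the rank never flips TRUE -> FALSE
    expect_true(all(diff(as.integer(flags)) <= 0) || all(flags))
  }
  scores <- seq(0, 1, by = 0.05)
  flags <- vapply(scores, function(s) regulatory_evidence_flag("6", s),
                  logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))
})

test_that("packaged evidence tables load and their tallies match brute force", {
  ann <- read_annotation_table(packaged("high_ratio_clinvar_evidence.tsv"))
  reg <- read_regulome_table(packaged("high_ratio_regulome_evidence.tsv"))
  expect_equal(nrow(ann), 25)
  expect_equal(nrow(reg), 25)
  expect_setequal(ann$variant_id, reg$variant_id)  # same 25 variants

  joined <- dplyr::left_join(ann, reg, by = "variant_id")
  s <- summarize_findings(joined)
  expect_equal(s$n_variants, 25)
  expect_equal(s$n_qc_fail, sum(ann$qc_fail_genomes == "yes"))
  expect_equal(s$n_benign_or_likely,
               sum(ann$clinvar_class %in%
                     c("BENIGN", "LIKELY_BENIGN", "BENIGN_OR_LIKELY_BENIGN")))
  expect_equal(s$n_regulatory_evidence,
               sum(regulome_rank_stratum(reg$regulome_rank) < 3 |
                     reg$regulome_score > 0.5))
  # permutation invariance
  set.seed(2)
  s2 <- summarize_findings(joined[sample(25), ])
  expect_equal(s2, s)
})

test_that("joins left-join on variant_id with placeholders for unmatched", {
  rec <- tibble::tibble(variant_id = c("a", "b", "c"), ratio = c(20, 30, 40))
  ann <- tibble::tibble(variant_id = c("a", "b"),
                        clinvar_class = c("BENIGN", "UNCERTAIN"),
                        qc_fail_genomes = c("yes", "no"))
  j <- join_annotations(rec, ann)
  expect_equal(nrow(j), 3)
  expect_equal(j$clinvar_class[3], "ABSENT")
  expect_equal(j$qc_fail_genomes[3], "not_assessed")
  expect_equal(attr(j, "n_unmatched"), 1L)
  # disjoint ids: all placeholders
  j2 <- join_annotations(tibble::tibble(variant_id = "zzz"), ann)
  expect_equal(j2$clinvar_class, "ABSENT")
  # duplicate annotation ids are an error naming the duplicates
  expect_error(join_annotations(rec, ann[c(1, 1, 2), ]), "a")
})

test_that("invalid enum values and empty collections are rejected", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.tsv")
  writeLines(paste(
    c("variant_id\tclinvar_class\tqc_fail_genomes\tomim_link\tstructural_prediction",
      "v1\tSORT_OF_BENIGN\tyes\tSPECIFIC\tNEUTRAL"), collapse = "\n"), path)
  expect_error(read_annotation_table(path), "clinvar_class")
  expect_error(summarize_findings(tibble::tibble()), "empty")
})
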