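test_that("compute_ratio reproduces worked examples", {
  # female-only FMR1-style variant: never seen in 38,527 male X chromosomes
  expect_equal(round(compute_ratio(18736, 104056, 0, 38527), 1), 6937.5)
  # symmetric zero-carrier case
  expect_equal(compute_ratio(0, 100, 0, 100), 1.0)
  # direct arithmetic: ((6/1001)/(6/501)) = 501/1001
  expect_equal(compute_ratio(5, 1000, 5, 500), 501 / 1001)
  # finite and positive even with empty male data
  expect_true(is.finite(compute_ratio(0, 0, 0, 0)))
  expect_gt(compute_ratio(3, 10, 0, 0), 0)
})

test_that("invalid counts are rejected with the offending field named", {
  expect_error(compute_ratio(-1, 10, 0, 5), "v_f")
  expect_error(compute_ratio(11, 10, 0, 5), "v_f exceeds a_f")
  expect_error(compute_ratio(1, 10, 6, 5), "v_m exceeds a_m")
  expect_error(validate_counts(5, 10, 0, 5, hom_f = 3), "hom_f")
})

test_that("pseudocount symmetry: swapping sexes inverts the ratio exactly", {
  set.seed(42)
  for (i in 1:50) {
    a_f <- sample(0:500, 1); v_f <- sample(0:a_f, 1)
    a_m <- sample(0:500, 1); v_m <- sample(0:a_m, 1)
    expect_equal(compute_ratio(v_f, a_f, v_m, a_m),
                 1 / compute_ratio(v_m, a_m, v_f, a_f), tolerance = 1e-14)
  }
})

test_that("ratio is monotone in each count and bounded by a_m + 1", {
  r0 <- compute_ratio(10, 100, 5, 50)
  expect_gt(compute_ratio(11, 100, 5, 50), r0)
  expect_lt(compute_ratio(10, 100, 6, 50), r0)
  set.seed(7)
  for (i in 1:100) {
    a_f <- sample(0:200, 1); v_f <- sample(0:a_f, 1)
    a_m <- sample(0:200, 1); v_m <- sample(0:a_m, 1)
    expect_lte(compute_ratio(v_f, a_f, v_m, a_m), a_m + 1)
  }
})

test_that("compute_ratio matches the rational oracle on a small grid", {
  grid <- expand.grid(a_f = 0:8, a_m = 0:8)
  for (k in seq_len(nrow(grid))) {
    a_f <- grid$a_f[k]; a_m <- grid$a_m[k]
    for (v_f in 0:a_f) for (v_m in 0:a_m) {
      expect_equal(compute_ratio(v_f, a_f, v_m, a_m, validate = FALSE),
                   oracle_ratio(v_f, a_f, v_m, a_m), tolerance = 1e-12)
    }
  }
})

test_that("log2_ratio is the exact base-2 logarithm and rejects non-positives", {
  expect_equal(log2_ratio(1), 0)
  expect_equal(log2_ratio(2), 1)
  expect_equal(log2_ratio(6937.5), log(6937.5, base = 2))
  expect_error(log2_ratio(0), "positive")
  expect_error(log2_ratio(-2), "positive")
})

test_that("carrier profiles follow the rule table", {
  # female-only with known zero hom count
  expect_equal(classify_carrier_profile(18736, 104056, 0, 38527, hom_f = 0),
               "ONLY_HET_FEMALES")
  # no carriers at all: no claim possible
  expect_equal(classify_carrier_profile(0, 100, 0, 100, hom_f = 0), "UNKNOWN")
  # no males, zygosity unknown
  expect_equal(classify_carrier_profile(10, 1000, 0, 500), "NO_MALES")
  # no males, hom females present
  expect_equal(classify_carrier_profile(10, 1000, 0, 500, hom_f = 2),
               "NO_MALES")
  # male carriers but zygosity absent: rarity cannot be judged
  expect_equal(classify_carrier_profile(10, 1000, 2, 500), "UNKNOWN")
  # rare males and rare hom females
  expect_equal(classify_carrier_profile(500, 2e6, 1, 1e6, hom_f = 0),
               "MALES_AND_HOM_FEMALES_RARE")
  # common in both
  expect_equal(classify_carrier_profile(500, 2000, 150, 1000, hom_f = 60),
               "UNRESTRICTED")
})

test_that("ratio summaries use the sample (n-1) standard deviation", {
  s <- summarize_ratios(c(1, 1, 1))
  expect_equal(s$mean_ratio, 1); expect_equal(s$sd_ratio, 0)
  expect_equal(s$min_ratio, 1); expect_equal(s$max_ratio, 1)
  s2 <- summarize_ratios(c(0.5, 2))
  expect_equal(s2$mean_ratio, 1.25)
  expect_equal(s2$sd_ratio, sd(c(0.5, 2)))
  expect_equal(round(s2$sd_ratio, 4), 1.0607)
  expect_equal(s2$mean_log2, 0)  # log2(0.5) and log2(2) cancel
  expect_error(summarize_ratios(numeric(0)), "empty")
  # report layer rounds to one decimal, internals keep full precision
  f <- format_ratio_summary(s2)
  expect_equal(f$sd_ratio, 1.1)
})
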