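test_that("simulation is reproducible and respects count conservation", {
  cfg <- simulation_config(n_variants = 300, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  rec <- a$records
  expect_true(all(rec$v_f <= rec$a_f))
  expect_true(all(rec$v_m <= rec$a_m))
  expect_true(all(2 * rec$hom_f <= rec$v_f))
  nonpar <- rec$region == "NONPAR_X"
  expect_true(all(rec$hemi_m[nonpar] == rec$v_m[nonpar]))
  # regions and causal labels are structured as configured
  expect_equal(sum(a$truth$region %in% c("PAR1", "PAR2")), 60)
  expect_true(all(a$truth$region[a$truth$causal] == "NONPAR_X"))
  # simulated positions classify back to their assigned region
  expect_equal(classify_region(rec$chrom, rec$pos, region_map("GRCh38")),
               rec$region)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(w_m = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(n_males = 0), "population sizes")
  expect_error(simulation_config(freq_dist = list(kind = "loguniform",
                                                  p_min = 0, p_max = 0.1)))
})

test_that("an empty simulation yields valid empty outputs", {
  sim <- simulate_cohort(simulation_config(n_variants = 0))
  expect_equal(nrow(sim$records), 0)
  expect_equal(nrow(sim$truth), 0)
  # empty records still flow through the downstream operations
  expect_equal(nrow(filter_by_allele_count(sim$records, 5)), 0)
})

test_that("a no-effect null cohort has log2 ratios centered near zero", {
  cfg <- simulation_config(n_variants = 3000, frac_par = 0.2, frac_causal = 0,
                           w_m = 1, w_f_het = 1, w_f_hom = 1, seed = 4,
                           freq_dist = list(kind = "loguniform",
                                            p_min = 0.01, p_max = 0.2))
  sim <- simulate_cohort(cfg)
  rec <- score_variants(filter_by_allele_count(sim$records, 5))
  l2 <- rec$log2_ratio
  expect_lt(abs(mean(l2)), 3 * sd(l2) / sqrt(length(l2)))
  expect_lt(abs(mean(rec$ratio) - 1), 0.05)
  # the PAR class has sex-symmetric allele counts, so its log2 ratios are
  # symmetric about 0 (sign test)
  par_l2 <- l2[rec$region != "NONPAR_X" & l2 != 0]
  st <- binom.test(sum(par_l2 > 0), length(par_l2))
  expect_gt(st$p.value, 0.01)
})

test_that("a fully male-lethal variant matches the analytic expectation", {
  # with w_m = 0, w_f_hom = 0: no male carriers survive, so v_m = 0 and
  # E[R] ~ (p/(1+p)) * (a_m + 1) with a_m ~ n_males * (1 - p)
  p <- 0.09
  cfg <- simulation_config(n_variants = 200, n_males = 38527,
                           n_females = 52028,
                           frac_par = 0, frac_causal = 1,
                           w_m = 0, w_f_hom = 0, w_f_het = 1, seed = 21,
                           freq_dist = list(kind = "uniform",
                                            p_min = p, p_max = p))
  sim <- simulate_cohort(cfg)
  rec <- score_variants(sim$records)
  expect_true(all(rec$v_m == 0))
  expect_true(all(rec$hom_f == 0))
  expect_true(all(rec$carrier_profile == "ONLY_HET_FEMALES"))
  expected <- (p / (1 + p)) * (38527 * (1 - p) + 1)
  expect_gt(mean(rec$ratio), 1000)  # ratios of order 10^3
  expect_lt(abs(mean(rec$ratio) - expected) / expected, 0.05)
})

test_that("median causal ratio increases with male lethality", {
  med <- vapply(c(1, 0.5, 0.1, 0), function(wm) {
    cfg <- simulation_config(n_variants = 400, frac_par = 0, frac_causal = 1,
                             w_m = wm, w_f_hom = 1, w_f_het = 1, seed = 8,
                             freq_dist = list(kind = "uniform",
                                              p_min = 0.05, p_max = 0.2))
    rec <- score_variants(simulate_cohort(cfg)$records)
    median(rec$ratio)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("evaluate_detection handles degenerate thresholds and id mismatches", {
  cfg <- simulation_config(n_variants = 500, frac_causal = 0.5, seed = 13)
  sim <- simulate_cohort(cfg)
  rec <- score_variants(sim$records)
  perf_inf <- evaluate_detection(rec, sim$truth, threshold = Inf)
  expect_equal(perf_inf$sensitivity, 0)
  expect_equal(perf_inf$specificity, 1)
  rec$variant_id[1] <- "not_in_truth"
  expect_error(evaluate_detection(rec, sim$truth, threshold = 11), "absent")
})
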