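#' Simulation configuration for sex-stratified cohorts
#'
#' Describes a gnomAD-style cohort of unrelated adults genotyped at
#' independent X-linked (and pseudoautosomal) variants. Each variant has a
#' population minor-allele frequency drawn from `freq_dist`; genotypes
#' follow Hardy-Weinberg proportions at conception; viability selection
#' then acts once, pre-ascertainment, removing a fraction of carriers
#' before the cohort is sampled — the mechanism by which a male-lethal
#' variant is depleted from adult males.
#'
#' Defaults emulate the interpretive model for extreme high-ratio variants:
#' complete lethality in hemizygous males (`w_m = 0`) and homozygous
#' females (`w_f_hom = 0`) with no effect in heterozygous females
#' (`w_f_het = 1`). The allele-frequency spectrum defaults to log-uniform
#' over `[1e-4, 0.2]`, spanning rare to common exome variants.
#'
#' @param n_males,n_females Conceived individuals per sex per variant.
#' @param n_variants Number of independent variants.
#' @param freq_dist List with `kind` (`"loguniform"` or `"uniform"`),
#'   `p_min`, `p_max`.
#' @param w_m Viability of carrier (hemizygous) males for causal variants.
#' @param w_f_het,w_f_hom Viability of heterozygous / homozygous females.
#' @param frac_par Fraction of variants assigned pseudoautosomal status
#'   (always simulated with no sex effect: the built-in null class).
#' @param frac_causal Fraction of non-PAR variants given the sex-effect
#'   viabilities; the remainder are null.
#' @param seed Integer seed; identical configs and seeds give identical
#'   output (Mersenne-Twister streams).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_males = 10000, n_females = 10000,
                              n_variants = 1000,
                              freq_dist = list(kind = "loguniform",
                                               p_min = 1e-4, p_max = 0.2),
                              w_m = 0, w_f_het = 1, w_f_hom = 0,
                              frac_par = 0.2, frac_causal = 0.05,
                              seed = 1L) {
  probs <- c(w_m = w_m, w_f_het = w_f_het, w_f_hom = w_f_hom,
             frac_par = frac_par, frac_causal = frac_causal)
  if (any(probs < 0 | probs > 1)) {
    stop("viabilities and fractions must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  if (n_males < 1 || n_females < 1) {
    stop("population sizes must be >= 1", call. = FALSE)
  }
  if (n_variants < 0) stop("n_variants must be >= 0", call. = FALSE)
  stopifnot(freq_dist$kind %in% c("loguniform", "uniform"),
            freq_dist$p_min > 0, freq_dist$p_min <= freq_dist$p_max,
            freq_dist$p_max <= 1)
  structure(list(n_males = as.integer(n_males),
                 n_females = as.integer(n_females),
                 n_variants = as.integer(n_variants),
                 freq_dist = freq_dist,
                 w_m = w_m, w_f_het = w_f_het, w_f_hom = w_f_hom,
                 frac_par = frac_par, frac_causal = frac_causal,
                 seed = as.integer(seed),
                 rng = "Mersenne-Twister"),
            class = "simulation_config")
}

draw_freqs <- function(freq_dist, n) {
  if (freq_dist$kind == "uniform") {
    runif(n, freq_dist$p_min, freq_dist$p_max)
  } else {
    exp(runif(n, log(freq_dist$p_min), log(freq_dist$p_max)))
  }
}

#' Simulate a sex-stratified allele-count cohort
#'
#' For each variant, draws an allele frequency, assigns a region (PAR
#' variants are always null; a fraction of non-PAR X variants are causal),
#' samples conception genotypes under Hardy-Weinberg proportions, applies
#' sex- and genotype-specific viability, and tallies the surviving cohort's
#' allele counts:
#' * non-PAR X males are hemizygous — one allele each, carriers survive
#'   with probability `w_m` (causal) or 1 (null); `a_m` is the number of
#'   surviving males, `v_m` (= `hemi_m`) the surviving carriers;
#' * PAR males are diploid with Hardy-Weinberg genotypes and no selection;
#' * females are diploid everywhere; homozygous carriers survive with
#'   `w_f_hom`, heterozygotes with `w_f_het` (causal) or 1 (null);
#'   `a_f = 2 *` surviving females, `v_f = 2 * hom + het` among survivors.
#'
#' @param config A [simulation_config()].
#' @return A list with `records` (variant record tibble, the same layout
#'   [read_count_table()] returns) and `truth` (tibble with `variant_id`,
#'   `true_freq`, `causal`, `region`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_variants
  if (n == 0) {
    return(list(records = empty_records(),
                truth = tibble::tibble(variant_id = character(),
                                       true_freq = numeric(),
                                       causal = logical(),
                                       region = character())))
  }
  map <- region_map("GRCh38")
  n_par <- round(config$frac_par * n)
  n_nonpar <- n - n_par
  n_causal <- round(config$frac_causal * n_nonpar)
  region <- c(rep(c("PAR1", "PAR2"), length.out = n_par),
              rep("NONPAR_X", n_nonpar))
  causal <- c(rep(FALSE, n_par), rep(TRUE, n_causal),
              rep(FALSE, n_nonpar - n_causal))

  withr::with_seed(config$seed, {
    p <- draw_freqs(config$freq_dist, n)
    # positions: uniform within the region's interval (non-PAR X between
    # the two PARs)
    pos <- numeric(n)
    i1 <- region == "PAR1"; i2 <- region == "PAR2"; ix <- region == "NONPAR_X"
    pos[i1] <- floor(runif(sum(i1), map$par1[1], map$par1[2]))
    pos[i2] <- floor(runif(sum(i2), map$par2[1], map$par2[2]))
    pos[ix] <- floor(runif(sum(ix), map$par1[2], map$par2[1]))

    nm <- config$n_males; nf <- config$n_females

    # males
    v_m <- integer(n); a_m <- integer(n); hemi_m <- rep(NA_integer_, n)
    # non-PAR X: hemizygous
    carriers <- rbinom(sum(ix), nm, p[ix])
    wm <- ifelse(causal[ix], config$w_m, 1)
    surv_car <- rbinom(sum(ix), carriers, wm)
    v_m[ix] <- surv_car
    a_m[ix] <- (nm - carriers) + surv_car
    hemi_m[ix] <- surv_car
    # PAR: diploid, no selection; HWE genotypes via conditional binomials
    ipar <- i1 | i2
    if (any(ipar)) {
      pp <- p[ipar]
      hom_m <- rbinom(sum(ipar), nm, pp^2)
      het_m <- rbinom(sum(ipar), nm - hom_m, 2 * pp / (1 + pp))
      v_m[ipar] <- 2L * hom_m + het_m
      a_m[ipar] <- 2L * nm
    }

    # females: diploid everywhere
    hom <- rbinom(n, nf, p^2)
    het <- rbinom(n, nf - hom, 2 * p / (1 + p))
    wt <- nf - hom - het
    w_hom <- ifelse(causal, config$w_f_hom, 1)
    w_het <- ifelse(causal, config$w_f_het, 1)
    surv_hom <- rbinom(n, hom, w_hom)
    surv_het <- rbinom(n, het, w_het)
    a_f <- 2L * (surv_hom + surv_het + wt)
    v_f <- 2L * surv_hom + surv_het
  })

  id <- sprintf("sim%06d", seq_len(n))
  records <- tibble::tibble(
    variant_id = id, chrom = "X", pos = pos,
    ref = "A", alt = "G",
    v_f = as.integer(v_f), a_f = as.integer(a_f),
    v_m = as.integer(v_m), a_m = as.integer(a_m),
    hom_f = as.integer(surv_hom), hemi_m = hemi_m,
    region = region
  )
  truth <- tibble::tibble(variant_id = id, true_freq = p,
                          causal = causal, region = region)
  list(records = records, truth = truth)
}

#' Detection operating characteristics against simulated truth
#'
#' Compares flagged variants with the simulator's causal labels.
#' Sensitivity is the fraction of causal variants (among the records
#' supplied, i.e. after any allele-count filtering) that are flagged;
#' specificity is the fraction of non-causal records not flagged.
#'
#' @param records Scored variant records; if they lack a `high_ratio`
#'   column, `threshold` is applied via [flag_high_ratio()].
#' @param truth Truth tibble from [simulate_cohort()].
#' @param threshold Threshold used when `high_ratio` is absent.
#' @return A one-row tibble with `sensitivity`, `specificity`, and the
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_detection <- function(records, truth, threshold = NULL) {
  if (!all(records$variant_id %in% truth$variant_id)) {
    stop("records contain variant ids absent from truth", call. = FALSE)
  }
  if (!"high_ratio" %in% names(records)) {
    if (is.null(threshold)) {
      stop("records are unflagged and no threshold supplied", call. = FALSE)
    }
    records <- flag_high_ratio(records, threshold)
  }
  causal <- truth$causal[match(records$variant_id, truth$variant_id)]
  flagged <- records$high_ratio
  tp <- sum(flagged & causal); fn <- sum(!flagged & causal)
  fp <- sum(flagged & !causal); tn <- sum(!flagged & !causal)
  tibble::tibble(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}
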