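---
title: "Detecting sex-specific pathogenicity with allele proportion ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-specific pathogenicity with allele proportion ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmratio)
```

## The problem

Standard variant-pathogenicity annotation averages over biological sex. On
the non-pseudoautosomal X chromosome this can be badly misleading: males are
hemizygous, so a variant that is lethal or strongly deleterious in males can
be carried safely by heterozygous females, reach a high sex-averaged minor
allele frequency, and be labelled *benign* — while not a single adult male
carrier exists in a cohort of tens of thousands. fmratio screens for this
signature directly from sex-stratified allele counts of the kind gnomAD
distributes.

## The statistic

For a variant with minor allele count $V_f$ among $A_f$ female alleles and
$V_m$ among $A_m$ male alleles, the female-to-male allele proportion ratio is

$$R = \frac{(V_f + 1)/(A_f + 1)}{(V_m + 1)/(A_m + 1)}.$$

Adding 1 to all four terms keeps $R$ finite and positive even when
$V_m = 0$ — exactly the case of interest. The pseudocount placement is fixed
by design, not a configurable prior: the published worked example (the FMR1
variant rs201580891, seen 18,736 times among 104,056 female alleles and
never among 38,527 male alleles) yields $R = 6937.5$ only under this
convention:

```{r}
round(compute_ratio(18736, 104056, 0, 38527), 1)
```

The total of 104,056 female observations is interpreted as $A_f$, the number
of *allele* observations (females carry two X-linked loci each), because the
ratio arithmetic reproduces the published value only under that reading.

Properties the test suite verifies: swapping the sexes maps $R$ to $1/R$;
$R$ is strictly increasing in $V_f$ and decreasing in $V_m$; and
$R \le A_m + 1$, so the male cohort size caps the attainable evidence.

The ratio targets *recessive-in-females* sex-specific effects. A variant
deleterious in both sexes, or dominant in females, depletes both numerator
and denominator and will not stand out; this is a stated limitation, not a
modelling target.

## Threshold calibration against the pseudoautosomal null

Pseudoautosomal (PAR) variants are diploid in both sexes, so no sex-specific
depletion is expected and their ratios form a built-in empirical null.
`calibrate_threshold()` defaults to `par_max`: the smallest integer strictly
greater than the largest observed PAR ratio. This yields a round empiric
threshold that, by construction, no PAR variant exceeds; flagging
(`flag_high_ratio()`) is then *strictly* greater-than, so a ratio exactly at
the threshold is not flagged. A raw (non-integer) maximum and an
order-statistic quantile mode (`par_quantile`, `stats::quantile(type = 1)`)
are available, as is a `fixed` mode for externally chosen thresholds.

Flagging defaults to the non-PAR X only. Extreme ratios on autosomes may
also mark sex-differential effects, but autosomal thresholds are far less
established, so autosomal flagging is opt-in (`include_autosomes = TRUE`).

## Filtering and carrier profiles

Variants with combined minor allele count $V_f + V_m < 5$ are removed before
analysis (`filter_by_allele_count()`, inclusive boundary, sex-combined count
as in gnomAD AC semantics; a per-sex mode exists). The minor allele is taken
as the distributed ALT allele; no re-folding to the rarer allele is done.

`classify_carrier_profile()` condenses the zygosity evidence: a variant seen
only in heterozygous females (`ONLY_HET_FEMALES`, requires a female
homozygote count of zero), seen in no males with zygosity unknown
(`NO_MALES`), carried by males and homozygous females only at frequencies
below a rarity fraction (`MALES_AND_HOM_FEMALES_RARE`; default $10^{-4}$ of
the respective denominator — a deliberately conservative plumbing default,
since no published cutoff exists), `UNRESTRICTED`, or `UNKNOWN` when the
question cannot be answered from the available fields.

## Annotation reconciliation

For flagged variants, `summarize_findings()` applies five counting rules to
clinical/structural/regulatory evidence tables:

* benign-or-likely: ClinVar class in {Benign, Likely benign,
  Benign/likely benign};
* QC failure in a second (genomes) dataset — sex-differential allele
  frequencies are often mistaken for genotyping error and filtered away;
* specific OMIM gene–phenotype links (putative/tentative links and genes
  with no noted phenotype excluded);
* explicit structural-effect predictions (Neutral/Stabilizing/
  Destabilizing; "Unclear" calls and variants with no specifiable amino acid
  change excluded);
* regulatory evidence: RegulomeDB rank stratum strictly less than 3 (any of
  1a–1f, 2a–2c) **or** score strictly greater than 0.5.

The package ships transcribed evidence tables for the 25 high-ratio
non-pseudoautosomal X variants identified in gnomAD exomes
(`fmratio_example()`). On these fixtures the rules tally 22/25 QC failures,
6/25 structural calls and 13/25 with regulatory evidence. The ClinVar tally
is 21/25 benign-or-likely and the OMIM tally 22/25 specific links: the
accompanying narrative counts (22 and 23) differ by one from a direct
recount of the published tables, and the package reports the recount rather
than forcing the narrative numbers.

## The simulator

`simulate_cohort()` generates gnomAD-style sex-stratified counts under a
one-round viability-selection model: each variant draws a population allele
frequency, conception genotypes follow Hardy–Weinberg proportions, and
carriers survive to ascertainment with sex- and genotype-specific
viabilities ($w_m$ for hemizygous males, $w_{f,het}$ and $w_{f,hom}$ for
females). Selection acts once, pre-ascertainment — premature death depleting
the adult cohort — with no age structure, no linkage, and no
multi-generation dynamics.

Defaults, fixed a priori as the study conditions: 10,000 conceived
individuals per sex per variant, log-uniform allele frequencies on
$[10^{-4}, 0.2]$ (spanning rare to common exome variants), 20% of variants
pseudoautosomal, 5% of non-PAR variants causal, and the lethal model
$w_m = 0$, $w_{f,hom} = 0$, $w_{f,het} = 1$. Non-PAR males are hemizygous
(one allele each); PAR variants are simulated with *diploid* males under
Hardy–Weinberg genotypes and no selection, because male diploidy is what
makes the PAR class a clean null: with sex-symmetric allele counts the null
log2-ratio distribution is exactly symmetric about zero. Everything is
driven by vectorized binomial draws under a fixed Mersenne–Twister seed, so
identical configurations reproduce byte-identical cohorts.

What the simulator does **not** emulate: genotyping error, coverage and
call-rate variation between sexes, relatedness, population structure, LD
between variants, and ancestry-specific frequencies. Passing operating
characteristic tests therefore demonstrate the statistic's behaviour under
clean sampling, not robustness to those artefacts — which is precisely why
the QC-reconciliation rules exist on the annotation side.

### A numerical subtlety of the null

Under a no-effect null that includes *rare* variants, the mean log2 ratio is
slightly negative (about $-0.02$ at the default spectrum): females
contribute roughly $2N$ alleles versus $N$ for hemizygous males, and the +1
pseudocounts act asymmetrically when expected counts are small (Jensen bias
of $\log(V+1)$ is larger for the smaller male counts). This is a property of
the statistic, not a simulation artefact, and it is conservative: it shrinks
ratios, it does not inflate them. The calibration checks therefore assert
(i) specificity $\ge 0.999$ at the PAR-max threshold under the
rare-inclusive default spectrum, and (ii) a mean log2 ratio within 3
standard errors of zero under a common-variant null ($p \ge 0.01$, so
expected counts $\ge 100$ and the small-count bias vanishes), with the
sign-test symmetry property asserted on the count-symmetric PAR class. Both
use 10,000 variants per seed across 10 seeds (sizes chosen to make the
order-statistic threshold stable while keeping the default suite fast).

Detection power: with full male lethality and $p \ge 0.01$ in cohorts of
10,000 per sex, $E[R] \approx \frac{p}{1+p}\,(A_m + 1) \gg 11$, and the
suite verifies sensitivity $\ge 0.95$ at a fixed threshold of 11 across
seeds; a $w_m$ grid confirms the median causal ratio rises monotonically
with male lethality.

## Degenerate inputs and tie-breaks

* $A_m = 0$ (variant never genotyped in males) is valid; $R$ stays finite.
* A variant with no carriers at all has $R = 1$ and an `UNKNOWN` profile.
* Rows violating count invariants ($V > A$, negative counts,
  $2 \cdot hom_f > V_f$) are dropped with row-numbered diagnostics, or abort
  in strict mode.
* Multiallelic VCF sites decompose to one record per alternate allele;
  per-allele AC/nhomalt lists are split and the site-level AN is shared.
* Coordinates are 1-based; PAR intervals are half-open $[start, end)$;
  default PAR coordinates ship for GRCh37 and GRCh38 (Ensembl definitions)
  with a custom option, since published analyses name the PAR/non-PAR split
  without giving coordinates.
* Ratio summaries use the sample (n − 1) standard deviation, recorded in
  the run metadata; report-layer rounding is one decimal, internals keep
  full precision.

## Reproducibility

`run_pipeline()` writes, per output directory, the per-variant results, the
threshold report, per-chromosome summaries, the findings table and a
`run.json` with stage record counts and conventions, so a run's narrative
(records read → passing the AC filter → flagged → annotated) is
reconstructible. The `fmratio` command-line script exposes `ratio`,
`calibrate`, `simulate`, `annotate` and `report` subcommands that compose
through intermediate files and match the monolithic pipeline exactly (a
property the test suite asserts).
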