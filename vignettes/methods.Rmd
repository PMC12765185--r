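---
title: "Models and design choices behind rxswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind rxswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxswitch)
```

`rxswitch` turns raw prescription-fill streams into a case/control
drug-switching phenotype and runs the genetic association analyses that use
it. This vignette is the package's account of the underlying models, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice had
to be made.

## 1. The switching phenotype

The unit of observation is a prescription fill `(person_id, date,
atc_code)`. For a drug pair (A = zopiclone N05CF01, B = zolpidem N05CF02 by
default), a person is a **case** in the A→B direction when their first
recorded study-drug fill is A and, among fills *strictly after their first
drug-B fill* (the "tail"), at least 50% are drug B. **Controls** started on
A and either never filled B or did so for under half of the tail. People
with fewer than 3 study-drug fills are ineligible: one or two fills cannot
distinguish a consistent switch from a one-off substitution (e.g. a
stockout). The B→A direction swaps drug roles; a person's first drug places
them in exactly one direction, so the two directions partition the eligible
cohort.

Four readings of this definition are genuinely underdetermined by the verbal
rule, and each is an explicit `drug_pair()` parameter rather than a silent
choice:

* **`min_fills = 3`, combined.** "At least 3 prescriptions of either drug"
  is read as 3 fills of the two drugs *combined* (the natural reading of an
  eligibility screen over the union of study drugs); `per_drug = TRUE` gives
  the stricter per-drug reading.
* **Tail excludes the first B fill** (`tail_includes_first_b = FALSE`).
  "Subsequent prescriptions" after "trying B for the first time" is read
  strictly: the first B fill is evidence of *trying*, not of *staying*, and
  excluding it is the reading that targets a consistent switch. A person
  whose only B fill is their last fill has an empty tail and is a control —
  consistency simply cannot be assessed.
* **Exactly 50% is a case** ("at least 50%"): ties go to case.
* **Same-day first fills of both drugs** leave the first drug undefined; the
  person is excluded with reason `ambiguous_first` and counted in the
  summary, rather than silently tie-broken by ATC code order.

Duplicate same-day, same-drug fills are retained (fills are events; no
dedup rule is imposed), and all non-pair medications are ignored.
`call_switch()` is the scalar reference implementation of this rule;
`call_cohort()` is an algebraically vectorized equivalent (per-person
sufficient statistics: total fills, first drug, position of the first
destination-drug fill, destination-fill counts), and the test suite asserts
their agreement, plus exhaustive agreement of the caller with an independent
brute-force interpreter of the verbal rule on *every* fill sequence of
length ≤ 7.

Switch percentages are reported against two denominators, because published
cohort descriptions do not pin one down: eligible starters
(cases + controls, the default) and everyone whose first fill matched the
origin drug regardless of eligibility.

## 2. Association models

All genetic models are additive: dose = effect-allele count (0/1/2) or
imputed dosage in [0, 2].

**Case/control.** `logistic_assoc()` fits maximum-likelihood logistic
regression `logit P(case) = b0 + beta*dose + gamma'covariates` and reports
the Wald per-allele log-OR, SE, 95% CI and two-sided p. A registry analysis
would typically adjust for relatedness with a linear mixed model; synthetic
cohorts have no relatedness structure and the package deliberately uses
plain regression — a documented fidelity gap, not an oversight. Covariates
default to sex and year of birth in the pipeline (the published adjustment
set is not stated). Quasi-separation is flagged (`possible_separation`) from
non-convergence or an exploding SE rather than thrown, so genome-scale loops
survive degenerate variants. On a binary dose with no covariates the fit
collapses to the 2×2 closed form: `or_from_counts()` (cross-product OR,
Woolf SE, Haldane–Anscombe 0.5 correction for zero cells) and the logistic
route are tested to agree to 6 decimals — a dual-route check, not a shared
code path.

**Sex heterogeneity.** `sex_difference_test()` uses the independent-strata
z-test on the log scale, `z = (b_F − b_M)/sqrt(se_F² + se_M²)`. Fitting a
genotype×sex interaction term is the main alternative; the z-test was chosen
as the default because it operates on published-style per-stratum summaries
(OR + CI), needs no individual-level data, and reproduces reported
heterogeneity p values from printed CIs alone (SEs reconstructed as
`ln(U/L)/3.92`). It refuses overlapping strata, where independence fails.

**Conditional analysis.** `conditional_assoc()` adds the conditioning
variant's dose as a covariate and reports the target's adjusted effect —
the standard test of whether two correlated signals at a locus are
distinct. Exact collinearity (r² = 1, including self-conditioning) is a
hard, named error: the adjusted effect is not identified. At r² = 0.93 the
conditional SE inflates by 1/sqrt(1 − r²) ≈ 3.8×, so conditional power at
registry scale is real but far from certain; the test suite checks the
empirical significance rate against the analytic Wald power rather than
against wishful thinking.

**Quantitative traits.** `linear_assoc()` regresses a taste-intensity-style
rating on dose, after `rank_inverse_normal()`: Blom scores
`qnorm((rank − 3/8)/(n + 1/4))` with average ranks for ties. Blom offsets
are the common GWAS choice and make effects directly interpretable in SD
units; the transform is applied to the pooled sample by default with sex as
a covariate (`transform_by` gives the per-group alternative) because the
per-sex standardization used in published taste-test analyses is not
reproducible from the main text. Rank-INT of an approximately Gaussian
trait is close to the identity, so a generative per-allele effect of
−0.25 SD is recovered with attenuation well under the 0.01 tolerance the
tests use.

**LD and QC.** `ld_r2()` is the squared Pearson correlation of doses
(composite LD — no phasing needed, equal to allelic r² under HWE).
`eaf_and_hwe()` reports EAF = mean(dose)/2 and a mid-p exact
Hardy–Weinberg test computed by enumerating Levene's conditional
distribution of the heterozygote count on the log scale; mid-p (half weight
on equiprobable outcomes) is used for its better calibration than the
conservative full-p exact test. The implementation is hand-written (tested
against an independent enumeration oracle) because no installed package
provides it.

**Multiple testing.** `threshold_scheme()` implements class-weighted
Bonferroni: variant class `c` gets threshold `alpha*w_c / sum_v w_class(v)`,
so the class-size-weighted thresholds sum to `alpha` exactly (asserted to
1e-12). The default is a single class — plain Bonferroni; enrichment-derived
weight sets are configuration, not hardcoded truth. Significance is strict
(`p < threshold`): a p value exactly at the threshold is not significant.

## 3. The synthetic-data generator

The generator exists so that every stage — parsing, calling, regression —
can be validated by *parameter recovery* against a known truth, offline.
Defaults mirror the registry conditions the package targets: 59% female,
effect-allele frequency 0.446, per-allele switching ORs 1.36 (F) / 1.19
(M), a 14% population switch rate, and a taste trait at −0.25 SD per allele
in a sub-study of n = 2238.

* **Genotypes** are two independent Bernoulli(p) allele draws per person —
  HWE by construction. Frequencies within 1e−9 of 0 or 1 are rejected as
  degenerate.
* **Linked pairs** are built from the four-haplotype distribution implied by
  (p₁, p₂, r²) with the positive-association root
  `D = +sqrt(r² p₁q₁p₂q₂)`; each person is two independent chromosomes.
  Infeasible triples — D beyond the Lewontin bound `min(p₁q₂, q₁p₂)` — fail
  loudly, naming the bound and the maximum attainable r².
* **Switch status** is latent Bernoulli with
  `logit P = b0(sex) + ln(OR_sex)·dose`. The intercepts are solved
  numerically (per sex) so the HWE-averaged *population* switch rate equals
  `baseline_switch_rate`: published anchors are cohort-level rates
  (14%/39%/4%), which include carriers, so anchoring the non-carrier rate
  instead would misstate them. A consequence worth knowing: as OR → ∞ the
  dose-2 switch rate saturates at `rate / P(dose = 2)`, not at 1.
* **Fill sequences** are constructed *inside the caller's decision regions*
  so the phenotype caller recovers the latent label exactly (the round-trip
  property): switchers get a drug-A prefix of ≥ 1 fill then a tail that is
  ≥ 75% drug B after the first B fill; non-switchers are all-A or carry a
  single-fill B excursion (tail fraction 0, or an empty tail). Bounding the
  tail fraction away from the 50% boundary is what makes the round trip
  deterministic rather than probabilistic. Within-tail placement of the
  minority fills carries no information for the caller beyond the fraction.
* **Fill counts** are shifted geometric with floor `fills_min = 3` and mean
  `fills_mean = 10` — right-skewed, as prescription data are, with a single
  parameter. Ten fills on average (≈ a year of monthly refills, with a long
  right tail over an 18-year registry window) is a realistic anchor; the
  published work does not report the empirical fill-count distribution, so
  this is a stand-in, exposed in `sim_config()`.
* **Dates** are one fill per 30 days from a common origin: dates only
  matter for ordering here, and equal spacing makes strict within-person
  monotonicity trivially auditable. Tied dates, gaps and episode structure
  are therefore *not* emulated.
* **Traits** are `beta_sd·(dose − mean) + N(0, s²)` with `s` solved for unit
  marginal variance by default, so `beta_sd` is in SD units on the raw and
  (approximately) the rank-normalized scale.
* **Determinism.** One master seed per config; component sub-streams
  (genotypes, demographics/latent labels, fill counts, sequence layout,
  trait noise) are derived from it, so identical configs give byte-identical
  cohorts.

What passing tests on these cohorts do **not** show: robustness to episode
structure and censoring, co-medication, pharmacy-level supply shocks,
relatedness/stratification confounding, genotyping error, or tied fill
dates. The generator validates the *statistical machinery*, not the messiness
of real registries.

## 4. Numerical choices

* Logistic fits run IRLS to `epsilon = 1e-12` so closed-form equalities
  (2×2 OR, Woolf SE) hold to 6 decimals.
* Wald CIs are `±1.96·se` on the model scale, exponentiated for ORs; p
  values are two-sided normal. Large-sample normal p values are used for
  the linear model too (GWAS convention; df are large at any realistic n).
* Missing doses are handled complete-case per variant, with a warning
  carrying the dropped count.
* The exact-HWE enumeration is done on the log scale and normalized by the
  maximum term, so it is stable out to registry-scale n.
* Problem sizes in the test suite mirror the study conditions where the
  property is about recovery at scale (cohorts of 40,000–42,000; the trait
  sub-study at n = 2238; LD at n = 50,000) and drop to a few thousand where
  the property is structural (round trips, partitions, symmetries), which
  keeps the default suite comfortably reproducible on a laptop.

## 5. Pipeline and provenance

`run_pipeline()` accepts exactly one input mode — a `sim_config()` or real
files (prescriptions TSV; sample sheet TSV; VCF with GT/DS or dosage TSV) —
and produces phenotype calls, per-variant results (overall, per sex, and
the heterogeneity test), optional conditional and trait analyses, and
significance annotation. Every written output (phenotypes TSV,
summary-stats TSV in the standard CHR/POS/ID/EA/OA/EAF/N/BETA/SE/P layout,
JSON report) carries a provenance header: package version, seed, config
hash; the threshold scheme is serialized into the summary-stats header.
Identical configs produce byte-identical outputs. The package's interface
is its functions (this is an R package, not a shell tool); `tidy()`,
`glance()`, `autoplot()`/`plot_forest()` expose results in the usual
tidyverse idioms.

## 6. Known limitations

* No mixed-model/kinship correction — effect estimates on real, related
  cohorts will be anti-conservative relative to the published analyses.
* No treatment-episode segmentation, dose/DDD quantities, or
  persistence/discontinuation phenotypes; switching only.
* Replication across cohorts is "run the pipeline twice", not a
  meta-analysis.
* The exact-HWE test requires hard calls; dosages get EAF only.
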