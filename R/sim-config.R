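#' Simulation configuration for a synthetic switching cohort
#'
#' Bundles and validates every parameter of the generative model: cohort
#' size and sex composition, the effect-allele frequency of the variant
#' driving switching, per-allele odds ratios by sex, the population-average
#' baseline switch rate the intercepts are anchored to, the fill-count
#' distribution, and (optionally) a second variant in linkage disequilibrium
#' with the first and a quantitative taste trait with a per-allele effect in
#' SD units.
#'
#' Defaults mirror a registry cohort of zopiclone starters: 59% female,
#' effect-allele frequency 0.446, per-allele odds ratios 1.36 (females) and
#' 1.19 (males), and a 14% population switch rate.
#'
#' @param n_individuals Number of individuals to simulate.
#' @param female_fraction Proportion of females, in `[0, 1]`.
#' @param eaf Effect-allele frequency of the switching variant, in `(0, 1)`.
#' @param or_per_allele_female,or_per_allele_male Per-allele odds ratio for
#'   switching in each sex; must be positive and finite.
#' @param baseline_switch_rate Population-average switch probability the
#'   sex-specific intercepts are solved to reproduce at the configured
#'   allele frequency, in `(0, 1)`.
#' @param fills_min Minimum number of study-drug fills per person (>= 3 so
#'   every simulated person passes the eligibility filter).
#' @param fills_mean Mean number of fills per person; must exceed
#'   `fills_min`. Fill counts follow a shifted geometric distribution with
#'   floor `fills_min`.
#' @param seed Integer master seed; all component streams derive from it.
#' @param eaf2 Optional effect-allele frequency of a second, linked variant.
#' @param target_r2 Optional target squared genotype-dose correlation
#'   between the two variants, in `[0, 1]`. Required with `eaf2`; checked
#'   for haplotype-frequency feasibility at construction time.
#' @param beta_sd Optional per-allele effect on the quantitative trait, in
#'   SD units of the trait.
#' @param trait_noise_sd Optional residual SD of the quantitative trait. If
#'   `NULL`, the residual SD is solved so the trait has unit marginal
#'   variance.
#' @param excursion_prob Probability that a non-switcher's sequence contains
#'   a brief drug-B excursion rather than drug A only.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_switch_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 500, seed = 7)
#' cfg$baseline_switch_rate
sim_config <- function(n_individuals,
                       female_fraction = 0.59,
                       eaf = 0.446,
                       or_per_allele_female = 1.36,
                       or_per_allele_male = 1.19,
                       baseline_switch_rate = 0.14,
                       fills_min = 3L,
                       fills_mean = 10,
                       seed = 1L,
                       eaf2 = NULL,
                       target_r2 = NULL,
                       beta_sd = NULL,
                       trait_noise_sd = NULL,
                       excursion_prob = 0.3) {
  check_count <- function(x, nm, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
      stop_param("`%s` must be a single integer >= %s", nm, min)
  }
  check_prop_open <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x >= 1)
      stop_param("`%s` must lie strictly inside (0, 1), got %s", nm, format(x))
  }
  check_count(n_individuals, "n_individuals")
  check_count(fills_min, "fills_min", min = 3)
  check_count(seed, "seed", min = -.Machine$integer.max)
  if (!is.numeric(female_fraction) || female_fraction < 0 || female_fraction > 1)
    stop_param("`female_fraction` must lie in [0, 1]")
  check_prop_open(eaf, "eaf")
  check_prop_open(baseline_switch_rate, "baseline_switch_rate")
  for (nm in c("or_per_allele_female", "or_per_allele_male")) {
    or <- get(nm)
    if (!is.numeric(or) || length(or) != 1 || !is.finite(or) || or <= 0)
      stop_param("`%s` must be a positive finite odds ratio", nm)
  }
  if (!is.numeric(fills_mean) || fills_mean <= fills_min)
    stop_param("`fills_mean` must exceed `fills_min` (%d)", fills_min)
  if (!is.null(eaf2) || !is.null(target_r2)) {
    if (is.null(eaf2) || is.null(target_r2))
      stop_param("`eaf2` and `target_r2` must be supplied together")
    check_prop_open(eaf2, "eaf2")
    if (target_r2 < 0 || target_r2 > 1)
      stop_param("`target_r2` must lie in [0, 1]")
    haplotype_freqs(eaf, eaf2, target_r2) # fails loudly if infeasible
  }
  if (!is.null(trait_noise_sd) && trait_noise_sd <= 0)
    stop_param("`trait_noise_sd` must be > 0")
  if (!is.null(beta_sd) && !is.finite(beta_sd))
    stop_param("`beta_sd` must be finite")
  if (excursion_prob < 0 || excursion_prob > 1)
    stop_param("`excursion_prob` must lie in [0, 1]")

  structure(
    list(
      n_individuals = as.integer(n_individuals),
      female_fraction = female_fraction,
      eaf = eaf,
      or_per_allele_female = or_per_allele_female,
      or_per_allele_male = or_per_allele_male,
      baseline_switch_rate = baseline_switch_rate,
      fills_min = as.integer(fills_min),
      fills_mean = fills_mean,
      seed = as.integer(seed),
      eaf2 = eaf2,
      target_r2 = target_r2,
      beta_sd = beta_sd,
      trait_noise_sd = trait_noise_sd,
      excursion_prob = excursion_prob
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  n = %d (%.0f%% female), seed = %d\n",
              x$n_individuals, 100 * x$female_fraction, x$seed))
  cat(sprintf("  variant: EAF = %.3f; OR/allele F = %.2f, M = %.2f; baseline rate = %.2f\n",
              x$eaf, x$or_per_allele_female, x$or_per_allele_male,
              x$baseline_switch_rate))
  if (!is.null(x$eaf2))
    cat(sprintf("  linked variant: EAF2 = %.3f, target r2 = %.2f\n",
                x$eaf2, x$target_r2))
  if (!is.null(x$beta_sd))
    cat(sprintf("  trait: beta = %.2f SD/allele\n", x$beta_sd))
  invisible(x)
}
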