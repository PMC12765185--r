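#' Haplotype frequencies for a two-locus target r-squared
#'
#' Converts a pair of effect-allele frequencies and a target squared
#' correlation into the four haplotype frequencies of a two-locus system,
#' taking the positive-association root `D = +sqrt(r2 p1 q1 p2 q2)`. Fails
#' with an explicit feasibility error (naming the attainable bound) when the
#' implied disequilibrium exceeds the Lewontin bound, i.e. when any
#' haplotype frequency would be negative.
#'
#' @param p1,p2 Effect-allele frequencies of the two variants, in `(0, 1)`.
#' @param r2 Target squared allelic correlation, in `[0, 1]`.
#' @return Named numeric vector of haplotype frequencies
#'   (`h11`, `h10`, `h01`, `h00`), non-negative and summing to 1.
#' @export
#' @examples
#' haplotype_freqs(0.446, 0.446, 0.93)
haplotype_freqs <- function(p1, p2, r2) {
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
    stop_param("allele frequencies must lie strictly inside (0, 1)")
  if (r2 < 0 || r2 > 1) stop_param("`r2` must lie in [0, 1]")
  q1 <- 1 - p1; q2 <- 1 - p2
  d <- sqrt(r2 * p1 * q1 * p2 * q2)
  d_max <- min(p1 * q2, q1 * p2)
  if (d > d_max + 1e-12) {
    r2_max <- d_max^2 / (p1 * q1 * p2 * q2)
    stop_param(paste0(
      "target r2 = %.4g infeasible for p1 = %.4g, p2 = %.4g: ",
      "D = %.4g exceeds the Lewontin bound min(p1*q2, q1*p2) = %.4g ",
      "(maximum attainable r2 with positive D is %.4g)"),
      r2, p1, p2, d, d_max, r2_max)
  }
  d <- min(d, d_max) # clamp roundoff at the exact bound
  h <- c(h11 = p1 * p2 + d, h10 = p1 * q2 - d,
         h01 = q1 * p2 - d, h00 = q1 * q2 + d)
  pmax(h, 0) / sum(pmax(h, 0))
}

check_eaf <- function(eaf, tol = 1e-9) {
  if (!is.numeric(eaf) || length(eaf) != 1 || is.na(eaf) ||
      eaf < tol || eaf > 1 - tol)
    stop_param(
      "`eaf` must lie strictly inside (0, 1) (frequencies within %g of the boundary are degenerate)",
      tol)
}

#' Simulate Hardy-Weinberg genotypes at one biallelic variant
#'
#' Draws effect-allele doses in `{0, 1, 2}` for `n` individuals as two
#' independent Bernoulli allele draws, i.e. genotype frequencies
#' `(1-p)^2, 2p(1-p), p^2` under Hardy-Weinberg equilibrium.
#'
#' @param n Number of individuals.
#' @param eaf Effect-allele frequency, strictly inside `(0, 1)`.
#' @param seed Integer seed; the draw is deterministic given it.
#' @param id Variant identifier used as the dose column name.
#' @return A tibble with columns `person_id` and `<id>` (dose in 0..2).
#' @export
#' @examples
#' g <- simulate_genotypes(1000, eaf = 0.446, seed = 1)
#' mean(g$var1) / 2 # realized allele frequency
simulate_genotypes <- function(n, eaf, seed, id = "var1") {
  check_eaf(eaf)
  if (!is.numeric(n) || n < 1) stop_param("`n` must be >= 1")
  dose <- withr::with_seed(as.integer(seed), rbinom(n, 2L, eaf))
  tibble::tibble(person_id = person_ids(n), !!id := as.integer(dose))
}

person_ids <- function(n) sprintf("P%06d", seq_len(n))

#' Simulate a pair of variants in linkage disequilibrium
#'
#' Samples `2n` haplotypes from the four-class haplotype distribution
#' implied by (`eaf1`, `eaf2`, `target_r2`) (see [haplotype_freqs()]) and
#' forms each individual from two independent chromosomes, so that the
#' squared correlation of the genotype doses approximates `target_r2`.
#'
#' @param n Number of individuals.
#' @param eaf1,eaf2 Effect-allele frequencies of the two variants.
#' @param target_r2 Target squared genotype-dose correlation, in `[0, 1]`.
#' @param seed Integer seed.
#' @param ids Character vector of length 2: variant identifiers.
#' @return A tibble with columns `person_id`, `<ids[1]>`, `<ids[2]>`.
#' @export
#' @examples
#' g <- simulate_linked_pair(5000, 0.446, 0.446, target_r2 = 0.93, seed = 1)
#' ld_r2(g$var1, g$var2)
simulate_linked_pair <- function(n, eaf1, eaf2, target_r2, seed,
                                 ids = c("var1", "var2")) {
  check_eaf(eaf1); check_eaf(eaf2)
  h <- haplotype_freqs(eaf1, eaf2, target_r2)
  # haplotype classes: 1 = (1,1), 2 = (1,0), 3 = (0,1), 4 = (0,0)
  a1 <- c(1L, 1L, 0L, 0L); a2 <- c(1L, 0L, 1L, 0L)
  withr::with_seed(as.integer(seed), {
    hap <- sample.int(4L, 2L * n, replace = TRUE, prob = h)
  })
  m <- matrix(hap, nrow = 2L)
  tibble::tibble(
    person_id = person_ids(n),
    !!ids[1] := a1[m[1, ]] + a1[m[2, ]],
    !!ids[2] := a2[m[1, ]] + a2[m[2, ]]
  )
}

#' Simulate a standardized quantitative trait with an additive genetic effect
#'
#' Generates `trait = beta_sd * (dose - mean(dose)) + e`, with Gaussian
#' noise `e`. By default the residual SD is solved so the trait has unit
#' marginal variance, making `beta_sd` directly interpretable as the
#' per-allele effect in SD units of the trait (the scale on which
#' rank-normalized association effects are reported).
#'
#' @param genotypes Genotype tibble from [simulate_genotypes()] (or any data
#'   frame with a `person_id` column and one dose column), or a bare numeric
#'   dose vector.
#' @param beta_sd Per-allele effect in trait-SD units; finite.
#' @param noise_sd Residual SD. `NULL` (default) solves for unit marginal
#'   trait variance; requires `beta_sd^2 * var(dose) < 1`.
#' @param seed Integer seed.
#' @param dose Column holding the dose when `genotypes` is a data frame;
#'   defaults to the first non-`person_id` column.
#' @return A tibble with columns `person_id` and `trait`.
#' @export
simulate_quantitative_trait <- function(genotypes, beta_sd, noise_sd = NULL,
                                        seed = 1L, dose = NULL) {
  if (!is.finite(beta_sd)) stop_param("`beta_sd` must be finite")
  if (is.data.frame(genotypes)) {
    dose_col <- dose %||% setdiff(names(genotypes), "person_id")[1]
    d <- genotypes[[dose_col]]
    pid <- genotypes$person_id %||% person_ids(nrow(genotypes))
  } else {
    d <- as.numeric(genotypes)
    pid <- person_ids(length(d))
  }
  if (is.null(noise_sd)) {
    resid_var <- 1 - beta_sd^2 * stats::var(d)
    if (resid_var <= 0)
      stop_param("`beta_sd` too large for unit trait variance; supply `noise_sd`")
    noise_sd <- sqrt(resid_var)
  }
  if (noise_sd <= 0) stop_param("`noise_sd` must be > 0")
  e <- withr::with_seed(as.integer(seed), rnorm(length(d), 0, noise_sd))
  tibble::tibble(person_id = pid, trait = beta_sd * (d - mean(d)) + e)
}

# Solve the logistic intercept so the HWE-averaged switch probability at the
# configured allele frequency equals the target population rate.
solve_intercept <- function(rate, log_or, eaf) {
  gw <- c((1 - eaf)^2, 2 * eaf * (1 - eaf), eaf^2)
  f <- function(b0) sum(gw * stats::plogis(b0 + log_or * (0:2))) - rate
  stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
}

#' Simulate the latent layer of a switching cohort
#'
#' Fast path underneath [simulate_switch_cohort()]: draws sex, year of
#' birth, genotype dose(s) and the latent switch indicator from the
#' logistic model `logit P(switch) = b0(sex) + ln(OR_sex) * dose`, without
#' emitting prescription sequences. The sex-specific intercepts are solved
#' numerically so each sex's population-average switch probability equals
#' `baseline_switch_rate` at the configured allele frequency.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `person_id`, `sex` (`"F"`/`"M"`), `yob`,
#'   `var1` (and `var2` when a linked variant is configured), and `switch`
#'   (0/1 latent case indicator).
#' @export
simulate_latent_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  seeds <- derive_seeds(config$seed, 4L)
  if (is.null(config$eaf2)) {
    geno <- simulate_genotypes(n, config$eaf, seed = seeds[1])
  } else {
    geno <- simulate_linked_pair(n, config$eaf, config$eaf2,
                                 config$target_r2, seed = seeds[1])
  }
  b0_f <- solve_intercept(config$baseline_switch_rate,
                          log(config$or_per_allele_female), config$eaf)
  b0_m <- solve_intercept(config$baseline_switch_rate,
                          log(config$or_per_allele_male), config$eaf)
  withr::with_seed(seeds[2], {
    female <- runif(n) < config$female_fraction
    yob <- sample(1930:1990, n, replace = TRUE)
    eta <- ifelse(female,
                  b0_f + log(config$or_per_allele_female) * geno$var1,
                  b0_m + log(config$or_per_allele_male) * geno$var1)
    sw <- rbinom(n, 1L, stats::plogis(eta))
  })
  dplyr::mutate(geno,
                sex = ifelse(female, "F", "M"),
                yob = as.integer(yob),
                switch = as.integer(sw),
                .after = "person_id")
}

# Build prescription fill sequences that the phenotype caller maps back to
# the latent labels exactly. Switchers: >=1 drug-A prefix, then a tail after
# the first B fill with B-fraction >= 0.75. Non-switchers: all A, or a single
# B excursion (post-excursion fills all A, so the tail B-fraction is 0, or
# the tail is empty when the excursion is the last fill).
build_fill_sequences <- function(n_fills, switch, excursion_prob, seed,
                                 drug_a, drug_b) {
  n <- length(n_fills)
  withr::with_seed(as.integer(seed), {
    u_prefix <- runif(n)
    u_taila <- runif(n)
    u_exc <- runif(n)
    u_excpos <- runif(n)
  })
  # switchers: A-prefix length k in 1..(n_fills - 2); first B at k + 1
  k <- 1L + floor(u_prefix * (n_fills - 2L))
  tail_len <- n_fills - k - 1L
  n_tail_a <- floor(u_taila * (floor(0.25 * tail_len) + 1L))
  # non-switcher excursion: single B at position j in 2..n_fills
  j <- 2L + floor(u_excpos * (n_fills - 1L))
  has_exc <- u_exc < excursion_prob

  idx <- rep.int(seq_len(n), n_fills)
  pos <- sequence(n_fills)
  is_sw <- switch[idx] == 1L
  # switcher pattern: A for pos <= k, B after, except n_tail_a trailing A's
  drug <- ifelse(
    is_sw,
    ifelse(pos <= k[idx] | pos > n_fills[idx] - n_tail_a[idx], drug_a, drug_b),
    ifelse(has_exc[idx] & pos == j[idx], drug_b, drug_a)
  )
  list(person_index = idx, position = pos, drug = drug)
}

#' Simulate a full registry-style switching cohort
#'
#' Generates, for each simulated person: a genotype dose (optionally a
#' linked second variant), sex and year of birth, a latent switch indicator
#' drawn from the sex-specific per-allele logistic model, and a prescription
#' fill sequence that the phenotype caller ([call_cohort()]) maps back to
#' the latent label by construction (switch sequences have a drug-A prefix
#' followed by a tail that is at least 75% drug B after the first B fill;
#' non-switch sequences are drug A throughout or contain a brief single-fill
#' excursion to drug B). Fill counts follow a shifted geometric distribution
#' with floor `fills_min`; fills are spaced 30 days apart from a common
#' origin, so dates are strictly increasing within person.
#'
#' @param config A [sim_config()].
#' @param pair A [drug_pair()] giving the ATC codes emitted for drug A and
#'   drug B (defaults: zopiclone N05CF01 / zolpidem N05CF02).
#' @return An object of class `rx_cohort`: a list with elements
#'   `prescriptions` (tibble: `person_id`, `date`, `atc_code`),
#'   `samples` (tibble: `person_id`, `sex`, `yob`),
#'   `genotypes` (tibble: `person_id`, dose columns),
#'   `latent` (tibble incl. the true `switch` label), and `config`.
#' @export
#' @examples
#' coh <- simulate_switch_cohort(sim_config(n_individuals = 300, seed = 42))
#' head(coh$prescriptions)
simulate_switch_cohort <- function(config, pair = drug_pair()) {
  stopifnot(inherits(config, "sim_config"))
  latent <- simulate_latent_cohort(config)
  n <- config$n_individuals
  seeds <- derive_seeds(config$seed, 4L)
  # shifted geometric fill counts with floor fills_min
  p_geom <- 1 / (config$fills_mean - config$fills_min + 1)
  n_fills <- withr::with_seed(seeds[3], {
    config$fills_min + rgeom(n, p_geom)
  })
  seqs <- build_fill_sequences(n_fills, latent$switch, config$excursion_prob,
                               seed = seeds[4],
                               drug_a = pair$drug_a, drug_b = pair$drug_b)
  prescriptions <- tibble::tibble(
    person_id = latent$person_id[seqs$person_index],
    date = as.Date("2003-01-01") + 30L * (seqs$position - 1L),
    atc_code = seqs$drug
  )
  structure(
    list(
      prescriptions = prescriptions,
      samples = dplyr::select(latent, "person_id", "sex", "yob"),
      genotypes = dplyr::select(latent, "person_id",
                                dplyr::any_of(c("var1", "var2"))),
      latent = latent,
      config = config
    ),
    class = "rx_cohort"
  )
}

#' @export
print.rx_cohort <- function(x, ...) {
  cat(sprintf("<rx_cohort> %d individuals, %d prescription fills, seed %d\n",
              x$config$n_individuals, nrow(x$prescriptions), x$config$seed))
  invisible(x)
}
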