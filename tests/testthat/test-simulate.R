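test_that("genotype draws recover the allele frequency and HWE proportions", {
  g <- simulate_genotypes(1e5, eaf = 0.446, seed = 101)$var1
  expect_lt(abs(mean(g) / 2 - 0.446), 0.005)
  g5 <- simulate_genotypes(1e5, eaf = 0.5, seed = 102)$var1
  expect_lt(abs(mean(g5 == 1) - 0.5), 0.01)
})

test_that("HWE goodness of fit holds at n = 1e5 across 20 seeds", {
  for (s in 1:20) {
    d <- simulate_genotypes(1e5, eaf = 0.446, seed = s)$var1
    counts <- as.numeric(table(factor(d, levels = 0:2)))
    p <- mean(d) / 2
    expected <- 1e5 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    x2 <- sum((counts - expected)^2 / expected)
    expect_gt(1 - stats::pchisq(x2, df = 1), 0.001)
  }
})

test_that("degenerate or invalid allele frequencies are rejected", {
  expect_error(simulate_genotypes(100, eaf = 1 - 1e-12, seed = 1),
               class = "rxswitch_parameter_error")
  expect_error(simulate_genotypes(100, eaf = 0, seed = 1),
               class = "rxswitch_parameter_error")
  expect_error(simulate_genotypes(100, eaf = 1.2, seed = 1),
               class = "rxswitch_parameter_error")
})

test_that("haplotype construction hits the target LD and degenerates correctly", {
  g <- simulate_linked_pair(5e4, 0.446, 0.446, target_r2 = 0.93, seed = 11)
  expect_lt(abs(ld_r2(g$var1, g$var2) - 0.93), 0.02)

  g1 <- simulate_linked_pair(2e3, 0.3, 0.3, target_r2 = 1, seed = 12)
  expect_identical(g1$var1, g1$var2)

  g0 <- simulate_linked_pair(1e5, 0.446, 0.446, target_r2 = 0, seed = 13)
  expect_lt(ld_r2(g0$var1, g0$var2), 0.005)
})

test_that("infeasible LD triples fail loudly, naming the bound", {
  expect_error(haplotype_freqs(0.05, 0.9, 0.9), "Lewontin")
  expect_error(simulate_linked_pair(100, 0.05, 0.9, 0.9, seed = 1),
               "infeasible")
  expect_error(sim_config(100, eaf = 0.05, eaf2 = 0.9, target_r2 = 0.9),
               "infeasible")
})

test_that("accepted LD triples always give a valid haplotype distribution", {
  withr::with_seed(5, {
    for (i in 1:200) {
      p1 <- runif(1, 0.05, 0.95); p2 <- runif(1, 0.05, 0.95)
      r2 <- runif(1, 0, 1)
      h <- tryCatch(haplotype_freqs(p1, p2, r2), error = function(e) NULL)
      if (is.null(h)) next
      expect_true(all(h >= 0))
      expect_equal(sum(h), 1, tolerance = 1e-12)
      # marginals are preserved
      expect_equal(h[["h11"]] + h[["h10"]], p1, tolerance = 1e-9)
      expect_equal(h[["h11"]] + h[["h01"]], p2, tolerance = 1e-9)
    }
  })
})

test_that("quantitative trait has the configured effect and unit variance by default", {
  g <- simulate_genotypes(1e4, 0.446, seed = 31)
  tr <- simulate_quantitative_trait(g, beta_sd = 0, seed = 32)
  d <- dplyr::inner_join(g, tr, by = "person_id")
  r <- linear_assoc(d, "var1", "trait", transform = FALSE)
  expect_lt(abs(r$beta), 3 * r$se) # null: slope indistinguishable from 0

  tr2 <- simulate_quantitative_trait(g, beta_sd = -0.25, seed = 33)
  expect_lt(abs(sd(tr2$trait) - 1), 0.05)
  expect_error(simulate_quantitative_trait(g, -0.25, noise_sd = -1, seed = 1),
               class = "rxswitch_parameter_error")
})

test_that("trait point estimate is unbiased regardless of the noise level", {
  g <- simulate_genotypes(2000, 0.446, seed = 41)
  ests <- vapply(1:200, function(s) {
    tr <- simulate_quantitative_trait(g, beta_sd = 0.4, noise_sd = 2, seed = s)
    d <- dplyr::inner_join(g, tr, by = "person_id")
    linear_assoc(d, "var1", "trait", transform = FALSE)$beta
  }, numeric(1))
  # Monte-Carlo oracle: mean of 200 estimates vs truth, 3 MC SE band
  expect_lt(abs(mean(ests) - 0.4), 3 * sd(ests) / sqrt(200))
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(100, eaf = 1.1), class = "rxswitch_parameter_error")
  expect_error(sim_config(100, baseline_switch_rate = 0),
               class = "rxswitch_parameter_error")
  expect_error(sim_config(100, fills_min = 2), class = "rxswitch_parameter_error")
  expect_error(sim_config(100, fills_mean = 2), class = "rxswitch_parameter_error")
  expect_error(sim_config(100, eaf2 = 0.3), "together")
  expect_s3_class(sim_config(100), "sim_config")
})

test_that("cohort generation is byte-deterministic given the config", {
  cfg <- sim_config(800, seed = 77, eaf2 = 0.446, target_r2 = 0.8,
                    beta_sd = -0.25)
  c1 <- simulate_switch_cohort(cfg)
  c2 <- simulate_switch_cohort(cfg)
  expect_identical(c1$prescriptions, c2$prescriptions)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$latent, c2$latent)
  c3 <- simulate_switch_cohort(sim_config(800, seed = 78, eaf2 = 0.446,
                                          target_r2 = 0.8, beta_sd = -0.25))
  expect_false(identical(c1$latent, c3$latent))
})

test_that("fill sequences respect the floor, ordering and decision margins", {
  cfg <- sim_config(2000, seed = 55, fills_min = 3, fills_mean = 8)
  coh <- simulate_switch_cohort(cfg)
  per <- coh$prescriptions |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(n = dplyr::n(), sorted = !is.unsorted(date, strictly = TRUE))
  expect_true(all(per$n >= 3))
  expect_true(all(per$sorted))
  expect_lt(abs(mean(per$n) - 8), 0.5)
  # switchers' tails are bounded away from the 50% boundary (>= 75% B)
  fills <- filter_to_pair(coh$prescriptions)
  tails <- fills |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(frac = {
      fb <- match("B", drug)
      if (is.na(fb) || fb == dplyr::n()) NA_real_
      else mean(drug[(fb + 1):dplyr::n()] == "B")
    })
  sw <- dplyr::inner_join(tails, coh$latent, by = "person_id")
  expect_true(all(sw$frac[sw$switch == 1] >= 0.75))
  expect_true(all(is.na(sw$frac[sw$switch == 0]) | sw$frac[sw$switch == 0] <= 0.25))
})

test_that("phenotype caller recovers every latent label (round trip)", {
  cfg <- sim_config(5000, seed = 61)
  coh <- simulate_switch_cohort(cfg)
  calls <- call_cohort(coh)
  m <- calls |>
    dplyr::filter(direction == "ab", status %in% c("case", "control")) |>
    dplyr::inner_join(coh$latent, by = "person_id")
  expect_equal(nrow(m), 5000) # everyone eligible and an A-starter
  expect_true(all((m$status == "case") == (m$switch == 1)))
})

test_that("population switch rate matches the configured anchor", {
  cfg <- sim_config(1e5, seed = 71, baseline_switch_rate = 0.14)
  lat <- simulate_latent_cohort(cfg)
  expect_lt(abs(mean(lat$switch) - 0.14), 0.005)
  for (sx in c("F", "M"))
    expect_lt(abs(mean(lat$switch[lat$sex == sx]) - 0.14), 0.01)
})

test_that("a null genetic effect leaves case status independent of dose", {
  cfg <- sim_config(1e5, seed = 81, or_per_allele_female = 1,
                    or_per_allele_male = 1)
  lat <- simulate_latent_cohort(cfg)
  p <- stats::chisq.test(table(lat$var1, lat$switch))$p.value
  expect_gt(p, 0.01)
})

test_that("a huge effect saturates carriers under the population-rate anchor", {
  cfg <- sim_config(4e4, seed = 91, or_per_allele_female = 1000,
                    or_per_allele_male = 1000, baseline_switch_rate = 0.14)
  lat <- simulate_latent_cohort(cfg)
  rate_by_dose <- tapply(lat$switch, lat$var1, mean)
  # non-carriers essentially never switch; homozygotes absorb nearly the
  # whole population rate (0.14 / P(dose = 2) at this allele frequency)
  expect_lt(rate_by_dose[["0"]], 0.01)
  expect_gt(rate_by_dose[["2"]], 0.6)
  expect_lt(abs(rate_by_dose[["2"]] - 0.14 / mean(lat$var1 == 2)), 0.05)
})
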