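test_that("logistic regression on a binary dose equals the closed-form 2x2 OR", {
  # exposed cases / unexposed cases / exposed controls / unexposed controls
  a <- 40; b <- 25; c <- 160; d <- 175
  data <- tibble::tibble(
    dose = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    status = c(rep("case", a + b), rep("control", c + d))
  )
  fit <- logistic_assoc(data, "dose", "status")
  closed <- or_from_counts(a, b, c, d)
  expect_equal(fit$or, closed$or, tolerance = 1e-6)
  expect_equal(fit$beta, log(a * d / (b * c)), tolerance = 1e-6)
  # Woolf SE is the Wald SE of the saturated 2x2 logistic fit
  expect_equal(fit$se, sqrt(1 / a + 1 / b + 1 / c + 1 / d), tolerance = 1e-6)
})

test_that("or_from_counts has the right symmetries and zero-cell handling", {
  sym <- or_from_counts(12, 12, 12, 12)
  expect_equal(sym$or, 1)
  f <- or_from_counts(30, 10, 20, 40)
  swapped <- or_from_counts(20, 40, 30, 10) # rows exchanged
  expect_equal(swapped$or, 1 / f$or, tolerance = 1e-12)
  z <- or_from_counts(5, 0, 10, 20)
  expect_match(z$note, "haldane")
  expect_true(is.finite(z$or) && is.finite(z$se))
  expect_error(or_from_counts(-1, 2, 3, 4), class = "rxswitch_parameter_error")
})

test_that("separation is flagged, not thrown", {
  d <- tibble::tibble(dose = rep(c(0, 2), each = 20),
                      status = rep(c("control", "case"), each = 20))
  r <- logistic_assoc(d, "dose", "status")
  expect_equal(r$note, "possible_separation")
})

test_that("flipping the effect allele negates beta and inverts the OR", {
  lat <- simulate_latent_cohort(sim_config(3000, seed = 12))
  r1 <- logistic_assoc(lat, "var1", "switch")
  lat$flipped <- 2 - lat$var1
  r2 <- logistic_assoc(lat, "flipped", "switch")
  expect_equal(r2$beta, -r1$beta, tolerance = 1e-9)
  expect_equal(r2$or, 1 / r1$or, tolerance = 1e-9)
  expect_equal(r2$se, r1$se, tolerance = 1e-9)
})

test_that("sex-difference z-test: identity, refusal, and CI reconstruction", {
  f <- tibble::tibble(beta = 0.3, se = 0.05, stratum = "F")
  m <- tibble::tibble(beta = 0.3, se = 0.07, stratum = "M")
  same <- sex_difference_test(f, m |> dplyr::mutate(beta = 0.3))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_error(sex_difference_test(f, f), "disjoint")

  # strata SEs reconstructed from published-style 95% CIs: se = ln(U/L)/3.92
  z975 <- 2 * qnorm(0.975)
  fem <- tibble::tibble(beta = log(1.36), se = log(1.44 / 1.29) / z975,
                        stratum = "F")
  mal <- tibble::tibble(beta = log(1.19), se = log(1.27 / 1.11) / z975,
                        stratum = "M")
  res <- sex_difference_test(fem, mal)
  expect_equal(res$z, 3.010393, tolerance = 1e-5)
  expect_equal(res$p, 0.0026091, tolerance = 1e-4)
})

test_that("conditioning on an independent variant leaves the estimate unchanged", {
  cfg <- sim_config(20000, seed = 14, eaf2 = 0.446, target_r2 = 0)
  lat <- simulate_latent_cohort(cfg)
  unc <- logistic_assoc(lat, "var1", "switch")
  con <- conditional_assoc(lat, "var1", "var2", "switch", type = "logistic")
  expect_lt(abs(con$beta - unc$beta), 0.5 * unc$se)
  expect_match(con$note, "conditioned_on=var2")
  expect_equal(con$model, "conditional_logistic")
})

test_that("collinear conditioning fails with a named collinearity error", {
  lat <- simulate_latent_cohort(sim_config(500, seed = 15))
  expect_error(conditional_assoc(lat, "var1", "var1", "switch"), "itself")
  lat$copy <- lat$var1
  expect_error(conditional_assoc(lat, "var1", "copy", "switch"), "collinear")
})

test_that("two correlated causal signals remain separable by conditioning", {
  # variant 1 drives switching; variant 2 (r2 = 0.93 with it) does not.
  # Analytic oracle for the conditional Wald power at alpha = 0.01:
  # z = ln(OR) * sqrt(n * 2pq(1-r2) * mu(1-mu)), power = Phi(z - z_{.995}).
  n <- 40000; p <- 0.446; mu <- 0.14; or <- 1.29; r2 <- 0.93
  z_mean <- log(or) * sqrt(n * 2 * p * (1 - p) * (1 - r2) * mu * (1 - mu))
  power <- pnorm(z_mean - qnorm(0.995))
  n_rep <- 60
  sig <- vapply(1:n_rep, function(s) {
    cfg <- sim_config(n, eaf = p, eaf2 = p, target_r2 = r2,
                      or_per_allele_female = or, or_per_allele_male = or,
                      baseline_switch_rate = mu, seed = s)
    lat <- simulate_latent_cohort(cfg)
    conditional_assoc(lat, "var1", "var2", "switch", type = "logistic")$p < 0.01
  }, logical(1))
  mc_se <- sqrt(power * (1 - power) / n_rep)
  expect_lt(abs(mean(sig) - power), 3 * mc_se)
  expect_gt(mean(sig), 0.5) # the adjusted signal survives in most runs
})

test_that("rank-inverse-normal transform is rank-invariant and Blom-exact", {
  x <- c(3.2, 1.1, 5.9, 2.4, 4.0)
  # direct formula evaluation as the oracle
  blom <- qnorm((rank(x) - 0.375) / (length(x) + 0.25))
  expect_equal(rank_inverse_normal(x), blom, tolerance = 1e-12)
  expect_equal(rank_inverse_normal(exp(x)), rank_inverse_normal(x)) # monotone map
  expect_error(rank_inverse_normal(rep(1, 5)), "distinct")
  expect_error(rank_inverse_normal(c(1, NA)), class = "rxswitch_parameter_error")
  y <- withr::with_seed(1, rexp(5000))
  z <- rank_inverse_normal(y)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sd(z) - 1), 0.01)
  # ties get the average rank
  expect_equal(rank_inverse_normal(c(1, 1, 2))[1],
               rank_inverse_normal(c(1, 1, 2))[2])
})

test_that("linear association: null under orthogonalized dose, covariate stability", {
  g <- simulate_genotypes(4000, 0.446, seed = 16)
  tr <- simulate_quantitative_trait(g, beta_sd = -0.3, seed = 17)
  d <- dplyr::inner_join(g, tr, by = "person_id")
  # residualize the dose against the trait: association must vanish
  d$ortho <- stats::resid(lm(var1 ~ trait, data = d))
  r0 <- linear_assoc(d, "ortho", "trait", transform = FALSE)
  expect_lt(abs(r0$beta), 3 * r0$se)
  # an irrelevant covariate barely moves the estimate
  r1 <- linear_assoc(d, "var1", "trait")
  d$noise <- withr::with_seed(18, rnorm(nrow(d)))
  r2 <- linear_assoc(d, "var1", "trait", covariates = "noise")
  expect_lt(abs(r2$beta - r1$beta), 2 * r1$se)
})

test_that("ld_r2 is the squared dose correlation with sane degenerate handling", {
  v <- c(0, 1, 2, 1, 0, 2)
  expect_equal(ld_r2(v, v), 1)
  expect_error(ld_r2(v, rep(1, 6)), "non-constant")
  expect_error(ld_r2(v, v[-1]), "lengths")
  a <- simulate_genotypes(1e5, 0.4, seed = 19)$var1
  b <- simulate_genotypes(1e5, 0.4, seed = 20)$var1
  expect_lt(ld_r2(a, b), 0.005)
})

test_that("EAF and exact HWE test behave on canonical inputs", {
  het <- rep(1, 100)
  r <- eaf_and_hwe(het)
  expect_equal(r$eaf, 0.5)
  expect_lt(r$hwe_p, 1e-10) # all-heterozygote: maximal HWE violation
  expect_error(eaf_and_hwe(numeric(0)), class = "rxswitch_parameter_error")
  g <- simulate_genotypes(1e5, 0.446, seed = 21)$var1
  r2 <- eaf_and_hwe(g)
  expect_lt(abs(r2$eaf - 0.446), 0.005)
  expect_gt(r2$hwe_p, 0.001)
  # dosages: EAF only
  rd <- eaf_and_hwe(c(0.1, 1.4, 1.9))
  expect_false(rd$hard_calls)
  expect_true(is.na(rd$hwe_p))
})

test_that("exact HWE mid-p matches an independent enumeration oracle", {
  cases <- list(c(3, 1, 10), c(10, 5, 40), c(0, 3, 12), c(7, 0, 30))
  for (cs in cases) {
    dose <- rep(c(1, 2, 0), c(cs[1], cs[2], cs[3] - cs[1] - cs[2]))
    expect_equal(eaf_and_hwe(dose)$hwe_p,
                 brute_force_hwe_midp(cs[1], cs[2], cs[3]),
                 tolerance = 1e-10, info = paste(cs, collapse = "/"))
  }
})

test_that("threshold schemes allocate and conserve the alpha budget", {
  # single class reduces to plain Bonferroni
  sc <- threshold_scheme(rep("all", 20))
  expect_equal(sc$thresholds$threshold, 0.05 / 20)
  # 10:1 weights over equal class sizes give 10:1 thresholds
  classes <- rep(c("hi", "lo"), each = 5)
  sc2 <- threshold_scheme(classes, weights = c(hi = 10, lo = 1))
  th <- setNames(sc2$thresholds$threshold, sc2$thresholds$class)
  expect_equal(unname(th["hi"] / th["lo"]), 10)
  expect_equal(sum(sc2$thresholds$n_variants * sc2$thresholds$threshold), 0.05,
               tolerance = 1e-12)
  # random schemes conserve the budget exactly
  withr::with_seed(4, {
    for (i in 1:50) {
      k <- sample(2:5, 1)
      cls <- sample(letters[1:k], sample(5:50, 1), replace = TRUE)
      w <- setNames(runif(k, 0.1, 20), letters[1:k])
      sc <- threshold_scheme(cls, w)
      expect_equal(sum(sc$thresholds$n_variants * sc$thresholds$threshold),
                   0.05, tolerance = 1e-12)
    }
  })
})

test_that("significance annotation is strict and validates classes", {
  sc <- threshold_scheme(rep("all", 10))
  res <- tibble::tibble(variant = c("v1", "v2"), p = c(0.05 / 10, 0.05 / 10 - 1e-9))
  out <- apply_threshold_scheme(res, sc)
  expect_false(out$significant[1]) # p exactly at the threshold: not significant
  expect_true(out$significant[2])
  res$class <- c("all", "unknown")
  expect_error(apply_threshold_scheme(res, sc), "unknown")
})

test_that("strata need both outcome classes and non-constant dose", {
  lat <- simulate_latent_cohort(sim_config(200, seed = 23))
  lat$switch <- 0L
  expect_error(logistic_assoc(lat, "var1", "switch"), "case")
  lat2 <- simulate_latent_cohort(sim_config(200, seed = 24))
  lat2$var1 <- 1L
  expect_error(logistic_assoc(lat2, "var1", "switch"), "variance")
})
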