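#' @importFrom generics tidy
#' @export
generics::tidy

# assemble a one-row AssociationResult tibble on a common layout
assoc_row <- function(variant, stratum, model, beta, se, p, n,
                      n_cases = NA_integer_, n_controls = NA_integer_,
                      note = "") {
  z <- qnorm(0.975)
  logistic <- model %in% c("logistic", "conditional_logistic")
  tibble::tibble(
    variant = variant, stratum = stratum, model = model,
    beta = beta, se = se,
    ci_low = beta - z * se, ci_high = beta + z * se,
    p = p,
    or = if (logistic) exp(beta) else NA_real_,
    or_low = if (logistic) exp(beta - z * se) else NA_real_,
    or_high = if (logistic) exp(beta + z * se) else NA_real_,
    n = as.integer(n), n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls), note = note
  )
}

prep_assoc_data <- function(data, dose, outcome, covariates, stratum) {
  cols <- c(dose, outcome, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0)
    stop_param("`data` lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (!is.null(stratum)) {
    if (!"sex" %in% names(data))
      stop_param("stratum filtering requires a `sex` column")
    data <- dplyr::filter(data, .data$sex == stratum)
    covariates <- setdiff(covariates, "sex")
  }
  keep <- stats::complete.cases(data[, cols[cols %in% names(data)], drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warn(sprintf("dropping %d sample(s) with missing values (complete-case)",
                 n_dropped))
  list(data = data[keep, , drop = FALSE], covariates = covariates)
}

#' Additive-model logistic association for a case/control phenotype
#'
#' Fits maximum-likelihood logistic regression of case status on the
#' effect-allele dose (additive coding: 0/1/2 or dosage), optionally with
#' covariates and restricted to one sex stratum. Reports the Wald per-allele
#' log-odds ratio with its SE, 95% CI, two-sided p value, and the
#' odds-ratio scale. Missing values are handled complete-case per variant.
#' Quasi-separation (non-convergence or an exploding standard error) is
#' flagged in the `note` column rather than raised as an error.
#'
#' @param data Data frame with one row per person, holding the dose column,
#'   the status column and any covariates.
#' @param dose Name of the dose column (values in `[0, 2]`).
#' @param status Name of the case indicator column: logical, 0/1, or
#'   `"case"`/`"control"` strings (anything else is an error).
#' @param covariates Character vector of covariate column names (default
#'   none; `c("sex", "yob")` is a typical registry adjustment set).
#' @param stratum Optional sex stratum label (`"F"` or `"M"`) to restrict
#'   to; `sex` is then dropped from the covariates.
#' @param variant Variant id recorded in the result.
#' @return One-row tibble (see `assoc_row` layout): `variant`, `stratum`,
#'   `model`, `beta` (log-OR per allele), `se`, `ci_low`, `ci_high`, `p`,
#'   `or`, `or_low`, `or_high`, `n`, `n_cases`, `n_controls`, `note`.
#' @export
#' @examples
#' d <- data.frame(dose = rbinom(500, 2, 0.4))
#' d$status <- rbinom(500, 1, plogis(-1 + 0.3 * d$dose))
#' logistic_assoc(d, "dose", "status")
logistic_assoc <- function(data, dose, status, covariates = NULL,
                           stratum = NULL, variant = dose) {
  pd <- prep_assoc_data(data, dose, status, covariates, stratum)
  d <- pd$data
  y <- as_case_indicator(d[[status]])
  n_cases <- sum(y == 1); n_controls <- sum(y == 0)
  if (n_cases < 1 || n_controls < 1)
    stop_param("stratum has %d case(s) and %d control(s); need at least one of each",
               n_cases, n_controls)
  if (stats::var(d[[dose]]) == 0)
    stop_param("dose `%s` has zero variance in this stratum", dose)
  form <- stats::reformulate(c(dose, pd$covariates), response = ".y")
  d$.y <- y
  fit <- suppressWarnings(glm(form, data = d, family = binomial(),
                              control = stats::glm.control(epsilon = 1e-12,
                                                           maxit = 50)))
  b <- coef(fit)[[dose]]
  se <- sqrt(vcov(fit)[dose, dose])
  note <- ""
  if (!fit$converged || se > 10 || abs(b) > 10)
    note <- "possible_separation"
  assoc_row(variant, stratum %||% "all", "logistic",
            beta = b, se = se, p = 2 * pnorm(-abs(b / se)),
            n = nrow(d), n_cases = n_cases, n_controls = n_controls,
            note = note)
}

as_case_indicator <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x) && all(x %in% c(0, 1))) return(as.integer(x))
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    if (all(x %in% c("case", "control")))
      return(as.integer(x == "case"))
  }
  stop_param("case status must be logical, 0/1, or 'case'/'control'")
}

#' Odds ratio from a 2x2 contingency table
#'
#' Cross-product odds ratio `ad/bc` with the Woolf standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` on the log scale and a 95% Wald CI. Any
#' zero cell triggers the Haldane-Anscombe 0.5 continuity correction to
#' every cell, flagged in `note`.
#'
#' @param a,b,c,d Cell counts: `a`/`b` are exposed/unexposed cases, `c`/`d`
#'   exposed/unexposed controls (all non-negative).
#' @param variant Label recorded in the result.
#' @return One-row association tibble with the OR scale filled in.
#' @export
#' @examples
#' # female-vs-male odds of switching, from published cohort counts
#' or_from_counts(3546, 2280, 21074, 15218)
or_from_counts <- function(a, b, c, d, variant = "2x2") {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || anyNA(cells)) stop_param("counts must be non-negative")
  note <- ""
  if (any(cells == 0)) {
    cells <- cells + 0.5
    note <- "haldane_anscombe_correction"
  }
  beta <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  assoc_row(variant, "all", "logistic",
            beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
            n = sum(round(c(a, b, c, d))),
            n_cases = round(a + b), n_controls = round(c + d), note = note)
}

#' Compare per-allele effects between two independent strata
#'
#' Two-sample z-test for a difference in log-odds ratios (or linear betas)
#' estimated in disjoint strata, the standard heterogeneity test for
#' sex-stratified GWAS effects: `z = (b1 - b2) / sqrt(se1^2 + se2^2)`,
#' two-sided normal p value. Refuses overlapping strata, where the
#' independence assumption fails.
#'
#' @param result_1,result_2 One-row association tibbles (e.g. the female
#'   and male strata from [logistic_assoc()]).
#' @return One-row tibble: `stratum_1`, `stratum_2`, `beta_diff`,
#'   `se_diff`, `z`, `p`.
#' @export
#' @examples
#' f <- data.frame(beta = log(1.36), se = log(1.44 / 1.29) / (2 * qnorm(.975)),
#'                 stratum = "F")
#' m <- data.frame(beta = log(1.19), se = log(1.27 / 1.11) / (2 * qnorm(.975)),
#'                 stratum = "M")
#' sex_difference_test(f, m)
sex_difference_test <- function(result_1, result_2) {
  for (r in list(result_1, result_2))
    if (!all(c("beta", "se") %in% names(r)) || nrow(r) != 1)
      stop_param("each result must be a one-row tibble with `beta` and `se`")
  s1 <- result_1$stratum %||% "stratum1"
  s2 <- result_2$stratum %||% "stratum2"
  if (identical(s1, s2))
    stop_param("strata must be disjoint (both results are for stratum '%s'); a z-test on overlapping samples is invalid", s1)
  bd <- result_1$beta - result_2$beta
  sed <- sqrt(result_1$se^2 + result_2$se^2)
  z <- bd / sed
  tibble::tibble(stratum_1 = s1, stratum_2 = s2,
                 beta_diff = bd, se_diff = sed, z = z,
                 p = 2 * pnorm(-abs(z)))
}

#' Conditional association adjusting for other variant(s)
#'
#' Re-tests a target variant with one or more conditioning variants' doses
#' included as covariates, the standard way to ask whether two correlated
#' association signals at a locus are distinct. Errors on exact
#' collinearity (r-squared of 1 between target and a conditioner, including
#' conditioning a variant on itself), naming the offending pair.
#'
#' @param data Data frame holding target dose, conditioning dose(s),
#'   outcome and covariates.
#' @param dose Target variant dose column.
#' @param condition_on Character vector of conditioning dose column(s);
#'   must be distinct from `dose`.
#' @param outcome Outcome column: case status for `type = "logistic"`,
#'   numeric trait for `type = "linear"`.
#' @param covariates,stratum As in [logistic_assoc()].
#' @param type `"logistic"` or `"linear"`.
#' @param transform For the linear model, rank-inverse-normal transform the
#'   trait first (see [rank_inverse_normal()]).
#' @return One-row association tibble; `model` is
#'   `"conditional_logistic"` or `"conditional_linear"`.
#' @export
conditional_assoc <- function(data, dose, condition_on, outcome,
                              covariates = NULL, stratum = NULL,
                              type = c("logistic", "linear"),
                              transform = TRUE) {
  type <- match.arg(type)
  if (dose %in% condition_on)
    stop_param("cannot condition variant `%s` on itself", dose)
  for (cv in condition_on) {
    r2 <- ld_r2(data[[dose]], data[[cv]])
    if (r2 > 1 - 1e-10)
      stop_param("target `%s` and conditioning variant `%s` are collinear (r2 = 1); their signals cannot be separated",
                 dose, cv)
  }
  res <- if (type == "logistic") {
    logistic_assoc(data, dose, outcome,
                   covariates = c(condition_on, covariates),
                   stratum = stratum, variant = dose)
  } else {
    linear_assoc(data, dose, outcome,
                 covariates = c(condition_on, covariates),
                 stratum = stratum, transform = transform, variant = dose)
  }
  dplyr::mutate(
    res,
    model = paste0("conditional_", type),
    or = if (type == "logistic") .data$or else NA_real_,
    note = paste0(.data$note,
                  ifelse(nzchar(.data$note), ";", ""),
                  "conditioned_on=", paste(condition_on, collapse = "+"))
  )
}

#' Rank-based inverse-normal transform (Blom scores)
#'
#' Replaces values by normal quantiles of their ranks,
#' `qnorm((rank - 3/8) / (n + 1/4))`, with ties given the average rank.
#' The result is invariant to any strictly monotone transform of the input
#' and has mean approximately 0 and SD approximately 1, so downstream
#' regression effects are in SD units.
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' rank_inverse_normal(c(3.2, 1.1, 5.9, 2.4, 4.0))
rank_inverse_normal <- function(values) {
  if (!is.numeric(values)) stop_param("`values` must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stop_param("`values` must be finite and non-missing")
  if (length(unique(values)) < 2)
    stop_param("rank-inverse-normal transform needs >= 2 distinct values")
  r <- rank(values, ties.method = "average")
  qnorm((r - 0.375) / (length(values) + 0.25))
}

#' Linear association for a quantitative trait
#'
#' Ordinary least squares of a (by default rank-inverse-normal transformed)
#' trait on the effect-allele dose, with optional covariates and sex
#' stratum. With the transform on, the per-allele effect is in SD units of
#' the trait. The transform is applied to the pooled (post-stratum) sample;
#' use `transform_by` to rank-normalize within groups (e.g. per sex)
#' instead.
#'
#' @param data Data frame with dose, trait and covariate columns.
#' @param dose Dose column name.
#' @param trait Trait column name (finite numeric).
#' @param covariates,stratum,variant As in [logistic_assoc()].
#' @param transform Apply [rank_inverse_normal()] to the trait (default on).
#' @param transform_by Optional grouping column for a within-group
#'   transform.
#' @return One-row association tibble; `model` is `"linear"`, `beta` in SD
#'   units when `transform = TRUE`.
#' @export
linear_assoc <- function(data, dose, trait, covariates = NULL,
                         stratum = NULL, transform = TRUE,
                         transform_by = NULL, variant = dose) {
  pd <- prep_assoc_data(data, dose, trait, covariates, stratum)
  d <- pd$data
  if (nrow(d) <= length(pd$covariates) + 2)
    stop_param("need n > number of covariates + 2")
  y <- d[[trait]]
  if (!all(is.finite(y))) stop_param("trait contains non-finite values")
  if (isTRUE(transform)) {
    if (!is.null(transform_by)) {
      y <- unsplit(lapply(split(y, d[[transform_by]]), rank_inverse_normal),
                   d[[transform_by]])
    } else {
      y <- rank_inverse_normal(y)
    }
  }
  d$.y <- y
  form <- stats::reformulate(c(dose, pd$covariates), response = ".y")
  fit <- lm(form, data = d)
  b <- coef(fit)[[dose]]
  se <- sqrt(vcov(fit)[dose, dose])
  # Wald normal p, the GWAS convention (df are large in any realistic cohort)
  assoc_row(variant, stratum %||% "all", "linear",
            beta = b, se = se, p = 2 * pnorm(-abs(b / se)), n = nrow(d))
}

#' Composite linkage disequilibrium between two variants
#'
#' Squared Pearson correlation of genotype doses — the composite LD
#' r-squared, which requires no phasing and equals the allelic r-squared
#' under Hardy-Weinberg equilibrium.
#'
#' @param dose1,dose2 Numeric dose vectors over the same persons, both
#'   non-constant.
#' @return r-squared in `[0, 1]`.
#' @export
#' @examples
#' g <- simulate_linked_pair(2000, 0.4, 0.4, 0.8, seed = 3)
#' ld_r2(g$var1, g$var2)
ld_r2 <- function(dose1, dose2) {
  if (length(dose1) != length(dose2))
    stop_param("dose vectors must cover the same persons (lengths %d vs %d)",
               length(dose1), length(dose2))
  if (stats::var(dose1) == 0 || stats::var(dose2) == 0)
    stop_param("both dose vectors must be non-constant")
  cor(dose1, dose2)^2
}

#' Effect-allele frequency and Hardy-Weinberg exact test
#'
#' EAF is half the mean dose. For hard genotype calls (all doses in
#' `{0, 1, 2}`), a mid-p exact Hardy-Weinberg test is computed by
#' enumerating the conditional distribution of the heterozygote count given
#' the allele counts; for fractional dosages only the EAF is returned
#' (`hwe_p = NA`).
#'
#' @param dose Numeric dose vector in `[0, 2]`, non-empty.
#' @return One-row tibble: `eaf`, `n`, `n_het`, `hwe_p`, `hard_calls`.
#' @export
#' @examples
#' eaf_and_hwe(simulate_genotypes(5000, 0.446, seed = 1)$var1)
eaf_and_hwe <- function(dose) {
  if (length(dose) == 0) stop_param("`dose` is empty")
  if (anyNA(dose)) {
    warn(sprintf("dropping %d missing dose(s)", sum(is.na(dose))))
    dose <- dose[!is.na(dose)]
    if (length(dose) == 0) stop_param("`dose` is empty after dropping missing")
  }
  if (any(dose < 0 | dose > 2)) stop_param("doses must lie in [0, 2]")
  eaf <- mean(dose) / 2
  hard <- all(dose %in% c(0, 1, 2))
  n_het <- if (hard) sum(dose == 1) else NA_integer_
  hwe_p <- if (hard) hwe_exact_midp(sum(dose == 1), sum(dose == 2),
                                    length(dose)) else NA_real_
  tibble::tibble(eaf = eaf, n = length(dose), n_het = n_het,
                 hwe_p = hwe_p, hard_calls = hard)
}

# Exact Hardy-Weinberg test: conditional distribution of the heterozygote
# count given minor-allele count, enumerated on the log scale; mid-p =
# P(less probable than observed) + 0.5 * P(equally probable).
hwe_exact_midp <- function(n_het, n_hom_alt, n_total) {
  n_minor <- min(n_het + 2 * n_hom_alt, n_het + 2 * (n_total - n_het - n_hom_alt))
  if (n_minor == 0) return(1)
  hets <- seq.int(n_minor %% 2, n_minor, by = 2)
  # P(het = h | n_minor, n) on log scale (Levene's conditional distribution)
  log_p <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n_total - h - hom_min
    lgamma(n_total + 1) - lgamma(h + 1) - lgamma(hom_min + 1) -
      lgamma(hom_maj + 1) + h * log(2) +
      lgamma(n_minor + 1) + lgamma(2 * n_total - n_minor + 1) -
      lgamma(2 * n_total + 1)
  }, numeric(1))
  p <- exp(log_p - max(log_p)); p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  sum(p[p < obs - 1e-12]) + 0.5 * sum(p[abs(p - obs) <= 1e-12])
}
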