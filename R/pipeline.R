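#' Configure an end-to-end pipeline run
#'
#' A run takes exactly one input mode: either a [sim_config()] (synthetic
#' cohort) or paths to real registry files (prescriptions TSV; sample sheet
#' TSV; genotypes as VCF or dosage TSV). Supplying both, or neither, is a
#' validation error.
#'
#' @param sim Optional [sim_config()].
#' @param rx_file,samples_file,geno_file Optional paths to prescription,
#'   sample-sheet and genotype files (all three required for the real-data
#'   mode; `geno_file` ending in `.vcf` is read as VCF, otherwise as a
#'   dosage TSV).
#' @param pair A [drug_pair()].
#' @param covariates Covariate columns for the regressions (taken from the
#'   sample sheet; default sex and year of birth).
#' @param stratify_sex Also fit per-sex strata and the between-sex
#'   difference test.
#' @param condition_on Optional conditioning variant id: each other variant
#'   is additionally tested adjusted for it.
#' @param trait Optional trait column name present in the sample sheet (or
#'   simulated when `sim$beta_sd` is set): adds a rank-normalized linear
#'   association.
#' @param scheme A [threshold_scheme()] or `NULL` for plain Bonferroni over
#'   the tested variants.
#' @param out_dir Optional directory; when set, [run_pipeline()] writes the
#'   phenotype TSV, summary-stats TSV and JSON report there.
#' @param seed Seed recorded in every output header; defaults to the
#'   simulation config's seed (or 1 in real-data mode).
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = NULL, rx_file = NULL, samples_file = NULL,
                       geno_file = NULL, pair = drug_pair(),
                       covariates = c("sex", "yob"), stratify_sex = TRUE,
                       condition_on = NULL, trait = NULL, scheme = NULL,
                       out_dir = NULL, seed = NULL) {
  real <- !is.null(rx_file) || !is.null(samples_file) || !is.null(geno_file)
  if (!is.null(sim) && real)
    stop_param("supply either `sim` or real input files, not both")
  if (is.null(sim) && !real)
    stop_param("supply either `sim` or real input files")
  if (real && (is.null(rx_file) || is.null(samples_file) || is.null(geno_file)))
    stop_param("real-data mode needs `rx_file`, `samples_file` and `geno_file`")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(
    list(sim = sim, rx_file = rx_file, samples_file = samples_file,
         geno_file = geno_file, pair = pair, covariates = covariates,
         stratify_sex = isTRUE(stratify_sex), condition_on = condition_on,
         trait = trait, scheme = scheme, out_dir = out_dir,
         # provenance seed defaults to the simulation's own
         seed = as.integer(seed %||% sim$seed %||% 1L)),
    class = "run_config"
  )
}

#' Run the full pipeline: cohort in, phenotypes and association results out
#'
#' Orchestrates simulation (or file loading), phenotype calling for both
#' switching directions, per-variant additive logistic association (overall
#' and, optionally, per sex with the between-sex difference test),
#' optional conditional analysis and quantitative-trait association, and
#' class-weighted significance annotation. Deterministic given the
#' configuration and seed. When `out_dir` is set, writes `phenotypes.tsv`,
#' `summary_stats.tsv` and `report.json`, each with a provenance header.
#'
#' @param config A [run_config()].
#' @return An object of class `rx_run`: list with `calls` (the
#'   [call_cohort()] table), `cohort_summary`, `results` (association
#'   tibble), `sex_difference` (tibble or `NULL`), `trait_results`,
#'   `config`, and `paths` when files were written. [tidy()] returns the
#'   association tibble; [glance()] the per-direction cohort summary.
#' @export
#' @examples
#' run <- run_pipeline(run_config(sim = sim_config(2000, seed = 5)))
#' tidy(run)
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pair <- config$pair

  if (!is.null(config$sim)) {
    cohort <- simulate_switch_cohort(config$sim, pair = pair)
    rx <- cohort$prescriptions
    samples <- cohort$samples
    geno <- cohort$genotypes
    if (!is.null(config$sim$beta_sd)) {
      trait_seed <- derive_seeds(config$sim$seed, 5L)[5]
      tr <- simulate_quantitative_trait(geno, config$sim$beta_sd,
                                        config$sim$trait_noise_sd,
                                        seed = trait_seed)
      samples <- dplyr::left_join(samples, tr, by = "person_id")
      config$trait <- config$trait %||% "trait"
    }
  } else {
    rx <- read_prescriptions(config$rx_file)
    samples <- read_sample_sheet(config$samples_file)
    geno <- if (grepl("\\.vcf(\\.gz)?$", config$geno_file))
      read_genotypes_vcf(config$geno_file) else
      read_dosage_tsv(config$geno_file)
  }

  calls <- call_cohort(rx, pair)
  cohort_summary <- summarize_calls(calls)

  variants <- setdiff(names(geno), "person_id")
  model_data_for <- function(direction) {
    calls |>
      dplyr::filter(.data$direction == !!direction,
                    .data$status %in% c("case", "control")) |>
      dplyr::select("person_id", "status") |>
      dplyr::inner_join(geno, by = "person_id") |>
      dplyr::inner_join(samples, by = "person_id")
  }

  results <- list(); sexdiff <- list()
  for (dir in c("ab", "ba")) {
    md <- model_data_for(dir)
    if (nrow(md) == 0 || length(unique(md$status)) < 2) next
    covs <- intersect(config$covariates, names(md))
    for (v in variants) {
      r_all <- logistic_assoc(md, v, "status", covariates = covs)
      r_all$direction <- dir
      results <- c(results, list(r_all))
      if (config$stratify_sex) {
        r_f <- logistic_assoc(md, v, "status", covariates = covs, stratum = "F")
        r_m <- logistic_assoc(md, v, "status", covariates = covs, stratum = "M")
        r_f$direction <- dir; r_m$direction <- dir
        results <- c(results, list(r_f, r_m))
        sd_row <- sex_difference_test(r_f, r_m)
        sd_row$variant <- v; sd_row$direction <- dir
        sexdiff <- c(sexdiff, list(sd_row))
      }
      if (!is.null(config$condition_on) && v != config$condition_on &&
          config$condition_on %in% variants) {
        r_c <- conditional_assoc(md, v, config$condition_on, "status",
                                 covariates = covs, type = "logistic")
        r_c$direction <- dir
        results <- c(results, list(r_c))
      }
    }
  }
  results <- dplyr::bind_rows(results)

  trait_results <- NULL
  if (!is.null(config$trait) && config$trait %in% names(samples)) {
    td <- dplyr::inner_join(geno, samples, by = "person_id")
    td <- td[is.finite(td[[config$trait]]), , drop = FALSE]
    covs <- intersect(setdiff(config$covariates, config$trait), names(td))
    trait_results <- dplyr::bind_rows(lapply(variants, function(v) {
      r <- linear_assoc(td, v, config$trait, covariates = covs,
                        transform = TRUE)
      r$direction <- "trait"
      r
    }))
    if (!is.null(config$condition_on) && length(variants) > 1) {
      others <- setdiff(variants, config$condition_on)
      cond <- dplyr::bind_rows(lapply(others, function(v) {
        r <- conditional_assoc(td, v, config$condition_on, config$trait,
                               covariates = covs, type = "linear")
        r$direction <- "trait"
        r
      }))
      trait_results <- dplyr::bind_rows(trait_results, cond)
    }
  }

  scheme <- config$scheme %||%
    threshold_scheme(rep("all", length(variants)), c(all = 1))
  main <- dplyr::filter(results, .data$stratum == "all",
                        .data$model == "logistic")
  main <- apply_threshold_scheme(main, scheme)
  results <- dplyr::left_join(
    results,
    main[, c("variant", "direction", "threshold", "significant")],
    by = c("variant", "direction")) |>
    dplyr::mutate(
      # the weighted-Bonferroni call annotates the main analysis only
      threshold = ifelse(.data$stratum == "all" & .data$model == "logistic",
                         .data$threshold, NA_real_),
      significant = ifelse(.data$stratum == "all" & .data$model == "logistic",
                           .data$significant, NA))
  attr(results, "threshold_scheme") <- scheme

  run <- structure(
    list(calls = calls, cohort_summary = cohort_summary, results = results,
         sex_difference = if (length(sexdiff)) dplyr::bind_rows(sexdiff),
         trait_results = trait_results, config = config, paths = NULL),
    class = "rx_run"
  )
  if (!is.null(config$out_dir)) run$paths <- write_run(run, config$out_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(run$config, run$config$seed)
  paths <- c(phenotypes = file.path(dir, "phenotypes.tsv"),
             summary_stats = file.path(dir, "summary_stats.tsv"),
             report = file.path(dir, "report.json"))
  write_tsv_with_header(tibble::as_tibble(run$calls), paths["phenotypes"], hdr)
  write_summary_stats(dplyr::bind_rows(run$results, run$trait_results),
                      paths["summary_stats"], seed = run$config$seed)
  report <- list(
    provenance = list(package = "rxswitch",
                      version = as.character(utils::packageVersion("rxswitch")),
                      seed = run$config$seed,
                      config_hash = rlang::hash(run$config)),
    cohort = list(n_persons = run$cohort_summary$n_persons,
                  by_direction = run$cohort_summary$by_direction),
    results = dplyr::bind_rows(run$results, run$trait_results),
    sex_difference = run$sex_difference
  )
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  paths
}

#' @export
print.rx_run <- function(x, ...) {
  cat("<rx_run>\n")
  s <- x$cohort_summary$by_direction
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %d cases / %d controls (%.1f%% switch)\n",
                s$direction[i], s$n_cases[i], s$n_controls[i], s$switch_pct[i]))
  cat(sprintf("  %d association result(s)\n", nrow(x$results)))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `rx_run`.
#' @param ... Unused.
#' @method tidy rx_run
#' @export
tidy.rx_run <- function(x, ...) {
  tibble::as_tibble(dplyr::bind_rows(x$results, x$trait_results))
}

#' @rdname run_pipeline
#' @method glance rx_run
#' @export
glance.rx_run <- function(x, ...) x$cohort_summary$by_direction

#' Forest-plot table of stratified effects
#'
#' Collects odds ratios with confidence intervals by stratum and switching
#' direction into the row layout of a forest plot, ordered for plotting
#' (direction, then overall/female/male). `autoplot()` draws the plot.
#'
#' @param results Association tibble (e.g. `tidy(run)` or `run$results`)
#'   with logistic rows.
#' @return A tibble of class `rx_forest`: `direction`, `stratum`, `or`,
#'   `or_low`, `or_high`, `n`, `label`.
#' @export
forest_table <- function(results) {
  if (is.null(results) || nrow(results) == 0)
    stop_param("`results` is empty; nothing to tabulate")
  rows <- dplyr::filter(results, .data$model == "logistic")
  if (nrow(rows) == 0) stop_param("no logistic results to tabulate")
  if (!"direction" %in% names(rows)) rows$direction <- "ab"
  out <- rows |>
    dplyr::mutate(stratum = factor(.data$stratum, c("all", "F", "M"))) |>
    dplyr::arrange(.data$variant, .data$direction, .data$stratum) |>
    dplyr::mutate(label = sprintf("%s %s [%s]", .data$variant,
                                  .data$direction, .data$stratum)) |>
    dplyr::select("variant", "direction", "stratum", "or", "or_low",
                  "or_high", "n", "label")
  structure(out, class = c("rx_forest", class(out)))
}

#' @rdname forest_table
#' @param object An `rx_forest` table.
#' @param ... Unused.
#' @method autoplot rx_forest
#' @export
autoplot.rx_forest <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$or_low,
                                          xmax = .data$or_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL,
                  title = "Per-allele switching effects by stratum") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of stratified switching effects
#'
#' Convenience wrapper: [forest_table()] then [autoplot()].
#'
#' @param run An `rx_run` or an association tibble.
#' @return A ggplot object.
#' @export
plot_forest <- function(run) {
  results <- if (inherits(run, "rx_run")) run$results else run
  autoplot(forest_table(results))
}
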