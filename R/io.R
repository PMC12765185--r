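#' Read a prescriptions TSV
#'
#' Expects the columns `person_id`, `date` (ISO-8601), `atc_code`. Lines
#' starting with `#` are treated as provenance comments.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble of prescription records.
#' @export
read_prescriptions <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    person_id = readr::col_character(),
                    date = readr::col_date(format = "%Y-%m-%d"),
                    atc_code = readr::col_character()
                  ))
}

#' Read a sample sheet TSV
#'
#' Expects `person_id` and `sex` columns; any further columns (e.g. `yob`)
#' are kept as covariates.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  s <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("person_id", "sex") %in% names(s)))
    stop_param("sample sheet must have `person_id` and `sex` columns")
  dplyr::mutate(s, person_id = as.character(.data$person_id))
}

#' Read genotype doses from a dosage TSV
#'
#' Variant-major table: one row per variant with columns `variant_id` and
#' one column per person holding the effect-allele dose.
#'
#' @param path Path to a tab-separated file.
#' @return A person-major tibble: `person_id` plus one dose column per
#'   variant.
#' @export
read_dosage_tsv <- function(path) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!"variant_id" %in% names(d))
    stop_param("dosage TSV must have a `variant_id` column")
  d |>
    tidyr::pivot_longer(-"variant_id", names_to = "person_id",
                        values_to = "dose") |>
    tidyr::pivot_wider(names_from = "variant_id", values_from = "dose")
}

#' Read genotype doses from a VCF
#'
#' Extracts effect-allele doses from a VCF 4.x file: the `DS` FORMAT field
#' when present, else hard-call doses from `GT` (count of ALT alleles; the
#' ALT allele is taken as the effect allele). Multiallelic records are
#' rejected.
#'
#' @param path Path to a VCF file.
#' @return A person-major tibble: `person_id` plus one dose column per
#'   variant (named by the VCF ID).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    stop_param("multiallelic VCF records are not supported")
  ids <- vcfR::getID(v)
  ids[is.na(ids)] <- paste0("var", seq_along(ids))[is.na(ids)]
  fmt <- unique(v@gt[, "FORMAT"])
  if (any(grepl("\\bDS\\b", fmt))) {
    dose <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  out <- tibble::as_tibble(t(dose), .name_repair = "minimal")
  names(out) <- ids
  dplyr::bind_cols(tibble::tibble(person_id = colnames(dose)), out)
}

provenance_header <- function(config = NULL, seed = NULL) {
  c(sprintf("# rxswitch %s", as.character(utils::packageVersion("rxswitch"))),
    if (!is.null(seed)) sprintf("# seed: %d", seed),
    if (!is.null(config)) sprintf("# config_hash: %s", rlang::hash(config)))
}

write_tsv_with_header <- function(x, path, header) {
  readr::write_lines(header, path)
  readr::write_lines(readr::format_tsv(x), path, append = TRUE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits the registry-style files for a simulated cohort: a prescriptions
#' TSV (`person_id`, `date`, `atc_code`), a sample sheet TSV (`person_id`,
#' `sex`, `yob`), a variant-major dosage TSV, a minimal VCF 4.2 with `GT`
#' calls on a placeholder contig, and the latent truth table. All files
#' carry a provenance comment header (package version, seed, config hash).
#'
#' @param cohort An `rx_cohort` from [simulate_switch_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rx_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(cohort$config, cohort$config$seed)
  paths <- c(
    prescriptions = file.path(dir, "prescriptions.tsv"),
    samples = file.path(dir, "samples.tsv"),
    dosages = file.path(dir, "dosages.tsv"),
    vcf = file.path(dir, "genotypes.vcf"),
    latent = file.path(dir, "latent_truth.tsv")
  )
  write_tsv_with_header(cohort$prescriptions, paths["prescriptions"], hdr)
  write_tsv_with_header(cohort$samples, paths["samples"], hdr)
  geno <- cohort$genotypes
  dosage <- geno |>
    tidyr::pivot_longer(-"person_id", names_to = "variant_id",
                        values_to = "dose") |>
    tidyr::pivot_wider(names_from = "person_id", values_from = "dose")
  write_tsv_with_header(dosage, paths["dosages"], hdr)
  write_sim_vcf(geno, paths["vcf"])
  write_tsv_with_header(cohort$latent, paths["latent"], hdr)
  invisible(paths)
}

# minimal VCF 4.2 writer for simulated hard calls (GT only, placeholder
# contig, unphased heterozygotes)
write_sim_vcf <- function(genotypes, path) {
  variants <- setdiff(names(genotypes), "person_id")
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rxswitch",
    "##contig=<ID=sim1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$person_id), collapse = "\t")
  )
  body <- vapply(seq_along(variants), function(i) {
    doses <- genotypes[[variants[i]]]
    paste(c("sim1", i, variants[i], "A", "G", ".", "PASS", ".", "GT",
            gt_codes[as.character(doses)]), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write a GWAS summary-statistics TSV
#'
#' Standard summary-stats layout (CHR, POS, ID, EA, OA, EAF, N, BETA, SE,
#' P, OR, CI_L, CI_U, STRATUM, MODEL) with a provenance comment header; any
#' attached threshold scheme is serialized into the header.
#'
#' @param results Association tibble (rows from [logistic_assoc()] /
#'   [linear_assoc()] and friends), optionally annotated by
#'   [apply_threshold_scheme()].
#' @param path Output path.
#' @param eaf Optional named vector of effect-allele frequencies by
#'   variant.
#' @param seed Optional seed recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(results, path, eaf = NULL, seed = NULL) {
  hdr <- provenance_header(seed = seed)
  scheme <- attr(results, "threshold_scheme")
  if (!is.null(scheme)) {
    hdr <- c(hdr, sprintf("# threshold[%s]: weight=%g n=%d threshold=%.3g",
                          scheme$thresholds$class, scheme$thresholds$weight,
                          scheme$thresholds$n_variants,
                          scheme$thresholds$threshold))
  }
  out <- tibble::tibble(
    CHR = "sim1", POS = match(results$variant, unique(results$variant)),
    ID = results$variant, EA = "G", OA = "A",
    EAF = if (is.null(eaf)) NA_real_ else unname(eaf[results$variant]),
    N = results$n, BETA = results$beta, SE = results$se, P = results$p,
    OR = results$or, CI_L = results$or_low, CI_U = results$or_high,
    STRATUM = results$stratum, MODEL = results$model
  )
  if (!is.null(results$significant)) out$SIGNIFICANT <- results$significant
  write_tsv_with_header(out, path, hdr)
  invisible(path)
}
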