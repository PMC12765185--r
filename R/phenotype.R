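#' Define the drug pair and calling parameters
#'
#' The switching phenotype is defined over a pair of ATC codes: drug A (the
#' origin drug of the A-to-B direction) and drug B. `min_fills` is the
#' eligibility floor on the number of study-drug fills, counted over the two
#' drugs combined by default (`per_drug = TRUE` requires `min_fills` fills
#' of a single drug instead). `tail_threshold` is the minimum fraction of
#' drug-B fills, among fills after the first drug-B fill, that defines a
#' consistent switch ("at least" semantics: exactly the threshold counts as
#' a switch).
#'
#' @param drug_a,drug_b ATC codes of the two drugs; must differ. Defaults
#'   are zopiclone (N05CF01) and zolpidem (N05CF02).
#' @param min_fills Minimum study-drug fill count for eligibility (>= 1;
#'   the registry definition uses 3).
#' @param tail_threshold Switch threshold on the post-first-B fill fraction,
#'   in `(0, 1]`.
#' @param per_drug If `TRUE`, `min_fills` applies to each drug separately
#'   (eligible if either drug alone reaches it) instead of to the combined
#'   count.
#' @param tail_includes_first_b If `TRUE`, the first drug-B fill itself is
#'   included in the switch-fraction window; the default excludes it
#'   (fills strictly after the first B fill).
#' @return A list of class `drug_pair`.
#' @export
#' @examples
#' drug_pair()
drug_pair <- function(drug_a = "N05CF01", drug_b = "N05CF02",
                      min_fills = 3L, tail_threshold = 0.5,
                      per_drug = FALSE, tail_includes_first_b = FALSE) {
  if (!nzchar(drug_a) || !nzchar(drug_b) || identical(drug_a, drug_b))
    stop_param("`drug_a` and `drug_b` must be distinct non-empty ATC codes")
  if (min_fills < 1) stop_param("`min_fills` must be >= 1")
  if (tail_threshold <= 0 || tail_threshold > 1)
    stop_param("`tail_threshold` must lie in (0, 1]")
  structure(
    list(drug_a = drug_a, drug_b = drug_b, min_fills = as.integer(min_fills),
         tail_threshold = tail_threshold, per_drug = isTRUE(per_drug),
         tail_includes_first_b = isTRUE(tail_includes_first_b)),
    class = "drug_pair"
  )
}

#' @export
print.drug_pair <- function(x, ...) {
  cat(sprintf("<drug_pair> A = %s, B = %s; min_fills = %d, tail_threshold = %g\n",
              x$drug_a, x$drug_b, x$min_fills, x$tail_threshold))
  invisible(x)
}

#' Restrict prescription records to the study drug pair
#'
#' Drops fills whose ATC code is neither study drug, parses and validates
#' dates, sorts within person by (date, ATC code), and flags persons whose
#' earliest date carries fills of both drugs (first drug undefined).
#'
#' @param records Data frame of prescription fills with columns
#'   `person_id`, `date` (ISO-8601 string or `Date`), `atc_code`. Records
#'   need not be sorted.
#' @param pair A [drug_pair()].
#' @param skip_bad_records If `FALSE` (default), an unparseable date or an
#'   empty `person_id` aborts the run with the offending row numbers; if
#'   `TRUE`, such records are dropped with a warning.
#' @return A tibble with columns `person_id`, `date`, `drug`
#'   (`"A"`/`"B"`), `atc_code`, and `ambiguous_first` (per-person logical),
#'   sorted by person, date and code.
#' @export
filter_to_pair <- function(records, pair = drug_pair(),
                           skip_bad_records = FALSE) {
  stopifnot(is.data.frame(records), inherits(pair, "drug_pair"))
  req <- c("person_id", "date", "atc_code")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0)
    stop_param("`records` lacks column(s): %s", paste(missing_cols, collapse = ", "))
  date_parsed <- if (inherits(records$date, "Date")) records$date else
    as.Date(as.character(records$date), format = "%Y-%m-%d", optional = TRUE)
  bad <- is.na(date_parsed) | is.na(records$person_id) |
    !nzchar(as.character(records$person_id))
  if (any(bad)) {
    lines <- which(bad)
    msg <- sprintf("%d bad prescription record(s) (unparseable date or empty person_id) at row(s): %s",
                   length(lines),
                   paste(utils::head(lines, 10), collapse = ", "))
    if (!skip_bad_records)
      abort(paste0(msg, " (use skip_bad_records = TRUE to drop them)"),
            class = "rxswitch_record_error")
    warn(msg)
  }
  tibble::tibble(
    person_id = as.character(records$person_id),
    date = date_parsed,
    atc_code = as.character(records$atc_code)
  ) |>
    dplyr::filter(!bad, .data$atc_code %in% c(pair$drug_a, pair$drug_b)) |>
    dplyr::mutate(drug = ifelse(.data$atc_code == pair$drug_a, "A", "B")) |>
    dplyr::arrange(.data$person_id, .data$date, .data$atc_code) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(
      ambiguous_first = dplyr::n_distinct(.data$drug[.data$date == .data$date[1]]) > 1
    ) |>
    dplyr::ungroup() |>
    dplyr::select("person_id", "date", "drug", "atc_code", "ambiguous_first")
}

#' Call the switch phenotype on one ordered fill sequence
#'
#' Implements the registry switching definition for one person and one
#' direction. For direction `"ab"` (origin drug A): the person is excluded
#' if the total fill count is below `min_fills` (reason `"min_fills"`), if
#' the earliest-date fills are ambiguous (reason `"ambiguous_first"`), or if
#' the first fill is not drug A (reason `"first_drug"`). Otherwise the
#' person is a control if drug B was never filled, or if the tail — fills
#' strictly after the first drug-B fill — is empty, or if the tail's drug-B
#' fraction is below `tail_threshold`; the person is a case when the tail
#' fraction is at least `tail_threshold`. Direction `"ba"` swaps the drug
#' roles.
#'
#' @param sequence Character vector of fills in time order, each `"A"` or
#'   `"B"` (or the pair's ATC codes).
#' @param pair A [drug_pair()].
#' @param direction `"ab"` (origin A) or `"ba"` (origin B).
#' @param ambiguous_first Logical: were the earliest-date fills mixed?
#' @return One-row tibble: `direction`, `status` (`"case"`, `"control"`,
#'   `"excluded"`), `first_drug`, `n_fills_total`, `n_fills_tail`,
#'   `frac_b_tail` (NA when no tail), `exclusion_reason`.
#' @export
#' @examples
#' call_switch(c("A", "B", "B", "B"))$status # case
#' call_switch(c("A", "B", "A", "A"))$status # control
call_switch <- function(sequence, pair = drug_pair(), direction = c("ab", "ba"),
                        ambiguous_first = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(pair, "drug_pair"))
  seq_ab <- normalize_sequence(sequence, pair)
  # role swap for the reverse direction: origin becomes B
  origin <- if (direction == "ab") "A" else "B"
  dest <- if (direction == "ab") "B" else "A"

  n_total <- length(seq_ab)
  eligible <- if (pair$per_drug) {
    sum(seq_ab == "A") >= pair$min_fills || sum(seq_ab == "B") >= pair$min_fills
  } else {
    n_total >= pair$min_fills
  }
  first_drug <- if (n_total > 0) seq_ab[1] else NA_character_

  res <- function(status, n_tail = NA_integer_, frac = NA_real_, reason = "") {
    tibble::tibble(direction = direction, status = status,
                   first_drug = first_drug, n_fills_total = n_total,
                   n_fills_tail = n_tail, frac_b_tail = frac,
                   exclusion_reason = reason)
  }
  if (!eligible) return(res("excluded", reason = "min_fills"))
  if (isTRUE(ambiguous_first)) return(res("excluded", reason = "ambiguous_first"))
  if (first_drug != origin) return(res("excluded", reason = "first_drug"))

  first_b <- match(dest, seq_ab)
  if (is.na(first_b)) return(res("control", 0L, NA_real_, "never_tried"))
  tail_start <- if (pair$tail_includes_first_b) first_b else first_b + 1L
  tail_fills <- if (tail_start > n_total) character(0) else seq_ab[tail_start:n_total]
  if (length(tail_fills) == 0) return(res("control", 0L, NA_real_, "empty_tail"))
  frac <- mean(tail_fills == dest)
  status <- if (frac >= pair$tail_threshold) "case" else "control"
  res(status, length(tail_fills), frac)
}

normalize_sequence <- function(sequence, pair) {
  s <- as.character(sequence)
  out <- dplyr::case_when(
    s %in% c("A", pair$drug_a) ~ "A",
    s %in% c("B", pair$drug_b) ~ "B",
    TRUE ~ NA_character_
  )
  if (anyNA(out))
    stop_param("sequence contains fills outside the drug pair: %s",
               paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

#' Call switch phenotypes for a whole cohort, both directions
#'
#' Applies [call_switch()] to every person in a prescription stream, for
#' both switching directions. Each eligible person contributes a
#' case/control status only in the direction whose origin drug they started
#' on (first drug partitions the cohort); in the other direction they are
#' excluded with reason `"first_drug"`.
#'
#' @param records Prescription data frame (see [filter_to_pair()]), or an
#'   `rx_cohort` from [simulate_switch_cohort()].
#' @param pair A [drug_pair()].
#' @param skip_bad_records Passed to [filter_to_pair()].
#' @return A tibble of class `rx_calls` with one row per person per
#'   direction (`person_id`, `direction`, `status`, `first_drug`,
#'   `n_fills_total`, `n_fills_tail`, `frac_b_tail`, `exclusion_reason`).
#'   Use [glance()][generics::glance] (or `summary()`) for the cohort
#'   summary: starters, cases, controls, switch percentage and exclusion
#'   counts per direction, under both denominators (eligible starters, and
#'   all persons whose first fill matches the origin drug).
#' @export
call_cohort <- function(records, pair = drug_pair(), skip_bad_records = FALSE) {
  if (inherits(records, "rx_cohort")) records <- records$prescriptions
  fills <- filter_to_pair(records, pair, skip_bad_records = skip_bad_records)

  # Vectorized equivalent of per-person call_switch() (their agreement is
  # asserted in the test suite): per-person sufficient statistics first.
  per_person <- fills |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      n_fills_total = dplyr::n(),
      n_a = sum(.data$drug == "A"),
      n_b = sum(.data$drug == "B"),
      first_drug = .data$drug[1],
      first_b_pos = match("B", .data$drug),
      first_a_pos = match("A", .data$drug),
      ambiguous_first = .data$ambiguous_first[1],
      .groups = "drop"
    )

  call_direction <- function(pp, direction) {
    if (direction == "ab") {
      origin <- "A"; n_dest <- pp$n_b; first_dest_pos <- pp$first_b_pos
    } else {
      origin <- "B"; n_dest <- pp$n_a; first_dest_pos <- pp$first_a_pos
    }
    eligible <- if (pair$per_drug)
      pp$n_a >= pair$min_fills | pp$n_b >= pair$min_fills
    else pp$n_fills_total >= pair$min_fills
    tail_start <- if (pair$tail_includes_first_b) first_dest_pos
                  else first_dest_pos + 1L
    n_tail <- pmax(pp$n_fills_total - tail_start + 1L, 0L)
    n_dest_tail <- if (pair$tail_includes_first_b) n_dest else n_dest - 1L
    frac <- ifelse(n_tail > 0, n_dest_tail / n_tail, NA_real_)

    status <- dplyr::case_when(
      !eligible ~ "excluded",
      pp$ambiguous_first ~ "excluded",
      pp$first_drug != origin ~ "excluded",
      is.na(first_dest_pos) ~ "control",
      n_tail == 0L ~ "control",
      frac >= pair$tail_threshold ~ "case",
      TRUE ~ "control"
    )
    reason <- dplyr::case_when(
      !eligible ~ "min_fills",
      pp$ambiguous_first ~ "ambiguous_first",
      pp$first_drug != origin ~ "first_drug",
      is.na(first_dest_pos) ~ "never_tried",
      n_tail == 0L ~ "empty_tail",
      TRUE ~ ""
    )
    tibble::tibble(
      person_id = pp$person_id,
      direction = direction,
      status = status,
      first_drug = pp$first_drug,
      n_fills_total = pp$n_fills_total,
      n_fills_tail = ifelse(status == "excluded", NA_integer_,
                            ifelse(is.na(first_dest_pos), 0L, n_tail)),
      frac_b_tail = ifelse(status == "excluded", NA_real_, frac),
      exclusion_reason = reason
    )
  }
  calls <- dplyr::bind_rows(call_direction(per_person, "ab"),
                            call_direction(per_person, "ba"))
  structure(calls, class = c("rx_calls", class(calls)), pair = pair)
}

summarize_calls <- function(calls) {
  pair <- attr(calls, "pair")
  by_dir <- calls |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(
      n_cases = sum(.data$status == "case"),
      n_controls = sum(.data$status == "control"),
      n_excluded_min_fills = sum(.data$exclusion_reason == "min_fills"),
      n_excluded_first_drug = sum(.data$exclusion_reason == "first_drug"),
      n_excluded_ambiguous = sum(.data$exclusion_reason == "ambiguous_first"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_starters = .data$n_cases + .data$n_controls,
      switch_pct = 100 * .data$n_cases / .data$n_starters,
      # alternative denominator: anyone whose first fill matched the origin
      # drug, regardless of eligibility (includes the under-min-fills)
      switch_pct_all_first_drug = NA_real_
    )
  # broader denominator needs first_drug of the excluded-short persons too
  origin <- c(ab = "A", ba = "B")
  broad <- calls |>
    dplyr::filter(.data$first_drug == origin[.data$direction]) |>
    dplyr::count(.data$direction, name = "n_first_drug_matches")
  by_dir <- dplyr::left_join(by_dir, broad, by = "direction") |>
    dplyr::mutate(switch_pct_all_first_drug =
                    100 * .data$n_cases / .data$n_first_drug_matches)
  list(
    n_persons = dplyr::n_distinct(calls$person_id),
    pair = pair,
    by_direction = by_dir
  )
}

#' @export
summary.rx_calls <- function(object, ...) summarize_calls(object)

#' @importFrom generics glance
#' @export
generics::glance

#' Cohort-level summary of phenotype calls
#'
#' One row per direction: cases, controls, eligible starters, exclusion
#' counts by reason, and the switch percentage under the eligible-starter
#' denominator (`switch_pct`) and the broader first-drug denominator
#' (`switch_pct_all_first_drug`).
#'
#' @param x An `rx_calls` object from [call_cohort()].
#' @param ... Unused.
#' @return A tibble with one row per direction.
#' @method glance rx_calls
#' @export
glance.rx_calls <- function(x, ...) summarize_calls(x)$by_direction

#' @export
print.rx_calls <- function(x, ...) {
  s <- summarize_calls(x)$by_direction
  cat(sprintf("<rx_calls> %d persons\n", dplyr::n_distinct(x$person_id)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %d cases / %d controls (%.1f%% switch)\n",
                s$direction[i], s$n_cases[i], s$n_controls[i], s$switch_pct[i]))
  NextMethod()
}

#' Switch percentage from summary counts
#'
#' The published framing of a switch rate: cases divided by origin-drug
#' starters, as a percentage.
#'
#' @param n_cases,n_starters Non-negative counts, `n_starters > 0`.
#' @param digits Rounding applied to the percentage (default 0, matching
#'   how registry switch rates are reported).
#' @return Numeric percentage.
#' @export
#' @examples
#' switch_rate_pct(5826, 42118) # 14
switch_rate_pct <- function(n_cases, n_starters, digits = 0) {
  if (any(n_starters <= 0)) stop_param("`n_starters` must be positive")
  round(100 * n_cases / n_starters, digits)
}
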