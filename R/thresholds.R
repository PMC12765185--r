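#' Class-weighted Bonferroni significance scheme
#'
#' Splits an overall significance budget `alpha` (default 0.05) across
#' variant annotation classes proportionally to prior class weights. With
#' per-variant weights `w_c` for the class of each of the tested variants,
#' the threshold for a variant in class `c` is
#' `alpha * w_c / sum_v w_class(v)`, so the weighted sum of thresholds over
#' all tested variants equals `alpha` exactly (budget conservation). A
#' single class of weight 1 reduces to the plain Bonferroni `alpha / M`.
#'
#' @param variant_classes Character vector: the annotation class of every
#'   tested variant (this defines the test budget).
#' @param weights Named numeric vector of positive class weights; every
#'   class present in `variant_classes` must have a weight. Default: one
#'   class `"all"` of weight 1 (plain Bonferroni).
#' @param alpha Overall significance budget.
#' @return A list of class `threshold_scheme` with a `thresholds` tibble
#'   (`class`, `weight`, `n_variants`, `threshold`).
#' @export
#' @examples
#' sc <- threshold_scheme(rep(c("coding", "intergenic"), each = 5),
#'                        weights = c(coding = 10, intergenic = 1))
#' sc$thresholds
threshold_scheme <- function(variant_classes = "all",
                             weights = c(all = 1),
                             alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_param("`alpha` must lie in (0, 1)")
  classes <- unique(variant_classes)
  if (!all(classes %in% names(weights)))
    stop_param("no weight for class(es): %s",
               paste(setdiff(classes, names(weights)), collapse = ", "))
  if (any(weights <= 0)) stop_param("class weights must be positive")
  total_weight <- sum(weights[variant_classes])
  thresholds <- tibble::tibble(
    class = classes,
    weight = unname(weights[classes]),
    n_variants = as.integer(table(variant_classes)[classes]),
    threshold = alpha * unname(weights[classes]) / total_weight
  )
  structure(list(alpha = alpha, total_weight = total_weight,
                 thresholds = thresholds),
            class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat(sprintf("<threshold_scheme> alpha = %g over %d variant(s)\n",
              x$alpha, sum(x$thresholds$n_variants)))
  print(x$thresholds)
  invisible(x)
}

#' Annotate association results with class-weighted significance
#'
#' Marks each result significant when its p value is strictly below the
#' threshold of its variant class. The scheme is attached to the returned
#' tibble (attribute `threshold_scheme`) for provenance and serialized into
#' written output headers.
#'
#' @param results Association tibble with columns `variant` and `p`, and
#'   optionally `class` (defaults to `"all"`).
#' @param scheme A [threshold_scheme()]; its classes must cover the
#'   results'.
#' @return `results` with added columns `class`, `threshold`,
#'   `significant`.
#' @export
apply_threshold_scheme <- function(results, scheme) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  if (!"class" %in% names(results)) results$class <- "all"
  out <- dplyr::left_join(results, scheme$thresholds[, c("class", "threshold")],
                          by = "class")
  if (anyNA(out$threshold))
    stop_param("scheme has no threshold for class(es): %s",
               paste(unique(out$class[is.na(out$threshold)]), collapse = ", "))
  out <- dplyr::mutate(out, significant = .data$p < .data$threshold)
  attr(out, "threshold_scheme") <- scheme
  out
}
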