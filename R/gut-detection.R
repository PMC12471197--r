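#' Construct a molecular gut-content detection table
#'
#' One row per natural-enemy taxon screened for prey DNA: individuals
#' collected in the field, individuals successfully assayed (DNA extracted
#' and amplified), and individuals scoring positive for the target prey
#' marker. The invariant 0 <= positive <= detected <= collected is enforced;
#' collected minus detected counts extraction failures, which are reported
#' separately and never enter rate denominators.
#'
#' @param records data.frame with columns `species`, `n_collected`,
#'   `n_detected`, `n_positive`, and optionally `class`, `order`, `family`.
#' @return An object of class `detection_table` (a validated data.frame).
#' @export
detection_table <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a non-empty data.frame", call. = FALSE)
  }
  req <- c("species", "n_collected", "n_detected", "n_positive")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("detection table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in req[-1]) {
    bad <- which(!is.finite(records[[col]]) | records[[col]] < 0 |
                   records[[col]] != round(records[[col]]))
    if (length(bad)) {
      stop(sprintf("%s must be a non-negative integer (row %d)", col,
                   bad[1L]), call. = FALSE)
    }
  }
  bad <- which(records$n_positive > records$n_detected |
                 records$n_detected > records$n_collected)
  if (length(bad)) {
    stop("invariant 0 <= n_positive <= n_detected <= n_collected violated ",
         "(row ", bad[1L], ")", call. = FALSE)
  }
  if (anyDuplicated(records$species)) {
    stop("species labels must be unique", call. = FALSE)
  }
  structure(records, class = c("detection_table", "data.frame"))
}

#' Positive DNA detection rate
#'
#' Percentage of successfully assayed individuals whose gut contents
#' amplified the prey-specific marker:
#' 100 * n_positive / n_detected. The denominator is the number assayed,
#' not the number collected; a taxon with nothing assayed has an undefined
#' rate (an error here, an explicit `NA` in summaries), which is distinct
#' from a true 0% rate.
#'
#' @param n_positive number of positive individuals (vectorised).
#' @param n_detected number of assayed individuals.
#' @return Detection rate(s) in percent, full precision.
#' @examples
#' detection_rate(28, 66)  # 42.42 at 2 dp
#' @export
detection_rate <- function(n_positive, n_detected) {
  check_nonneg(n_positive, "n_positive")
  check_nonneg(n_detected, "n_detected")
  if (any(n_detected == 0)) {
    stop("detection rate undefined: n_detected is zero", call. = FALSE)
  }
  if (any(n_positive > n_detected)) {
    stop("n_positive cannot exceed n_detected", call. = FALSE)
  }
  100 * n_positive / n_detected
}

#' Summarise a detection table
#'
#' Computes per-taxon positive detection rates, the pooled rate
#' 100 * sum(positive) / sum(detected) — identically the detected-count-
#' weighted mean of per-taxon rates — the list of taxa with at least one
#' positive, and extraction-failure counts.
#'
#' @param table a [detection_table].
#' @param ci_level optional confidence level; when supplied, exact
#'   Clopper-Pearson interval columns (in percent) are appended per taxon.
#' @return List with `per_taxon` (data.frame; `rate_percent` is `NA` for
#'   zero-assayed taxa), `pooled_rate_percent`, `positive_taxa`,
#'   `total_collected`, `total_detected`, `total_positive`,
#'   `extraction_failures`.
#' @examples
#' path <- system.file("extdata", "cotton_field_detection.csv",
#'                     package = "predfr")
#' summarize_detection(read_detection(path))$pooled_rate_percent
#' @export
summarize_detection <- function(table, ci_level = NULL) {
  stopifnot(inherits(table, "detection_table"))
  tot_det <- sum(table$n_detected)
  if (tot_det == 0) {
    stop("pooled rate undefined: no individuals were assayed", call. = FALSE)
  }
  per <- as.data.frame(table)
  per$rate_percent <- ifelse(per$n_detected > 0,
                             100 * per$n_positive / per$n_detected, NA_real_)
  if (!is.null(ci_level)) {
    ci <- t(mapply(binomial_ci, per$n_positive, pmax(per$n_detected, 1L),
                   MoreArgs = list(level = ci_level)))
    per$ci_lower_percent <- ifelse(per$n_detected > 0, 100 * ci[, 1], NA_real_)
    per$ci_upper_percent <- ifelse(per$n_detected > 0, 100 * ci[, 2], NA_real_)
  }
  list(
    per_taxon = per,
    pooled_rate_percent = 100 * sum(table$n_positive) / tot_det,
    positive_taxa = per$species[per$n_positive > 0],
    total_collected = sum(table$n_collected),
    total_detected = tot_det,
    total_positive = sum(table$n_positive),
    extraction_failures = sum(table$n_collected - table$n_detected)
  )
}

#' Exact binomial confidence interval for a positivity proportion
#'
#' Clopper-Pearson interval from the beta-quantile representation:
#' lower = qbeta(alpha/2, x, n - x + 1), upper =
#' qbeta(1 - alpha/2, x + 1, n - x), with the conventional 0 and 1 at the
#' boundaries x = 0 and x = n. Always contains the point estimate x/n.
#'
#' @param n_positive number of positives x.
#' @param n_detected number of trials n (> 0).
#' @param level confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)` on the proportion scale.
#' @examples
#' binomial_ci(28, 66)
#' @export
binomial_ci <- function(n_positive, n_detected, level = 0.95) {
  check_nonneg(n_positive, "n_positive")
  if (!is.numeric(n_detected) || n_detected <= 0) {
    stop("`n_detected` must be positive", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (n_positive > n_detected) {
    stop("n_positive cannot exceed n_detected", call. = FALSE)
  }
  alpha <- 1 - level
  x <- n_positive
  n <- n_detected
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Predator community composition summary
#'
#' Tallies collected individuals per species and per higher taxon (class),
#' with percentages of the grand total. Percentages are full precision;
#' report layers round half-up to 2 decimals.
#'
#' @param counts data.frame with columns `class`, `species`, `count`
#'   (non-negative; at least one positive). A [detection_table] with a
#'   `class` column is accepted, in which case `n_collected` is the count.
#' @return List of class `composition_summary`: `per_species` (species,
#'   count, percent), `per_class` (class, n_species, n_individuals,
#'   percent) and `grand_total`.
#' @examples
#' community_composition(data.frame(
#'   class = c("Insecta", "Arachnida"), species = c("A", "B"),
#'   count = c(447, 379)))
#' @export
community_composition <- function(counts) {
  if (inherits(counts, "detection_table")) {
    if (is.null(counts$class)) {
      stop("detection table has no `class` column", call. = FALSE)
    }
    counts <- data.frame(class = counts$class, species = counts$species,
                         count = counts$n_collected,
                         stringsAsFactors = FALSE)
  }
  req <- c("class", "species", "count")
  if (!is.data.frame(counts) || !all(req %in% names(counts))) {
    stop("`counts` needs columns class, species, count", call. = FALSE)
  }
  check_nonneg(counts$count, "count")
  total <- sum(counts$count)
  if (total == 0) {
    stop("degenerate input: all counts are zero", call. = FALSE)
  }

  per_species <- data.frame(
    class = counts$class, species = counts$species, count = counts$count,
    percent = 100 * counts$count / total, stringsAsFactors = FALSE
  )
  agg_n <- stats::aggregate(count ~ class, data = counts, FUN = sum)
  agg_s <- stats::aggregate(species ~ class, data = counts,
                            FUN = function(x) length(unique(x)))
  per_class <- merge(agg_s, agg_n, by = "class")
  names(per_class) <- c("class", "n_species", "n_individuals")
  per_class$percent <- 100 * per_class$n_individuals / total

  structure(list(per_species = per_species, per_class = per_class,
                 grand_total = total),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("Community composition: %d individuals, %d species, %d classes\n",
              x$grand_total, nrow(x$per_species), nrow(x$per_class)))
  pc <- x$per_class
  pc$percent <- round_half_up(pc$percent, 2)
  print(pc, row.names = FALSE)
  invisible(x)
}
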