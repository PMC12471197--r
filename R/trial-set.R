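#' Construct a set of predation trials for one predator and prey stage
#'
#' Bundles bottle-level predation observations (initial prey density `N`,
#' number consumed `Na` after the exposure window) for a single predator
#' taxon and prey developmental stage, the unit on which functional-response
#' fits operate.
#'
#' @param trials data.frame with numeric columns `density` (prey offered,
#'   > 0) and `consumed` (prey eaten, in `[0, density]`), and optionally
#'   `replicate`.
#' @param predator_id character label for the predator taxon.
#' @param prey_stage `"nymph_4_5"` (fourth to fifth instar nymphs) or
#'   `"adult"`.
#' @param exposure_T exposure time in days over which consumption was
#'   counted (default 1 day).
#' @return An object of class `trial_set`: a list with elements
#'   `predator_id`, `prey_stage`, `exposure_T` and `trials` (the validated
#'   data.frame).
#' @examples
#' ts <- trial_set(
#'   data.frame(density = rep(c(5, 10, 15, 20, 25, 30), each = 2),
#'              consumed = c(4, 5, 8, 7, 10, 11, 13, 12, 14, 15, 15, 16)),
#'   predator_id = "O. sertatus", prey_stage = "nymph_4_5"
#' )
#' ts
#' @export
trial_set <- function(trials, predator_id, prey_stage = c("nymph_4_5", "adult"),
                      exposure_T = 1.0) {
  prey_stage <- match.arg(prey_stage)
  if (!is.data.frame(trials) || nrow(trials) == 0L) {
    stop("`trials` must be a non-empty data.frame", call. = FALSE)
  }
  req <- c("density", "consumed")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols)) {
    stop("`trials` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  check_finite_scalar(exposure_T, "exposure_T")
  if (exposure_T <= 0) stop("`exposure_T` must be positive", call. = FALSE)

  bad <- which(!is.finite(trials$density) | trials$density <= 0)
  if (length(bad)) {
    stop("density must be positive and finite (row ", bad[1L], ")",
         call. = FALSE)
  }
  bad <- which(!is.finite(trials$consumed) | trials$consumed < 0 |
                 trials$consumed > trials$density)
  if (length(bad)) {
    stop("consumed must lie in [0, density] (row ", bad[1L], ")",
         call. = FALSE)
  }
  if (length(unique(trials$density)) < 3L) {
    stop("at least 3 distinct prey densities are required to identify ",
         "attack rate and handling time with residual degrees of freedom",
         call. = FALSE)
  }
  if (is.null(trials$replicate)) {
    trials$replicate <- stats::ave(trials$density, trials$density,
                                   FUN = seq_along)
  }

  structure(
    list(predator_id = as.character(predator_id),
         prey_stage = prey_stage,
         exposure_T = exposure_T,
         trials = trials[, c("density", "consumed", "replicate")]),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Predation trials: %s on %s prey\n", x$predator_id,
              x$prey_stage))
  cat(sprintf("  %d bottles, densities {%s}, exposure %.3g d\n",
              nrow(x$trials),
              paste(sort(unique(x$trials$density)), collapse = ", "),
              x$exposure_T))
  invisible(x)
}

#' @export
as.data.frame.trial_set <- function(x, ...) {
  data.frame(predator = x$predator_id, prey_stage = x$prey_stage,
             x$trials, stringsAsFactors = FALSE)
}

# Aggregate replicate bottles to per-density mean consumption; used by the
# fitting routines when aggregate = "mean".
aggregate_trials <- function(ts) {
  agg <- stats::aggregate(consumed ~ density, data = ts$trials, FUN = mean)
  agg$replicate <- 1L
  ts$trials <- agg[, c("density", "consumed", "replicate")]
  ts
}
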