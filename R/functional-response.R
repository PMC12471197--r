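#' Classify functional-response type from the linear polynomial coefficient
#'
#' In the two-stage functional-response workflow, the proportion of prey
#' consumed Na/N is first regressed on initial density N with a cubic
#' polynomial Na/N = a + bN + cN^2 + dN^3. The sign of the linear
#' coefficient b determines the response type: b < 0 gives the decelerating
#' hyperbolic Type II, b > 0 the sigmoid Type III.
#'
#' @param b linear coefficient of the cubic proportion-consumed polynomial.
#' @return `"II"`, `"III"`, or `"indeterminate"` (b exactly zero).
#' @examples
#' classify_response(-0.008)  # "II"
#' classify_response(0.02)    # "III"
#' @export
classify_response <- function(b) {
  check_finite_scalar(b, "b")
  if (b < 0) "II" else if (b > 0) "III" else "indeterminate"
}

#' Fit the cubic proportion-consumed polynomial and classify response type
#'
#' Fits Na/N = a + bN + cN^2 + dN^3 to bottle-level trials. The canonical
#' estimator is ordinary least squares on the per-bottle ratio
#' consumed/density; a binomial-logit GLM on the raw counts is available as
#' `method = "glm"` (classification then uses the sign of the GLM's linear
#' coefficient on the same convention). Classification relies only on the
#' sign of b; its standard error is reported but never gates the call.
#'
#' @param trials a [trial_set].
#' @param method `"ols"` (default; least squares on the ratio) or `"glm"`
#'   (binomial logit on counts).
#' @return An object of class `poly_type_fit`: list with `coefficients`
#'   (named a, b, c, d), `se_b`, `r_squared`, `response_type`, `method`,
#'   `n_points`, and the predator/stage labels.
#' @seealso [classify_response()], [fit_holling()]
#' @export
fit_polynomial_type <- function(trials, method = c("ols", "glm")) {
  stopifnot(inherits(trials, "trial_set"))
  method <- match.arg(method)
  df <- trials$trials
  if (length(unique(df$density)) < 4L) {
    stop("cubic polynomial is underdetermined: need >= 4 distinct densities",
         call. = FALSE)
  }
  ratio <- df$consumed / df$density
  if (all(ratio == 0)) {
    stop("degenerate data: no prey consumed in any bottle", call. = FALSE)
  }

  N <- df$density
  if (method == "ols") {
    fit <- stats::lm(ratio ~ N + I(N^2) + I(N^3))
    cf <- stats::coef(fit)
    s <- summary(fit)
    se_b <- s$coefficients["N", "Std. Error"]
    r2 <- s$r.squared
  } else {
    # consumed successes out of density offered, logit link
    fit <- stats::glm(cbind(df$consumed, df$density - df$consumed) ~
                        N + I(N^2) + I(N^3), family = stats::binomial())
    cf <- stats::coef(fit)
    se_b <- summary(fit)$coefficients["N", "Std. Error"]
    # pseudo-R2 on the response scale for reporting comparability
    mu <- stats::predict(fit, type = "response")
    r2 <- 1 - sum((ratio - mu)^2) / sum((ratio - mean(ratio))^2)
  }
  cf <- stats::setNames(as.numeric(cf), c("a", "b", "c", "d"))
  # coefficients that are zero up to solver round-off (e.g. a constant
  # ratio, where the exact OLS solution is b = c = d = 0) classify as
  # indeterminate rather than inheriting the sign of numerical noise
  b_eff <- if (abs(cf[["b"]]) < 1e-10) 0 else cf[["b"]]

  structure(
    list(coefficients = cf,
         se_b = as.numeric(se_b),
         r_squared = as.numeric(r2),
         response_type = classify_response(b_eff),
         method = method,
         n_points = length(ratio),
         predator_id = trials$predator_id,
         prey_stage = trials$prey_stage),
    class = "poly_type_fit"
  )
}

#' @export
print.poly_type_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("Functional-response type fit (%s): %s on %s\n",
              x$method, x$predator_id, x$prey_stage))
  cat(sprintf("  Na/N = %.4g %+.4g N %+.4g N^2 %+.4g N^3   (R2 = %.3f)\n",
              cf["a"], cf["b"], cf["c"], cf["d"], x$r_squared))
  cat(sprintf("  b = %.4g (se %.3g) => Type %s\n", cf["b"], x$se_b,
              x$response_type))
  invisible(x)
}

#' Construct a Holling disc-equation fit object
#'
#' Builds a `holling_fit` from known parameters, e.g. values published in a
#' functional-response table, so that derived metrics, predictions and
#' search-efficiency curves can be computed without refitting raw data.
#' [fit_holling()] returns the same class from data.
#'
#' @param attack_rate instantaneous attack rate a' (per day), > 0.
#' @param handling_time handling time Th (days per prey item), > 0.
#' @param model `"II"` or `"III"`.
#' @param exposure_T exposure time T in days.
#' @param predator_id,prey_stage optional labels.
#' @param r_squared,n_points,converged optional fit metadata.
#' @return An object of class `holling_fit`.
#' @examples
#' fit <- holling_fit(attack_rate = 1.339, handling_time = 0.022)
#' derived_metrics(fit)
#' @export
holling_fit <- function(attack_rate, handling_time, model = c("II", "III"),
                        exposure_T = 1.0, predator_id = NA_character_,
                        prey_stage = NA_character_, r_squared = NA_real_,
                        n_points = NA_integer_, converged = TRUE) {
  model <- match.arg(model)
  check_finite_scalar(attack_rate, "attack_rate")
  check_finite_scalar(handling_time, "handling_time")
  check_finite_scalar(exposure_T, "exposure_T")
  if (attack_rate <= 0 || handling_time <= 0 || exposure_T <= 0) {
    stop("attack_rate, handling_time and exposure_T must all be positive",
         call. = FALSE)
  }
  structure(
    list(model = model,
         attack_rate = attack_rate,
         handling_time = handling_time,
         exposure_T = exposure_T,
         r_squared = r_squared,
         n_points = n_points,
         converged = isTRUE(converged),
         boundary = FALSE,
         predator_id = as.character(predator_id),
         prey_stage = as.character(prey_stage)),
    class = "holling_fit"
  )
}

# Disc-equation expectation; N may be a vector.
holling_expectation <- function(N, attack_rate, handling_time, exposure_T,
                                model) {
  x <- if (model == "III") N^2 else N
  attack_rate * exposure_T * x / (1 + attack_rate * handling_time * x)
}

# lower box constraint for both parameters in the bounded NLS
.HOLLING_LOWER <- 1e-6

#' Fit the Holling disc equation by bounded nonlinear least squares
#'
#' Estimates the instantaneous attack rate a' and handling time Th of the
#' Type II disc equation Na = a'TN/(1 + a'Th N), or the Type III form with
#' N^2 in place of N, by minimising the residual sum of squares of observed
#' consumption counts. Both parameters are constrained positive (lower bound
#' 1e-6); fits that terminate within 10x the bound are flagged as boundary
#' solutions with a warning (typical when the data show no saturation, so Th
#' is effectively zero).
#'
#' Starting values follow low-density-slope and saturation heuristics:
#' a'0 = mean(Na/N) at the lowest density divided by T, Th0 = 1/max(Na).
#'
#' @param trials a [trial_set].
#' @param model `"II"` or `"III"`, typically taken from
#'   [fit_polynomial_type()].
#' @param exposure_T exposure time in days; defaults to the value stored in
#'   `trials`.
#' @param aggregate `"raw"` fits every bottle (default); `"mean"` first
#'   collapses replicates to per-density mean consumption.
#' @return A [holling_fit] with estimated parameters, `r_squared`
#'   (1 - SSE/SST about the mean of observed Na), `n_points`, `converged`
#'   (optimizer status) and `boundary` (TRUE when a parameter sits at its
#'   positivity bound).
#' @examples
#' ts <- simulate_trials(simulation_config(attack_rate = 1.276,
#'   handling_time = 0.023, noise = "none", seed = 1))
#' fit_holling(ts, model = "II")
#' @export
fit_holling <- function(trials, model = c("II", "III"), exposure_T = NULL,
                        aggregate = c("raw", "mean")) {
  stopifnot(inherits(trials, "trial_set"))
  model <- match.arg(model)
  aggregate <- match.arg(aggregate)
  if (aggregate == "mean") trials <- aggregate_trials(trials)
  if (is.null(exposure_T)) exposure_T <- trials$exposure_T
  check_finite_scalar(exposure_T, "exposure_T")

  df <- trials$trials
  N <- df$density
  Na <- df$consumed
  if (all(Na == 0)) {
    stop("no predation observed in any bottle: disc equation is not ",
         "identifiable", call. = FALSE)
  }

  low <- N == min(N)
  a0 <- max(mean(Na[low] / N[low]) / exposure_T, .HOLLING_LOWER * 10)
  th0 <- 1 / max(Na)

  fit <- minpack.lm::nlsLM(
    Na ~ holling_expectation(N, a, Th, exposure_T, model),
    start = list(a = a0, Th = th0),
    lower = rep(.HOLLING_LOWER, 2L),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)
  )

  est <- stats::coef(fit)
  converged <- isTRUE(fit$convInfo$isConv)
  if (!converged) {
    warning("disc-equation optimizer did not converge; inspect the fit",
            call. = FALSE)
  }
  boundary <- any(est <= 10 * .HOLLING_LOWER)
  if (boundary) {
    warning("parameter estimate at the positivity bound (no saturation in ",
            "the data?); derived metrics are unreliable", call. = FALSE)
  }

  resid <- Na - holling_expectation(N, est[["a"]], est[["Th"]], exposure_T,
                                    model)
  r2 <- 1 - sum(resid^2) / sum((Na - mean(Na))^2)

  out <- holling_fit(attack_rate = est[["a"]], handling_time = est[["Th"]],
                     model = model, exposure_T = exposure_T,
                     predator_id = trials$predator_id,
                     prey_stage = trials$prey_stage,
                     r_squared = r2, n_points = length(Na),
                     converged = converged)
  out$boundary <- boundary
  out
}

#' @export
print.holling_fit <- function(x, ...) {
  cat(sprintf("Holling Type %s disc-equation fit", x$model))
  if (!is.na(x$predator_id)) {
    cat(sprintf(": %s on %s", x$predator_id, x$prey_stage))
  }
  cat("\n")
  cat(sprintf("  attack rate a' = %.4g /d, handling time Th = %.4g d/prey, T = %.3g d\n",
              x$attack_rate, x$handling_time, x$exposure_T))
  dm <- derived_metrics(x)
  cat(sprintf("  daily max predation T/Th = %.4g, theoretical predation a'/Th = %.4g\n",
              dm[["daily_max_predation"]], dm[["theoretical_predation"]]))
  if (!is.na(x$r_squared)) cat(sprintf("  R2 = %.3f (n = %d)\n",
                                       x$r_squared, x$n_points))
  if (x$boundary) cat("  [parameter at positivity bound]\n")
  if (!x$converged) cat("  [optimizer did not converge]\n")
  invisible(x)
}

#' Predict prey consumption at given densities
#'
#' Evaluates the fitted disc equation. Consumption is monotone
#' non-decreasing in density and, for Type II, bounded above by the daily
#' maximum predation rate T/Th.
#'
#' @param fit a [holling_fit].
#' @param density non-negative prey densities (vectorised).
#' @return Expected number of prey consumed at each density.
#' @examples
#' fit <- holling_fit(1.276, 0.023)
#' predict_consumption(fit, c(0, 10, 30))
#' @export
predict_consumption <- function(fit, density) {
  stopifnot(inherits(fit, "holling_fit"))
  check_nonneg(density, "density")
  holling_expectation(density, fit$attack_rate, fit$handling_time,
                      fit$exposure_T, fit$model)
}

#' Derived predation metrics from a disc-equation fit
#'
#' The daily maximum predation rate T/Th (the most prey a predator can
#' handle during the exposure window) and the theoretical predation a'/Th
#' (a composite control-potential index combining attack rate and handling
#' time). Values are returned at full precision; report tables round
#' half-up to 2 decimals.
#'
#' @param fit a [holling_fit].
#' @return Named numeric vector `daily_max_predation`, and
#'   `theoretical_predation`.
#' @examples
#' derived_metrics(holling_fit(1.339, 0.022))  # 45.45, 60.86 at 2 dp
#' @export
derived_metrics <- function(fit) {
  stopifnot(inherits(fit, "holling_fit"))
  if (!is.finite(fit$handling_time) || fit$handling_time <= 0) {
    stop("invalid fit: handling_time must be positive", call. = FALSE)
  }
  c(daily_max_predation = fit$exposure_T / fit$handling_time,
    theoretical_predation = fit$attack_rate / fit$handling_time)
}

#' Search-efficiency curve
#'
#' Evaluates the density-dependent search efficiency
#' S(N) = a'/(1 + a'Th N), the effective attack capability at prey density
#' N. S is strictly decreasing in N and equals a' at N = 0.
#'
#' @param fit a [holling_fit].
#' @param densities non-negative prey densities.
#' @return An object of class `search_curve`: data.frame with columns
#'   `density` and `efficiency`, carrying the source fit as attribute
#'   `"fit"`.
#' @examples
#' search_efficiency(holling_fit(1.067, 0.045), c(0, 5, 10, 30))
#' @export
search_efficiency <- function(fit, densities) {
  stopifnot(inherits(fit, "holling_fit"))
  check_nonneg(densities, "densities")
  s <- fit$attack_rate /
    (1 + fit$attack_rate * fit$handling_time * densities)
  structure(
    data.frame(density = densities, efficiency = s),
    fit = fit,
    class = c("search_curve", "data.frame")
  )
}

#' @export
plot.search_curve <- function(x, ...) {
  fit <- attr(x, "fit")
  main <- if (!is.na(fit$predator_id)) {
    sprintf("Search efficiency: %s (%s)", fit$predator_id, fit$prey_stage)
  } else "Search efficiency"
  graphics::plot(x$density, x$efficiency, type = "b", pch = 16,
                 xlab = "Prey density N", ylab = "Search efficiency S",
                 main = main, ...)
  invisible(x)
}

#' Rank predators by control potential
#'
#' Orders disc-equation fits by descending theoretical predation a'/Th,
#' breaking ties by daily maximum predation rate T/Th and then by predator
#' label (lexicographic), so the ranking is deterministic.
#'
#' @param fits list of [holling_fit] objects (typically one prey stage).
#' @return The input list reordered, with a `ranking` attribute: data.frame
#'   of predator, theoretical predation and daily maximum predation rate in
#'   rank order.
#' @export
rank_predators <- function(fits) {
  if (!is.list(fits) || length(fits) == 0L ||
      !all(vapply(fits, inherits, logical(1), "holling_fit"))) {
    stop("`fits` must be a non-empty list of holling_fit objects",
         call. = FALSE)
  }
  tp <- vapply(fits, function(f) derived_metrics(f)[["theoretical_predation"]],
               numeric(1))
  dm <- vapply(fits, function(f) derived_metrics(f)[["daily_max_predation"]],
               numeric(1))
  id <- vapply(fits, function(f) f$predator_id, character(1))
  ord <- order(-tp, -dm, id)
  out <- fits[ord]
  attr(out, "ranking") <- data.frame(
    predator = id[ord],
    theoretical_predation = tp[ord],
    daily_max_predation = dm[ord],
    stringsAsFactors = FALSE
  )
  out
}

#' Summarise disc-equation fits as a report table
#'
#' Flattens a list of fits into the standard functional-response parameter
#' table: predator, stage, model, a', Th, T, R2 and the two derived
#' metrics. Derived columns are rounded half-up to 2 decimals when
#' `rounded = TRUE`; parameters keep 3 decimals.
#'
#' @param fits list of [holling_fit] objects.
#' @param rounded apply report rounding (default TRUE).
#' @return data.frame with one row per fit.
#' @export
fits_table <- function(fits, rounded = TRUE) {
  stopifnot(is.list(fits), length(fits) > 0L)
  rows <- lapply(fits, function(f) {
    dm <- derived_metrics(f)
    data.frame(predator = f$predator_id, prey_stage = f$prey_stage,
               model = f$model, a_prime = f$attack_rate,
               Th = f$handling_time, T = f$exposure_T,
               r_squared = f$r_squared,
               T_over_Th = dm[["daily_max_predation"]],
               aprime_over_Th = dm[["theoretical_predation"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (rounded) {
    out$a_prime <- round_half_up(out$a_prime, 3)
    out$Th <- round_half_up(out$Th, 3)
    out$r_squared <- round_half_up(out$r_squared, 3)
    out$T_over_Th <- round_half_up(out$T_over_Th, 2)
    out$aprime_over_Th <- round_half_up(out$aprime_over_Th, 2)
  }
  rownames(out) <- NULL
  out
}
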