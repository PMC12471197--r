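#' Run the full predation-analysis pipeline
#'
#' For every predator-by-stage group in the trials file: fit the cubic
#' type-classification polynomial, choose the Holling model from the sign
#' of its linear coefficient (unless `model` overrides it), fit the disc
#' equation, compute the derived predation metrics, and evaluate the
#' search-efficiency curve at the trial densities. When a detection table
#' is supplied, per-taxon and pooled positive detection rates and (if a
#' `class` column is present) community composition are appended. A failure
#' in any group is recorded in the report rather than aborting the run.
#'
#' @param trials_path path to a `trials.csv` file (see [read_trials()]).
#' @param detection_path optional path to a detection CSV
#'   (see [read_detection()]).
#' @param model `"auto"` (classify each group) or a forced `"II"`/`"III"`.
#' @param exposure_T exposure time in days.
#' @param aggregate `"raw"` or `"mean"`, passed to [fit_holling()].
#' @param ci_level optional confidence level for detection-rate intervals.
#' @param out_dir optional directory; when given, writes `fits.csv`,
#'   `type.csv`, `detection_summary.csv` (if applicable) and `report.json`
#'   (full precision) there.
#' @return An `analysis_report` list: `functional_response` (per-group
#'   poly fit, holling fit, derived metrics, search curve), `fits_table`,
#'   `type_table`, `detection`, `composition`, `errors`, `partial`, and a
#'   `provenance` block (input MD5 hashes, package version, timestamp).
#' @export
run_full_analysis <- function(trials_path, detection_path = NULL,
                              model = c("auto", "II", "III"),
                              exposure_T = 1.0,
                              aggregate = c("raw", "mean"),
                              ci_level = NULL, out_dir = NULL) {
  model <- match.arg(model)
  aggregate <- match.arg(aggregate)
  trial_sets <- read_trials(trials_path, exposure_T = exposure_T)

  groups <- list()
  errors <- list()
  for (key in names(trial_sets)) {
    res <- tryCatch({
      ts <- trial_sets[[key]]
      ptf <- fit_polynomial_type(ts)
      use_model <- if (model == "auto") {
        if (ptf$response_type == "indeterminate") "II" else ptf$response_type
      } else model
      hf <- fit_holling(ts, model = use_model, aggregate = aggregate)
      list(poly = ptf,
           holling = hf,
           derived = derived_metrics(hf),
           search = search_efficiency(hf, sort(unique(ts$trials$density))))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
    } else {
      groups[[key]] <- res
    }
  }

  detection <- NULL
  composition <- NULL
  if (!is.null(detection_path)) {
    dt <- read_detection(detection_path)
    detection <- summarize_detection(dt, ci_level = ci_level)
    if (!is.null(dt$class)) composition <- community_composition(dt)
  }

  ft <- if (length(groups)) {
    fits_table(lapply(groups, `[[`, "holling"))
  } else NULL
  tt <- if (length(groups)) {
    do.call(rbind, lapply(groups, function(g) {
      cf <- g$poly$coefficients
      data.frame(predator = g$poly$predator_id,
                 prey_stage = g$poly$prey_stage,
                 a = cf["a"], b = cf["b"], c = cf["c"], d = cf["d"],
                 r_squared = g$poly$r_squared,
                 type = g$poly$response_type,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  } else NULL

  report <- structure(
    list(functional_response = groups,
         fits_table = ft,
         type_table = tt,
         detection = detection,
         composition = composition,
         errors = errors,
         partial = length(errors) > 0L,
         provenance = list(
           trials_md5 = unname(tools::md5sum(trials_path)),
           detection_md5 = if (is.null(detection_path)) NA_character_ else
             unname(tools::md5sum(detection_path)),
           package_version = as.character(utils::packageVersion("predfr")),
           timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
         )),
    class = "analysis_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an analysis report to disk
#'
#' Emits `fits.csv` (disc-equation parameter table, report-rounded),
#' `type.csv` (cubic classification table), `detection_summary.csv` and
#' `report.json` (full precision, including search curves) into `out_dir`.
#'
#' @param report an `analysis_report` from [run_full_analysis()].
#' @param out_dir output directory, created if absent.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$fits_table)) {
    utils::write.csv(report$fits_table, file.path(out_dir, "fits.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$type_table)) {
    tt <- report$type_table
    tt$r_squared <- round_half_up(tt$r_squared, 3)
    utils::write.csv(tt, file.path(out_dir, "type.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$detection)) {
    per <- report$detection$per_taxon
    num <- intersect(c("rate_percent", "ci_lower_percent",
                       "ci_upper_percent"), names(per))
    for (col in num) per[[col]] <- round_half_up(per[[col]], 2)
    utils::write.csv(per, file.path(out_dir, "detection_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  json <- list(
    functional_response = lapply(report$functional_response, function(g) {
      list(predator = g$holling$predator_id,
           prey_stage = g$holling$prey_stage,
           poly = list(coefficients = as.list(g$poly$coefficients),
                       se_b = g$poly$se_b, r_squared = g$poly$r_squared,
                       response_type = g$poly$response_type),
           holling = list(model = g$holling$model,
                          attack_rate = g$holling$attack_rate,
                          handling_time = g$holling$handling_time,
                          exposure_T = g$holling$exposure_T,
                          r_squared = g$holling$r_squared,
                          converged = g$holling$converged,
                          boundary = g$holling$boundary),
           derived = as.list(g$derived),
           search_curve = list(density = g$search$density,
                               efficiency = g$search$efficiency))
    }),
    detection = if (!is.null(report$detection)) {
      list(pooled_rate_percent = report$detection$pooled_rate_percent,
           positive_taxa = report$detection$positive_taxa,
           total_detected = report$detection$total_detected,
           total_positive = report$detection$total_positive,
           extraction_failures = report$detection$extraction_failures)
    },
    composition = if (!is.null(report$composition)) {
      list(per_class = report$composition$per_class,
           grand_total = report$composition$grand_total)
    },
    errors = report$errors,
    partial = report$partial,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Predation analysis report\n")
  if (!is.null(x$fits_table)) {
    cat(sprintf("  %d predator x stage group(s) fitted\n",
                nrow(x$fits_table)))
    print(x$fits_table, row.names = FALSE)
  }
  if (!is.null(x$detection)) {
    cat(sprintf("  pooled positive detection rate: %.2f%% (%d/%d assayed)\n",
                round_half_up(x$detection$pooled_rate_percent, 2),
                x$detection$total_positive, x$detection$total_detected))
  }
  if (x$partial) {
    cat(sprintf("  PARTIAL: %d group(s) failed: %s\n", length(x$errors),
                paste(names(x$errors), collapse = ", ")))
  }
  invisible(x)
}
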