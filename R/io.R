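#' Read predation trials from CSV
#'
#' Expects the `trials.csv` schema: header columns `predator`, `prey_stage`,
#' `density`, `consumed`, `replicate` (UTF-8). Rows are grouped by predator
#' and prey stage into [trial_set] objects, validating every row; failures
#' name the file and the offending row.
#'
#' @param path path to the CSV file.
#' @param exposure_T exposure time (days) attached to every trial set.
#' @return Named list of [trial_set] objects, names `"predator|prey_stage"`.
#' @export
read_trials <- function(path, exposure_T = 1.0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty trials file: ", path, call. = FALSE)
  req <- c("predator", "prey_stage", "density", "consumed")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$prey_stage %in% PREY_STAGES)
  if (length(bad)) {
    stop(sprintf("%s row %d: unknown prey_stage '%s' (expected %s)", path,
                 bad[1L], df$prey_stage[bad[1L]],
                 paste(PREY_STAGES, collapse = " or ")), call. = FALSE)
  }
  bad <- which(!is.finite(df$density) | df$density <= 0)
  if (length(bad)) {
    stop(sprintf("%s row %d: density must be positive", path, bad[1L]),
         call. = FALSE)
  }
  bad <- which(!is.finite(df$consumed) | df$consumed < 0 |
                 df$consumed > df$density)
  if (length(bad)) {
    stop(sprintf("%s row %d: consumed (%s) outside [0, density = %s]", path,
                 bad[1L], df$consumed[bad[1L]], df$density[bad[1L]]),
         call. = FALSE)
  }

  key <- paste(df$predator, df$prey_stage, sep = "|")
  out <- lapply(split(df, key), function(g) {
    trial_set(g[, intersect(c("density", "consumed", "replicate"), names(g))],
              predator_id = g$predator[1L], prey_stage = g$prey_stage[1L],
              exposure_T = exposure_T)
  })
  out[order(names(out))]
}

#' Write trial sets to CSV
#'
#' Inverse of [read_trials()]: flattens trial sets back to the
#' `trials.csv` schema.
#'
#' @param trial_sets a [trial_set] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trial_sets, path) {
  if (inherits(trial_sets, "trial_set")) trial_sets <- list(trial_sets)
  df <- do.call(rbind, lapply(trial_sets, as.data.frame))
  df <- df[, c("predator", "prey_stage", "density", "consumed", "replicate")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gut-content detection table from CSV
#'
#' Expects columns `species`, `n_collected`, `n_detected`, `n_positive`;
#' optional `class`, `order`, `family` taxonomy columns are kept.
#'
#' @param path path to the CSV file.
#' @return A [detection_table].
#' @export
read_detection <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(detection_table(df),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Bundled field-survey datasets
#'
#' Convenience loaders for the plain-text datasets shipped with the
#' package: a molecular gut-content screen of 23 natural-enemy taxa from
#' cotton fields (826 collected, 806 assayed for *Lygus pratensis* DNA),
#' and the published functional-response parameter and type-classification
#' tables for the four spider species that screened positive.
#'
#' @return `predfr_detection_data()`: a [detection_table].
#'   `predfr_holling_params()` and `predfr_polytype_params()`: data.frames.
#' @export
predfr_detection_data <- function() {
  read_detection(system.file("extdata", "cotton_field_detection.csv",
                             package = "predfr", mustWork = TRUE))
}

#' @rdname predfr_detection_data
#' @export
predfr_holling_params <- function() {
  utils::read.csv(system.file("extdata", "spider_holling_params.csv",
                              package = "predfr", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname predfr_detection_data
#' @export
predfr_polytype_params <- function() {
  utils::read.csv(system.file("extdata", "spider_polytype_coefficients.csv",
                              package = "predfr", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
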