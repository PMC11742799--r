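#' Read and write calibration data as CSV
#'
#' The on-disk dialect is a UTF-8 comma-separated file with header
#' `time_h,od_mean,od_sd,pha_g_per_l,pha_sd,weight`, decimal point `.` and
#' `NA` for missing values. Only `od_mean` and `pha_g_per_l` are required;
#' missing optional columns default to `od_sd = 0`, `pha_sd = 0`,
#' `weight = 1`, `time_h = NA`. Rows without a PHA value are excluded from
#' the returned calibration set but kept in the `unlabeled` attribute (they
#' are still usable for estimation).
#'
#' @param path File path.
#' @return `read_calibration_csv()`: a [calibration_set()] (attribute
#'   `unlabeled`: data frame of PHA-less rows, possibly empty).
#'   `write_calibration_csv()`: `path`, invisibly.
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) stop(input_error(paste("no such file:", path)))
  d <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop(parse_error(path, conditionMessage(e)))
  )
  required <- c("od_mean", "pha_g_per_l")
  if (!all(required %in% names(d))) {
    stop(parse_error(path, paste(
      "header must contain", paste(required, collapse = " and "))))
  }
  for (col in c("time_h", "od_sd", "pha_sd", "weight")) {
    if (!col %in% names(d)) {
      d[[col]] <- switch(col, time_h = NA_real_, weight = 1, 0)
    }
  }
  bad <- which(!is.na(d$od_mean) & d$od_mean < 0 |
               !is.na(d$pha_g_per_l) & d$pha_g_per_l < 0)
  if (length(bad)) {
    stop(validation_error(sprintf(
      "%s: negative od/pha at data row %d", path, bad[1])))
  }
  labeled <- !is.na(d$pha_g_per_l) & !is.na(d$od_mean)
  keep <- d[labeled, , drop = FALSE]
  out <- calibration_set(
    od = keep$od_mean, pha = keep$pha_g_per_l, time_h = keep$time_h,
    od_sd = ifelse(is.na(keep$od_sd), 0, keep$od_sd),
    pha_sd = ifelse(is.na(keep$pha_sd), 0, keep$pha_sd),
    weight = ifelse(is.na(keep$weight), 1, keep$weight),
    label = basename(path)
  )
  attr(out, "unlabeled") <- d[!labeled, , drop = FALSE]
  out
}

#' @rdname read_calibration_csv
#' @param data A [calibration_set()] (or coercible data frame).
#' @export
write_calibration_csv <- function(data, path) {
  data <- as_calibration_set(data)
  out <- data.frame(time_h = data$time_h, od_mean = data$od,
                    od_sd = data$od_sd, pha_g_per_l = data$pha,
                    pha_sd = data$pha_sd, weight = data$weight)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_error <- function(path, msg) {
  structure(class = c("pha_parse_error", "error", "condition"),
            list(message = sprintf("%s: %s", path, msg), call = NULL))
}

validation_error <- function(msg) {
  structure(class = c("pha_validation_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Read and write fitted models as JSON
#'
#' Model files carry the structure id, the parameter map at full decimal
#' precision (17 significant digits, so a write/read round trip is
#' bit-exact), fit provenance (N, RSS, convergence, restarts, seed,
#' calibration OD range) and a timestamp. The timestamp is the only field
#' that differs between two runs with identical inputs.
#'
#' @param model A `fitted_pha_model`.
#' @param path File path.
#' @param data_label Free-text provenance label.
#' @return `write_model_json()`: `path`, invisibly;
#'   `read_model_json()`: a `fitted_pha_model`.
#' @export
write_model_json <- function(model, path, data_label = "") {
  stopifnot(inherits(model, "fitted_pha_model"))
  rec <- list(
    schema_version = 1L,
    structure_id = model$structure$id,
    formula = model$structure$formula_text,
    params = as.list(model$params),
    n_points = model$n_points,
    rss = model$rss,
    converged = model$converged,
    n_restarts_used = model$n_restarts_used,
    od_range = model$od_range,
    seed = model$seed,
    data_label = data_label,
    fitted_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  # digits = I(17): 17 significant digits, enough for a bit-exact round trip
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop(input_error(paste("no such file:", path)))
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- model_structure(rec$structure_id)
  params <- unlist(rec$params)[st$param_names]
  new_fitted_model(
    structure = st, params = params,
    rss = rec$rss %||% NA_real_, n_points = rec$n_points %||% NA_integer_,
    converged = isTRUE(rec$converged),
    n_restarts_used = rec$n_restarts_used %||% NA_integer_,
    od_range = if (!is.null(rec$od_range)) as.numeric(rec$od_range) else
      c(NA_real_, NA_real_),
    seed = rec$seed %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a selection table as TSV
#'
#' One row per requested candidate (infeasible candidates included with
#' `Inf` in the metric columns), tab-separated, mirroring the
#' model/RSS/AICc/R^2 layout of a selection report.
#'
#' @param selection A `selection_table` from [select_model()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_selection_tsv <- function(selection, path) {
  tab <- as.data.frame(selection)
  tab <- tab[, c("id", "name", "M", "rss", "aicc", "r2", "converged",
                 intersect(c("a", "b", "c", "d", "e"), names(tab)))]
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Accepts a YAML mapping whose keys are the arguments of
#' [simulation_config()] (unknown keys are an error); `truth_params` is a
#' nested mapping of parameter letters to values.
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_simulation_yaml <- function(path) {
  if (!file.exists(path)) stop(input_error(paste("no such file:", path)))
  raw <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(validation_error(paste("unknown config keys:",
                                paste(unknown, collapse = ", "))))
  }
  if (!is.null(raw$truth_params)) raw$truth_params <- unlist(raw$truth_params)
  if (!is.null(raw$sampling_times)) {
    raw$sampling_times <- as.numeric(raw$sampling_times)
  }
  for (key in c("od0", "od_max", "growth_rate", "pha_noise_sd",
                "od_rel_noise_sd", "shift_time", "shift_bias")) {
    if (!is.null(raw[[key]])) raw[[key]] <- as.numeric(raw[[key]])
  }
  do.call(simulation_config, raw)
}
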