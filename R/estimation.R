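#' Predict a PHA time series from OD measurements
#'
#' Applies a fitted soft-sensor model to a series of OD600 readings and
#' returns the predicted PHA concentration at every point together with its
#' first-order propagated standard deviation (see [propagate_sd()]).
#' Points whose OD lies outside the calibration OD range are still
#' estimated but flagged `extrapolated`: applying a batch-trained model to
#' a later continuous phase routinely leaves the calibrated span, and the
#' flag is the warning the operator gets.
#'
#' @param model A `fitted_pha_model` from [fit_model()] or
#'   [reference_model()].
#' @param od Numeric vector of OD600 means.
#' @param od_sd Replicate standard deviations of the OD readings
#'   (default 0).
#' @param time_h Optional sampling times (hours).
#' @return An `estimate_series` data frame with columns `time_h`, `od`,
#'   `od_sd`, `pha_est`, `pha_sd_est`, `extrapolated`, in input order;
#'   attributes record the model provenance.
#' @examples
#' estimate_series(reference_model("PHBV"), od = c(1, 10, 25))
#' @export
estimate_series <- function(model, od, od_sd = 0, time_h = NA_real_) {
  stopifnot(inherits(model, "fitted_pha_model"))
  n <- length(od)
  od_sd <- rep_len(od_sd, n)
  time_h <- rep_len(as.numeric(time_h), n)
  pha_est <- evaluate_model(model$structure, model$params, od)
  pha_sd_est <- propagate_sd(model, od, od_sd)
  rng <- model$od_range
  extrapolated <- if (is.null(rng) || anyNA(rng)) rep(FALSE, n) else
    od < rng[1] | od > rng[2]
  structure(
    data.frame(time_h = time_h, od = od, od_sd = od_sd, pha_est = pha_est,
               pha_sd_est = pha_sd_est, extrapolated = extrapolated),
    structure_id = model$structure$id, params = model$params,
    class = c("estimate_series", "data.frame")
  )
}

#' First-order uncertainty propagation from OD to PHA
#'
#' Propagates the OD replicate standard deviation through the calibration
#' curve to first order: `sd(PHA) = |df/dx (OD)| * sd(OD)`. This covers only
#' the OD measurement noise; uncertainty in the fitted parameters is not
#' included (the calibration data needed to estimate their covariance are
#' typically not retained with the model).
#'
#' @inheritParams estimate_series
#' @return Numeric vector of PHA standard deviations (g/L); exactly 0
#'   wherever `od_sd` is 0.
#' @export
propagate_sd <- function(model, od, od_sd) {
  stopifnot(inherits(model, "fitted_pha_model"))
  od_sd <- rep_len(od_sd, length(od))
  if (any(od_sd < 0)) stop(input_error("od_sd must be non-negative"))
  abs(model_derivative(model$structure, model$params, od)) * od_sd
}

#' Mean absolute error of a model on labelled data
#'
#' `MAE = sum(|y_i - f(x_i)|) / N` over a calibration set with measured PHA
#' concentrations; the score used to compare soft-sensor models across
#' processes.
#'
#' @inheritParams estimate_series
#' @param labeled A [calibration_set()] with measured `pha`.
#' @return Scalar MAE in g/L.
#' @export
mae <- function(model, labeled) {
  stopifnot(inherits(model, "fitted_pha_model"))
  labeled <- as_calibration_set(labeled)
  if (nrow(labeled) == 0L) stop(input_error("empty dataset"))
  pred <- evaluate_model(model$structure, model$params, labeled$od)
  mean(abs(labeled$pha - pred))
}

#' Cross-validate models against datasets
#'
#' Scores every (model, dataset) pair by [mae()], the cross-validation of
#' the workflow: a model calibrated on one process is applied to the other
#' process's data and vice versa, and the per-dataset best model is
#' reported.
#'
#' @param models Named list of `fitted_pha_model` objects.
#' @param datasets Named list of [calibration_set()] objects.
#' @return A numeric matrix of MAE values (rows = models, columns =
#'   datasets) with attribute `best_per_dataset`, the row name of the
#'   minimal-MAE model for each column.
#' @export
cross_validate <- function(models, datasets) {
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  if (is.null(names(datasets))) names(datasets) <- paste0("data", seq_along(datasets))
  m <- matrix(NA_real_, nrow = length(models), ncol = length(datasets),
              dimnames = list(names(models), names(datasets)))
  for (i in seq_along(models)) {
    for (j in seq_along(datasets)) {
      m[i, j] <- mae(models[[i]], datasets[[j]])
    }
  }
  structure(m, best_per_dataset = rownames(m)[apply(m, 2, which.min)])
}
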