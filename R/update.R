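#' Policy for online model updates
#'
#' Controls how in-process measurements are folded back into the
#' calibration. New points are appended to the prior training set with an
#' elevated fitting weight so the refit "focuses" on the running process,
#' and only become usable after the analytical lag of the reference PHA
#' measurement (the HPLC assay behind the labels takes about 2 h).
#'
#' @param weight_new Positive weight applied to every new point
#'   (default 5).
#' @param lag_h Measurement lag in hours between drawing a sample and its
#'   PHA label becoming available (default 2).
#' @param allow_structure_change If `TRUE` (default) the update re-runs
#'   model selection over `candidates`; if `FALSE` only the incumbent
#'   structure is refitted (the fast path for real-time use).
#' @param candidates Catalog ids considered when re-selecting (default all
#'   13).
#' @return A list of class `update_policy`.
#' @export
update_policy <- function(weight_new = 5, lag_h = 2,
                          allow_structure_change = TRUE, candidates = 1:13) {
  if (weight_new <= 0) stop(input_error("weight_new must be positive"))
  if (lag_h < 0) stop(input_error("lag_h must be non-negative"))
  structure(list(weight_new = weight_new, lag_h = lag_h,
                 allow_structure_change = allow_structure_change,
                 candidates = candidates),
            class = "update_policy")
}

#' Extend a training set with up-weighted new measurements
#'
#' Concatenates the prior calibration set with newly measured in-process
#' points, keeping prior weights unchanged and setting every new point's
#' weight to `policy$weight_new`.
#'
#' @param prior,new_points [calibration_set()] objects.
#' @param policy An [update_policy()].
#' @return A `calibration_set` with `nrow(prior) + nrow(new_points)` rows.
#' @export
extend_training_set <- function(prior, new_points, policy = update_policy()) {
  prior <- as_calibration_set(prior)
  new_points <- as_calibration_set(new_points)
  if (nrow(new_points) > 0L) new_points$weight <- policy$weight_new
  out <- rbind(as.data.frame(prior), as.data.frame(new_points))
  structure(out, label = attr(prior, "label"),
            class = c("calibration_set", "data.frame"))
}

#' Refit (and optionally re-select) the model on an extended training set
#'
#' Implements one online update: the prior training data plus the new,
#' up-weighted measurements are refitted. With
#' `policy$allow_structure_change = TRUE` the full candidate selection is
#' re-run on the extended set; otherwise only the incumbent structure is
#' refitted. Selection metrics (RSS, AICc, R^2) are always computed at unit
#' weights — the weights steer the fit, not the scoring.
#'
#' @inheritParams extend_training_set
#' @param incumbent The current `fitted_pha_model`; required when
#'   `allow_structure_change = FALSE`, otherwise used only for provenance.
#' @param options [fit_options()] for the refits.
#' @return An `update_event` list: `usable_new_points`, `extended_n`,
#'   `refit` (the updated `fitted_pha_model`), `selection`
#'   (a `selection_table`), and `trigger_time` (`NA` unless set by
#'   [schedule_updates()]).
#' @export
update_model <- function(prior, new_points, policy = update_policy(),
                         incumbent = NULL, options = fit_options()) {
  prior <- as_calibration_set(prior)
  new_points <- as_calibration_set(new_points)
  extended <- extend_training_set(prior, new_points, policy)
  candidates <- if (policy$allow_structure_change) policy$candidates else {
    if (is.null(incumbent)) {
      stop(input_error("incumbent model required when structure is frozen"))
    }
    incumbent$structure$id
  }
  sel <- select_model(extended, candidates = candidates, options = options)
  refit <- attr(sel, "fits")[[as.character(attr(sel, "chosen"))]]
  structure(
    list(trigger_time = NA_real_, usable_new_points = nrow(new_points),
         extended_n = nrow(extended), refit = refit, selection = sel),
    class = "update_event"
  )
}

#' @export
print.update_event <- function(x, ...) {
  cat(sprintf(
    "<update event%s: %d new points, extended N = %d, chosen structure %d>\n",
    if (is.na(x$trigger_time)) "" else sprintf(" at %g h", x$trigger_time),
    x$usable_new_points, x$extended_n, x$refit$structure$id))
  invisible(x)
}

#' Schedule lagged model updates along a monitored process
#'
#' Applies the availability rule of at-line monitoring: a sample drawn at
#' time `s` has its PHA label ready at `s + lag_h`, and an update triggered
#' at time `t` (typically a process-phase change) is actually applied at
#' `t_apply`, the first sampling time at or after `t + lag_h`. The update
#' then uses every new point whose label is available by `t_apply`
#' (`s + lag_h <= t_apply`). Events are cumulative: later updates include
#' all points usable by their own apply time.
#'
#' @inheritParams update_model
#' @param new_series Time-ordered [calibration_set()] of in-process
#'   measurements (must carry `time_h`).
#' @param trigger_times Ascending numeric vector of trigger times (hours).
#' @return List of `update_event` objects, one per trigger, each with
#'   `trigger_time` set to its apply time.
#' @export
schedule_updates <- function(prior, new_series, trigger_times,
                             policy = update_policy(), incumbent = NULL,
                             options = fit_options()) {
  prior <- as_calibration_set(prior)
  new_series <- as_calibration_set(new_series)
  if (is.unsorted(trigger_times)) {
    stop(input_error("trigger_times must be ascending"))
  }
  s <- new_series$time_h
  if (nrow(new_series) > 0L && anyNA(s)) {
    stop(input_error("new_series must carry sampling times"))
  }
  lapply(trigger_times, function(t) {
    # apply time: first sampling at or after t + lag; if none, end of series
    after <- s[s >= t + policy$lag_h]
    t_apply <- if (length(after)) min(after) else {
      if (length(s)) max(s) + policy$lag_h else t + policy$lag_h
    }
    usable <- new_series[s + policy$lag_h <= t_apply, , drop = FALSE]
    ev <- update_model(prior, usable, policy = policy, incumbent = incumbent,
                       options = options)
    ev$trigger_time <- t_apply
    ev
  })
}
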