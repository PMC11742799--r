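#' Assemble a calibration dataset
#'
#' A calibration set pairs OD600 readings with measured PHA concentrations,
#' optionally carrying sampling times, replicate standard deviations and
#' per-point fitting weights. It is a plain `data.frame` subclass with
#' columns `time_h`, `od`, `od_sd`, `pha`, `pha_sd`, `weight`.
#'
#' @param od Numeric vector of OD600 means (dilution-corrected), `>= 0`.
#' @param pha Numeric vector of measured PHA concentrations (g/L), `>= 0`.
#' @param time_h Optional sampling times in hours (`NA` allowed).
#' @param od_sd,pha_sd Optional replicate standard deviations (default 0).
#' @param weight Positive fitting weights (default 1). Weights scale squared
#'   residuals in [weighted_rss()]; selection metrics ignore them.
#' @param label Free-text label for reports.
#' @return A `calibration_set` data frame.
#' @examples
#' calibration_set(od = c(1, 5, 20), pha = c(0.05, 0.4, 2.9))
#' @export
calibration_set <- function(od, pha, time_h = NA_real_, od_sd = 0,
                            pha_sd = 0, weight = 1, label = "") {
  n <- length(od)
  if (length(pha) != n) stop(input_error("od and pha must have equal length"))
  d <- data.frame(
    time_h = rep_len(as.numeric(time_h), n),
    od = as.numeric(od),
    od_sd = rep_len(as.numeric(od_sd), n),
    pha = as.numeric(pha),
    pha_sd = rep_len(as.numeric(pha_sd), n),
    weight = rep_len(as.numeric(weight), n)
  )
  validate_calibration_set(d)
  structure(d, label = label, class = c("calibration_set", "data.frame"))
}

validate_calibration_set <- function(d) {
  if (any(!is.finite(d$od)) || any(!is.finite(d$pha))) {
    stop(input_error("od and pha must be finite"))
  }
  if (any(d$od < 0) || any(d$pha < 0)) {
    stop(input_error("od and pha must be non-negative"))
  }
  if (any(!is.finite(d$weight)) || any(d$weight <= 0)) {
    stop(input_error("weights must be positive"))
  }
  if (any(stats::na.omit(c(d$od_sd, d$pha_sd)) < 0)) {
    stop(input_error("standard deviations must be non-negative"))
  }
  invisible(d)
}

as_calibration_set <- function(x) {
  if (inherits(x, "calibration_set")) return(x)
  if (is.data.frame(x)) {
    od <- if ("od" %in% names(x)) x$od else x$od_mean
    pha <- if ("pha" %in% names(x)) x$pha else x$pha_g_per_l
    return(calibration_set(
      od = od, pha = pha,
      time_h = if ("time_h" %in% names(x)) x$time_h else NA_real_,
      od_sd = if ("od_sd" %in% names(x)) ifelse(is.na(x$od_sd), 0, x$od_sd) else 0,
      pha_sd = if ("pha_sd" %in% names(x)) ifelse(is.na(x$pha_sd), 0, x$pha_sd) else 0,
      weight = if ("weight" %in% names(x)) ifelse(is.na(x$weight), 1, x$weight) else 1
    ))
  }
  stop(input_error("cannot interpret object as a calibration set"))
}

#' @export
print.calibration_set <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf("<calibration set%s: %d points, OD %.3g-%.3g, PHA %.3g-%.3g g/L>\n",
              if (nzchar(lbl)) paste0(" '", lbl, "'") else "",
              nrow(x), min(x$od), max(x$od), min(x$pha), max(x$pha)))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Residual sum of squares of a structure on calibration data
#'
#' `rss()` computes the unweighted residual sum of squares
#' `sum((y_i - f(x_i))^2)`; `weighted_rss()` computes
#' `sum(w_i * (y_i - f(x_i))^2)` and reduces to `rss()` at unit weights.
#' When any data point falls outside the structure's domain guard the
#' functions return `+Inf` (the optimiser convention: infeasible parameters
#' are ranked worse than any feasible ones, never raised as errors).
#'
#' @inheritParams evaluate_model
#' @param data A [calibration_set()].
#' @return Non-negative scalar; `+Inf` when `params` are infeasible at some
#'   data point.
#' @examples
#' d <- calibration_set(od = c(1, 2), pha = c(1, 3))
#' rss(10, c(a = 0, b = 1), d)  # (1-1)^2 + (3-2)^2 = 1
#' @export
rss <- function(structure, params, data) {
  weighted_rss(structure, params, data, use_weights = FALSE)
}

#' @rdname rss
#' @param use_weights Internal switch; `weighted_rss()` uses the `weight`
#'   column, `rss()` does not.
#' @export
weighted_rss <- function(structure, params, data, use_weights = TRUE) {
  structure <- as_structure(structure)
  data <- as_calibration_set(data)
  params <- check_params(structure, params)
  if (!guard_ok(structure, params, data$od)) return(Inf)
  r <- data$pha - structure$eval_fn(params, data$od)
  w <- if (use_weights) data$weight else 1
  s <- sum(w * r * r)
  if (!is.finite(s)) Inf else s
}

#' Control options for the simplex fit
#'
#' @param reltol Relative convergence tolerance on the objective for the
#'   Nelder-Mead search (default `1e-8`).
#' @param maxit_per_param Iteration cap per start is `maxit_per_param * M`
#'   for a structure with `M` parameters (default 400).
#' @param n_perturb Number of random multi-start perturbations of the
#'   heuristic initial guess (default 10). Each perturbation multiplies every
#'   parameter by an independent log-uniform factor in
#'   `[perturb_range[1], perturb_range[2]]`.
#' @param perturb_range Two positive numbers, default `c(0.2, 5)`.
#' @param polish_rounds The best local optimum is re-polished by restarting
#'   the simplex from it up to this many times, stopping early when the
#'   objective no longer improves (default 3). Restarting rebuilds the
#'   simplex at full size, which rescues premature collapse near flat
#'   valleys.
#' @param seed Integer seed making the random restarts reproducible
#'   (default 1); recorded in the fit provenance.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(reltol = 1e-8, maxit_per_param = 400, n_perturb = 10,
                        perturb_range = c(0.2, 5), polish_rounds = 3,
                        seed = 1L) {
  structure(list(reltol = reltol, maxit_per_param = maxit_per_param,
                 n_perturb = n_perturb, perturb_range = perturb_range,
                 polish_rounds = polish_rounds, seed = as.integer(seed)),
            class = "fit_options")
}

#' Fit one candidate structure by weighted least squares
#'
#' Minimises [weighted_rss()] with a derivative-free Nelder-Mead simplex
#' search ([stats::optim()]). The search is multi-started from the
#' deterministic heuristic guess of [initial_guess()] plus `n_perturb`
#' log-uniform perturbations of it; the best feasible local optimum is then
#' polished by simplex restarts. Parameters outside the structure's domain
#' at any data point score `+Inf`, so the simplex walks back into the
#' feasible region on its own.
#'
#' @inheritParams rss
#' @param options A [fit_options()] list.
#' @param start Optional explicit starting parameter vector; replaces the
#'   heuristic anchor (perturbed starts are still added).
#' @return A `fitted_pha_model` object with fields `structure`, `params`,
#'   `rss` (unweighted, on `data`), `n_points`, `converged`,
#'   `n_restarts_used`, `od_range` (calibration OD span, used to flag
#'   extrapolation), `seed`.
#' @examples
#' d <- calibration_set(od = c(1, 2, 3, 4), pha = c(1.1, 1.9, 3.2, 3.9))
#' fit_model(10, d)
#' @export
fit_model <- function(structure, data, options = fit_options(), start = NULL) {
  structure <- as_structure(structure)
  data <- as_calibration_set(data)
  if (nrow(data) < structure$M + 2L) {
    stop(input_error(sprintf(
      "structure %d needs at least M + 2 = %d points, got %d",
      structure$id, structure$M + 2L, nrow(data))))
  }

  objective <- function(p) {
    names(p) <- structure$param_names
    weighted_rss(structure, p, data)
  }

  anchor <- if (is.null(start)) initial_guess(structure, data) else
    check_params(structure, start)
  starts <- list(anchor)
  rng <- local_rng(options$seed + 1000L * structure$id)
  on.exit(rng(), add = TRUE)
  lo <- log(options$perturb_range[1])
  hi <- log(options$perturb_range[2])
  for (i in seq_len(options$n_perturb)) {
    fac <- exp(stats::runif(structure$M, lo, hi))
    p <- anchor * fac
    # multiplicative perturbation cannot move a zero coefficient
    p[anchor == 0] <- stats::runif(sum(anchor == 0), -0.5, 0.5)
    starts[[i + 1L]] <- p
  }

  maxit <- options$maxit_per_param * structure$M
  best <- NULL
  n_used <- 0L
  for (s in starts) {
    if (!is.finite(objective(s))) next
    n_used <- n_used + 1L
    res <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(reltol = options$reltol, maxit = maxit))
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop(structure(class = c("pha_fit_error", "error", "condition"),
                   list(message = sprintf(
                          "structure %d: no feasible start found", structure$id),
                        call = NULL, structure_id = structure$id)))
  }
  # simplex restarts from the incumbent optimum rescue premature collapse
  for (i in seq_len(options$polish_rounds)) {
    res <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(reltol = options$reltol, maxit = maxit))
    if (res$value < best$value) best <- res else break
  }

  params <- stats::setNames(as.numeric(best$par), structure$param_names)
  new_fitted_model(
    structure = structure, params = params,
    rss = rss(structure, params, data), n_points = nrow(data),
    converged = best$convergence == 0L, n_restarts_used = n_used,
    od_range = range(data$od), seed = options$seed
  )
}

new_fitted_model <- function(structure, params, rss, n_points, converged,
                             n_restarts_used, od_range, seed = NA_integer_) {
  structure(
    list(structure = structure, params = params, rss = rss,
         n_points = n_points, converged = converged,
         n_restarts_used = n_restarts_used, od_range = od_range, seed = seed),
    class = "fitted_pha_model"
  )
}

#' @export
print.fitted_pha_model <- function(x, ...) {
  cat(sprintf("<fitted PHA model: structure %d (%s)>\n",
              x$structure$id, x$structure$name))
  cat("  y =", x$structure$formula_text, "\n")
  cat("  params:", paste(sprintf("%s = %.6g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  RSS = %.6g on %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}

#' Corrected Akaike information criterion
#'
#' Small-sample corrected AIC used to rank candidate structures:
#' `AICc = N * log10(RSS / N) + 2 * M * N / (N - M - 1)`, where `N` is the
#' number of calibration points and `M` the number of fitted parameters.
#' Lower is better. Note the base-10 logarithm: it is the convention this
#' package standardises on, chosen because it reproduces the published
#' reference metrics bundled in [reference_metrics()] to within rounding
#' (a natural-log variant does not). AICc values are therefore only
#' comparable within this convention.
#'
#' @param rss_value Positive residual sum of squares. A perfect fit
#'   (`rss_value = 0`) returns `-Inf` with a warning.
#' @param n Number of data points; must exceed `m + 1`.
#' @param m Number of fitted parameters.
#' @return AICc value (scalar; `-Inf` for a perfect fit).
#' @examples
#' aicc(34.907, n = 24, m = 2)
#' @export
aicc <- function(rss_value, n, m) {
  if (n <= m + 1) {
    stop(input_error(sprintf("AICc needs n > m + 1 (n = %d, m = %d)", n, m)))
  }
  if (rss_value < 0) stop(input_error("rss_value must be non-negative"))
  if (rss_value == 0) {
    warning("AICc of a perfect fit (RSS = 0) is -Inf")
    return(-Inf)
  }
  n * log10(rss_value / n) + 2 * m * n / (n - m - 1)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - RSS / sum((y_i - mean(y))^2)` on the (unweighted) calibration
#' data. Requires at least two distinct response values.
#'
#' @inheritParams rss
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(structure, params, data) {
  data <- as_calibration_set(data)
  tss <- sum((data$pha - mean(data$pha))^2)
  if (tss == 0) stop(input_error("R^2 undefined: zero total sum of squares"))
  1 - rss(structure, params, data) / tss
}

#' Fit and rank all candidate structures
#'
#' Runs the model-selection step of the workflow: every candidate structure
#' is fitted to the calibration data by [fit_model()], then scored by
#' unweighted RSS, [aicc()] and [r_squared()], and ranked by ascending AICc.
#' Candidates that cannot be fitted (no feasible start, or too few points
#' for their parameter count) are kept in the table with `Inf` RSS and
#' excluded from the ranking.
#'
#' The `chosen` structure applies a parsimony tie-break: all candidates
#' within `tie_window` AICc units of the minimum form a tie set, and the
#' one with the fewest parameters (then the lowest id) wins. This encodes
#' the preference for a simpler structure when the information criterion
#' cannot separate candidates.
#'
#' @param data A [calibration_set()]; selection metrics always use unit
#'   weights even if `data` carries fitting weights.
#' @param candidates Integer ids of catalog structures to consider
#'   (default all 13).
#' @param options A [fit_options()] list passed to every fit.
#' @param tie_window AICc width of the tie set (default 2).
#' @return A `selection_table`: a data frame with one row per candidate
#'   (`id`, `name`, `M`, `rss`, `aicc`, `r2`, `converged`, plus one column
#'   per parameter letter), ordered by the candidate ids as given, with
#'   attributes `best_by_aicc`, `best_by_r2`, `chosen`, and `fits` (the
#'   list of `fitted_pha_model` objects keyed by id).
#' @examples
#' d <- simulate_experiment(simulation_config(seed = 7))
#' sel <- select_model(d, candidates = c(1, 4, 7, 10))
#' attr(sel, "chosen")
#' @export
select_model <- function(data, candidates = 1:13, options = fit_options(),
                         tie_window = 2) {
  data <- as_calibration_set(data)
  udata <- data
  udata$weight <- 1
  rows <- list()
  fits <- list()
  for (id in candidates) {
    st <- model_structure(id)
    fit <- tryCatch(fit_model(st, data, options = options),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$rss)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, name = st$name, M = st$M, rss = Inf, aicc = Inf,
        r2 = NA_real_, converged = FALSE)
      next
    }
    fits[[as.character(id)]] <- fit
    rss_u <- rss(st, fit$params, udata)
    a <- suppressWarnings(
      if (nrow(udata) > st$M + 1L) aicc(rss_u, nrow(udata), st$M) else Inf)
    r2 <- r_squared(st, fit$params, udata)
    row <- data.frame(id = id, name = st$name, M = st$M, rss = rss_u,
                      aicc = a, r2 = r2, converged = fit$converged)
    rows[[length(rows) + 1L]] <- row
  }
  tab <- do.call(rbind, rows)
  for (letter in c("a", "b", "c", "d", "e")) {
    tab[[letter]] <- vapply(tab$id, function(id) {
      f <- fits[[as.character(id)]]
      if (!is.null(f) && letter %in% names(f$params)) f$params[[letter]]
      else NA_real_
    }, numeric(1))
  }
  if (!length(fits)) {
    stop(structure(class = c("pha_selection_error", "error", "condition"),
                   list(message = "no candidate structure could be fitted",
                        call = NULL)))
  }
  out <- rank_choices(tab, tie_window)
  attr(out, "fits") <- fits
  out
}

rank_choices <- function(tab, tie_window = 2) {
  ranked <- tab[is.finite(tab$aicc), , drop = FALSE]
  best_aicc <- ranked$id[which.min(ranked$aicc)]
  r2ranked <- tab[is.finite(tab$r2), , drop = FALSE]
  best_r2 <- r2ranked$id[which.max(r2ranked$r2)]
  ties <- ranked[ranked$aicc <= min(ranked$aicc) + tie_window, , drop = FALSE]
  ties <- ties[order(ties$M, ties$id), , drop = FALSE]
  chosen <- ties$id[1]
  structure(tab, best_by_aicc = best_aicc, best_by_r2 = best_r2,
            chosen = chosen,
            class = c("selection_table", class(tab)))
}

#' @export
print.selection_table <- function(x, ...) {
  cat("<selection table>\n")
  show <- as.data.frame(x)[, c("id", "name", "M", "rss", "aicc", "r2")]
  show$rss <- signif(show$rss, 5)
  show$aicc <- round(show$aicc, 3)
  show$r2 <- round(show$r2, 4)
  print.data.frame(show, row.names = FALSE)
  cat(sprintf("best by AICc: %d | best by R2: %d | chosen: %d\n",
              attr(x, "best_by_aicc"), attr(x, "best_by_r2"),
              attr(x, "chosen")))
  invisible(x)
}

# Run code under a private RNG stream; returns a restorer for on.exit().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
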