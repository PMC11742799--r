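#' Catalog of candidate soft-sensor model structures
#'
#' The package calibrates PHA concentration (g/L) against optical density at
#' 600 nm using a fixed catalog of thirteen regression structures
#' `y = f(x)`, where `y` is the PHA concentration and `x` the
#' (dilution-corrected, dimensionless) OD600 reading. Structures 1-9 are
#' classical saturating/sigmoidal calibration curves; structures 10-13 are
#' polynomials of degree 1-4.
#'
#' | id | formula                          | parameters |
#' |----|----------------------------------|------------|
#' | 1  | `a*x^b`                          | a, b       |
#' | 2  | `a + b*log(x)`                   | a, b       |
#' | 3  | `a*x/(b + x)`                    | a, b       |
#' | 4  | `a*(1 - exp(-b*x))`              | a, b       |
#' | 5  | `a - b*c^x`                      | a, b, c    |
#' | 6  | `(a + b*x)/(1 + c*x)`            | a, b, c    |
#' | 7  | `a*(1 - exp(-b*x))^c`            | a, b, c    |
#' | 8  | `a*(1 - (1 + (x/c)^d)^-b)`       | a, b, c, d |
#' | 9  | `a*(1 - exp(-(b*(x - c))^d))`    | a, b, c, d |
#' | 10 | `b*x + a`                        | a, b       |
#' | 11 | `c*x^2 + b*x + a`                | a, b, c    |
#' | 12 | `d*x^3 + c*x^2 + b*x + a`        | a, b, c, d |
#' | 13 | `e*x^4 + d*x^3 + c*x^2 + b*x + a`| a, b, c, d, e |
#'
#' `log` in structure 2 is the natural logarithm (the intercept/slope pair
#' absorbs any base change).
#'
#' @return An ordered list of 13 `model_structure` objects, in catalog order.
#' @seealso [model_structure()], [evaluate_model()], [model_derivative()]
#' @examples
#' length(model_catalog())           # 13
#' model_catalog()[[13]]$M           # 5 parameters (quartic)
#' @export
model_catalog <- function() {
  .catalog
}

#' Look up one candidate model structure
#'
#' @param id Integer structure id, 1 to 13 (see [model_catalog()]).
#' @return A `model_structure` object: a list with fields `id`, `name`,
#'   `param_names`, `M` (parameter count), `formula_text`, and the internal
#'   evaluation/derivative/guard functions.
#' @examples
#' model_structure(7)$formula_text
#' @export
model_structure <- function(id) {
  if (length(id) != 1L || is.na(id) || !(id %in% 1:13)) {
    stop("structure id must be a single integer in 1..13", call. = FALSE)
  }
  .catalog[[as.integer(id)]]
}

new_model_structure <- function(id, name, param_names, formula_text,
                                eval_fn, deriv_fn, guard_fn) {
  structure(
    list(id = as.integer(id), name = name, param_names = param_names,
         M = length(param_names), formula_text = formula_text,
         eval_fn = eval_fn, deriv_fn = deriv_fn, guard_fn = guard_fn),
    class = "model_structure"
  )
}

#' @export
print.model_structure <- function(x, ...) {
  cat(sprintf("<model structure %d: %s>\n  y = %s\n  parameters (%d): %s\n",
              x$id, x$name, x$formula_text, x$M,
              paste(x$param_names, collapse = ", ")))
  invisible(x)
}

# Guards return a logical vector over x; FALSE marks inputs where the formula
# is not a finite real number for the given parameters. is_near_int() lets
# negative bases through for integer exponents (x^2 etc. are always real).
is_near_int <- function(v) abs(v - round(v)) < 1e-8

.catalog <- list(
  new_model_structure(
    1L, "power law", c("a", "b"), "a*x^b",
    eval_fn = function(p, x) p[["a"]] * x^p[["b"]],
    deriv_fn = function(p, x) p[["a"]] * p[["b"]] * x^(p[["b"]] - 1),
    guard_fn = function(p, x) {
      b <- p[["b"]]
      if (is_near_int(b)) rep(TRUE, length(x)) else x > 0 | (x == 0 & b > 0)
    }
  ),
  new_model_structure(
    2L, "logarithmic", c("a", "b"), "a + b*log(x)",
    eval_fn = function(p, x) p[["a"]] + p[["b"]] * log(x),
    deriv_fn = function(p, x) p[["b"]] / x,
    guard_fn = function(p, x) x > 0
  ),
  new_model_structure(
    3L, "hyperbolic saturation", c("a", "b"), "a*x/(b + x)",
    eval_fn = function(p, x) p[["a"]] * x / (p[["b"]] + x),
    deriv_fn = function(p, x) p[["a"]] * p[["b"]] / (p[["b"]] + x)^2,
    guard_fn = function(p, x) abs(p[["b"]] + x) > 1e-12
  ),
  new_model_structure(
    4L, "exponential rise", c("a", "b"), "a*(1 - exp(-b*x))",
    eval_fn = function(p, x) p[["a"]] * (1 - exp(-p[["b"]] * x)),
    deriv_fn = function(p, x) p[["a"]] * p[["b"]] * exp(-p[["b"]] * x),
    guard_fn = function(p, x) rep(TRUE, length(x))
  ),
  new_model_structure(
    5L, "shifted exponential", c("a", "b", "c"), "a - b*c^x",
    eval_fn = function(p, x) p[["a"]] - p[["b"]] * p[["c"]]^x,
    deriv_fn = function(p, x) -p[["b"]] * p[["c"]]^x * log(p[["c"]]),
    guard_fn = function(p, x) rep(p[["c"]] > 0, length(x))
  ),
  new_model_structure(
    6L, "rational linear", c("a", "b", "c"), "(a + b*x)/(1 + c*x)",
    eval_fn = function(p, x) (p[["a"]] + p[["b"]] * x) / (1 + p[["c"]] * x),
    deriv_fn = function(p, x) (p[["b"]] - p[["a"]] * p[["c"]]) / (1 + p[["c"]] * x)^2,
    guard_fn = function(p, x) abs(1 + p[["c"]] * x) > 1e-12
  ),
  new_model_structure(
    7L, "stretched exponential rise", c("a", "b", "c"), "a*(1 - exp(-b*x))^c",
    eval_fn = function(p, x) p[["a"]] * (1 - exp(-p[["b"]] * x))^p[["c"]],
    deriv_fn = function(p, x) {
      u <- 1 - exp(-p[["b"]] * x)
      p[["a"]] * p[["c"]] * u^(p[["c"]] - 1) * p[["b"]] * exp(-p[["b"]] * x)
    },
    guard_fn = function(p, x) {
      u <- 1 - exp(-p[["b"]] * x)
      cc <- p[["c"]]
      if (is_near_int(cc)) u >= 0 | cc >= 0 else u > 0 | (u == 0 & cc > 0)
    }
  ),
  new_model_structure(
    8L, "log-logistic rise", c("a", "b", "c", "d"), "a*(1 - (1 + (x/c)^d)^-b)",
    eval_fn = function(p, x) {
      p[["a"]] * (1 - (1 + (x / p[["c"]])^p[["d"]])^(-p[["b"]]))
    },
    deriv_fn = function(p, x) {
      r <- x / p[["c"]]
      u <- 1 + r^p[["d"]]
      p[["a"]] * p[["b"]] * u^(-p[["b"]] - 1) * p[["d"]] * r^(p[["d"]] - 1) / p[["c"]]
    },
    guard_fn = function(p, x) {
      if (p[["c"]] == 0) return(rep(FALSE, length(x)))
      r <- x / p[["c"]]
      d <- p[["d"]]
      base_ok <- if (is_near_int(d)) r != 0 | d > 0 else r > 0 | (r == 0 & d > 0)
      base_ok & (1 + ifelse(base_ok, r^d, NA_real_)) > 0
    }
  ),
  new_model_structure(
    9L, "Weibull-type rise", c("a", "b", "c", "d"), "a*(1 - exp(-(b*(x - c))^d))",
    eval_fn = function(p, x) {
      p[["a"]] * (1 - exp(-(p[["b"]] * (x - p[["c"]]))^p[["d"]]))
    },
    deriv_fn = function(p, x) {
      v <- p[["b"]] * (x - p[["c"]])
      p[["a"]] * exp(-v^p[["d"]]) * p[["d"]] * v^(p[["d"]] - 1) * p[["b"]]
    },
    guard_fn = function(p, x) {
      v <- p[["b"]] * (x - p[["c"]])
      d <- p[["d"]]
      if (is_near_int(d)) rep(TRUE, length(x)) else v > 0 | (v == 0 & d > 0)
    }
  ),
  new_model_structure(
    10L, "linear", c("a", "b"), "b*x + a",
    eval_fn = function(p, x) p[["b"]] * x + p[["a"]],
    deriv_fn = function(p, x) rep(p[["b"]], length(x)),
    guard_fn = function(p, x) rep(TRUE, length(x))
  ),
  new_model_structure(
    11L, "quadratic", c("a", "b", "c"), "c*x^2 + b*x + a",
    eval_fn = function(p, x) p[["c"]] * x^2 + p[["b"]] * x + p[["a"]],
    deriv_fn = function(p, x) 2 * p[["c"]] * x + p[["b"]],
    guard_fn = function(p, x) rep(TRUE, length(x))
  ),
  new_model_structure(
    12L, "cubic", c("a", "b", "c", "d"), "d*x^3 + c*x^2 + b*x + a",
    eval_fn = function(p, x) p[["d"]] * x^3 + p[["c"]] * x^2 + p[["b"]] * x + p[["a"]],
    deriv_fn = function(p, x) 3 * p[["d"]] * x^2 + 2 * p[["c"]] * x + p[["b"]],
    guard_fn = function(p, x) rep(TRUE, length(x))
  ),
  new_model_structure(
    13L, "quartic", c("a", "b", "c", "d", "e"),
    "e*x^4 + d*x^3 + c*x^2 + b*x + a",
    eval_fn = function(p, x) {
      p[["e"]] * x^4 + p[["d"]] * x^3 + p[["c"]] * x^2 + p[["b"]] * x + p[["a"]]
    },
    deriv_fn = function(p, x) {
      4 * p[["e"]] * x^3 + 3 * p[["d"]] * x^2 + 2 * p[["c"]] * x + p[["b"]]
    },
    guard_fn = function(p, x) rep(TRUE, length(x))
  )
)

check_params <- function(structure, params) {
  params <- unlist(params)
  if (!setequal(names(params), structure$param_names)) {
    stop(sprintf("structure %d expects parameters {%s}, got {%s}",
                 structure$id, paste(structure$param_names, collapse = ","),
                 paste(names(params), collapse = ",")), call. = FALSE)
  }
  params[structure$param_names]
}

as_structure <- function(structure) {
  if (inherits(structure, "model_structure")) structure else model_structure(structure)
}

#' Evaluate a candidate structure at given OD values
#'
#' Computes the predicted PHA concentration `f(x)` (g/L) for a catalog
#' structure at OD600 values `x`. Inputs outside the structure's domain guard
#' (for instance `x = 0` for the logarithmic structure, or a negative base
#' under a non-integer power) raise a domain error; during optimisation the
#' residual objective instead maps such points to `+Inf` (see [rss()]).
#'
#' @param structure A `model_structure` or an integer id 1-13.
#' @param params Named numeric vector (or list) with exactly the structure's
#'   parameter names drawn from `a`,...,`e`.
#' @param x Numeric vector of OD600 values.
#' @return Numeric vector of predicted PHA concentrations, same length as `x`.
#' @examples
#' evaluate_model(7, c(a = 8.2031, b = 0.0556, c = 3.1885), x = 30)
#' @export
evaluate_model <- function(structure, params, x) {
  structure <- as_structure(structure)
  params <- check_params(structure, params)
  ok <- structure$guard_fn(params, x)
  if (!all(ok)) {
    stop(domain_error(structure$id, x[!ok][1]))
  }
  y <- structure$eval_fn(params, x)
  if (any(!is.finite(y))) {
    stop(domain_error(structure$id, x[!is.finite(y)][1]))
  }
  y
}

#' Analytic derivative of a structure with respect to OD
#'
#' Returns `d f / d x` (g/L per OD unit), the local sensitivity of the
#' predicted PHA concentration to the OD reading. This slope drives the
#' first-order propagation of OD replicate noise into the prediction
#' (see [propagate_sd()]).
#'
#' @inheritParams evaluate_model
#' @return Numeric vector of slopes, same length as `x`.
#' @examples
#' model_derivative(10, c(a = 1, b = 2), x = c(0, 5))  # constant slope b
#' @export
model_derivative <- function(structure, params, x) {
  structure <- as_structure(structure)
  params <- check_params(structure, params)
  ok <- structure$guard_fn(params, x)
  if (!all(ok)) {
    stop(domain_error(structure$id, x[!ok][1]))
  }
  d <- structure$deriv_fn(params, x)
  if (any(!is.finite(d))) {
    stop(domain_error(structure$id, x[!is.finite(d)][1]))
  }
  d
}

guard_ok <- function(structure, params, x) {
  ok <- structure$guard_fn(params, x)
  if (!all(ok)) return(FALSE)
  all(is.finite(structure$eval_fn(params, x)))
}

domain_error <- function(id, x) {
  structure(
    class = c("pha_domain_error", "error", "condition"),
    list(message = sprintf(
           "structure %d: evaluation undefined at OD x = %g for these parameters",
           id, x),
         call = NULL, structure_id = id, x = x)
  )
}

input_error <- function(msg) {
  structure(class = c("pha_input_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Deterministic starting parameters for a structure
#'
#' Supplies the heuristic initial guess used as the anchor of the multi-start
#' simplex search in [fit_model()]. The heuristics are closed-form and
#' deterministic for a given dataset: ordinary least squares for the
#' polynomial structures 10-13, log-log regression for the power law,
#' semi-log regression for the logarithmic structure, `a = 1.1 * max(y)` plus
#' scale guesses for the saturating structures, and midpoint-based guesses
#' for the four-parameter sigmoids.
#'
#' @inheritParams evaluate_model
#' @param data A [calibration_set()].
#' @return Named numeric parameter vector feasible at the data's OD values.
#' @export
initial_guess <- function(structure, data) {
  structure <- as_structure(structure)
  data <- as_calibration_set(data)
  if (nrow(data) == 0L) stop(input_error("empty calibration data"))
  x <- data$od
  y <- data$pha
  xpos <- x[x > 0]
  maxy <- max(y)
  medx <- stats::median(x)
  if (medx <= 0) medx <- max(stats::median(xpos, na.rm = TRUE), 1, na.rm = TRUE)

  polyfit <- function(deg) {
    cf <- stats::coef(stats::lm(y ~ stats::poly(x, deg, raw = TRUE)))
    cf[is.na(cf)] <- 0
    stats::setNames(as.numeric(cf), letters[seq_len(deg + 1L)])
  }

  switch(as.character(structure$id),
    "1" = { # log-log OLS on strictly positive pairs
      keep <- x > 0 & y > 0
      if (sum(keep) >= 2) {
        cf <- stats::coef(stats::lm(log(y[keep]) ~ log(x[keep])))
        c(a = exp(unname(cf[1])), b = unname(cf[2]))
      } else c(a = max(maxy, 0.1), b = 1)
    },
    "2" = { # semi-log OLS
      keep <- x > 0
      if (sum(keep) >= 2) {
        cf <- stats::coef(stats::lm(y[keep] ~ log(x[keep])))
        c(a = unname(cf[1]), b = unname(cf[2]))
      } else c(a = mean(y), b = 1)
    },
    "3" = c(a = 1.1 * maxy, b = medx),
    "4" = c(a = 1.1 * maxy, b = 1 / medx),
    "5" = c(a = 1.1 * maxy, b = max(1.1 * maxy - min(y), 0.1), c = 0.9),
    "6" = { # a near the intercept, b from the endpoint slope, small curvature
      ord <- order(x)
      xs <- x[ord]; ys <- y[ord]
      slope <- if (xs[length(xs)] > xs[1]) {
        (ys[length(ys)] - ys[1]) / (xs[length(xs)] - xs[1])
      } else 0
      c(a = min(y), b = slope, c = 0.01)
    },
    "7" = c(a = 1.1 * maxy, b = 1 / medx, c = 1),
    "8" = c(a = 1.1 * maxy, b = 1, c = medx, d = 2),
    "9" = c(a = 1.1 * maxy, b = 1 / medx, c = 0.25 * max(min(x), 0), d = 1),
    "10" = polyfit(1),
    "11" = polyfit(2),
    "12" = polyfit(3),
    "13" = polyfit(4)
  )
}
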