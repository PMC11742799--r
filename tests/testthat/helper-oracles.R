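# Shared oracles and generators, independent of the implementation paths
# they check.

# central finite difference slope of a structure's formula
fd_slope <- function(structure, params, x, h = 1e-6 * max(1, abs(x))) {
  (evaluate_model(structure, params, x + h) -
     evaluate_model(structure, params, x - h)) / (2 * h)
}

# draw one feasible (structure, params, x) triple; params are sampled in
# ranges where each formula is smooth and real over x in [0.5, 50]
random_feasible_triple <- function() {
  id <- sample(1:13, 1)
  x <- runif(1, 0.5, 50)
  params <- switch(as.character(id),
    "1" = c(a = runif(1, 0.01, 2), b = runif(1, 0.3, 2)),
    "2" = c(a = runif(1, -1, 1), b = runif(1, 0.1, 3)),
    "3" = c(a = runif(1, 1, 10), b = runif(1, 1, 30)),
    "4" = c(a = runif(1, 1, 10), b = runif(1, 0.02, 0.5)),
    "5" = c(a = runif(1, 1, 10), b = runif(1, 0.5, 5), c = runif(1, 0.5, 0.99)),
    "6" = c(a = runif(1, -1, 1), b = runif(1, 0.05, 1), c = runif(1, 0.001, 0.1)),
    "7" = c(a = runif(1, 1, 10), b = runif(1, 0.02, 0.5), c = runif(1, 0.5, 4)),
    "8" = c(a = runif(1, 1, 10), b = runif(1, 0.5, 3), c = runif(1, 5, 30),
            d = runif(1, 1, 3)),
    "9" = c(a = runif(1, 1, 10), b = runif(1, 0.02, 0.5), c = runif(1, 0, 0.4),
            d = runif(1, 1, 3)),
    "10" = c(a = runif(1, -1, 1), b = runif(1, -0.5, 0.5)),
    "11" = c(a = runif(1, -1, 1), b = runif(1, -0.5, 0.5), c = runif(1, -0.01, 0.01)),
    "12" = c(a = runif(1, -1, 1), b = runif(1, -0.5, 0.5), c = runif(1, -0.01, 0.01),
             d = runif(1, -1e-4, 1e-4)),
    "13" = c(a = runif(1, -1, 1), b = runif(1, -0.5, 0.5), c = runif(1, -0.01, 0.01),
             d = runif(1, -1e-4, 1e-4), e = runif(1, -1e-6, 1e-6))
  )
  list(id = id, params = params, x = x)
}

# Assert an analytic slope agrees with the central-difference oracle to
# relative 1e-6. The oracle itself carries cancellation noise of order
# |f| * eps / h (~1e-11 absolute here), so slopes below that floor are
# compared against it, not against a meaningless relative error.
expect_slope_match <- function(id, params, x) {
  an <- model_derivative(id, params, x)
  fd <- fd_slope(id, params, x)
  noise_floor <- 1e-9 * max(1, abs(evaluate_model(id, params, x)))
  expect_lt(abs(an - fd), 1e-6 * abs(fd) + noise_floor,
            label = sprintf("structure %d slope gap at x=%.4f", id, x))
}

# small noiseless dataset generated from a structure (self-consistency oracle)
noiseless_set <- function(id, params, od = seq(1, 55, length.out = 24)) {
  calibration_set(od = od, pha = evaluate_model(id, params, od))
}

phb_params <- c(a = 8.2031, b = 0.0556, c = 3.1885)
phbv_params <- c(a = 0.0404, b = 1.4341)
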