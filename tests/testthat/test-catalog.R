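test_that("catalog enumerates the 13 structures with the expected arity", {
  cat13 <- model_catalog()
  expect_length(cat13, 13L)
  ids <- vapply(cat13, `[[`, integer(1), "id")
  expect_identical(ids, 1:13)
  expect_identical(vapply(cat13, `[[`, integer(1), "M"),
                   c(2L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 2L, 3L, 4L, 5L))
  for (st in cat13) {
    expect_identical(st$M, length(st$param_names))
    expect_true(all(st$param_names %in% c("a", "b", "c", "d", "e")))
  }
})

test_that("evaluation matches direct arithmetic at anchor points", {
  # saturating structure is pinned to 0 at OD 0
  expect_identical(evaluate_model(7, phb_params, 0), 0)
  # power law at OD 1 returns its prefactor
  expect_identical(evaluate_model(1, phbv_params, 1), 0.0404)
  # direct high-precision arithmetic of the structure-7 formula
  expect_equal(evaluate_model(7, phb_params, 30),
               8.2031 * (1 - exp(-0.0556 * 30))^3.1885, tolerance = 1e-14)
  expect_equal(evaluate_model(7, phb_params, 30), 4.21, tolerance = 1e-2)
})

test_that("parameter vectors are checked against the owning structure", {
  expect_error(evaluate_model(7, c(a = 1, b = 1), 1), "expects parameters")
  expect_error(evaluate_model(10, c(a = 1, b = 1, c = 1), 1),
               "expects parameters")
  # order does not matter, names do
  expect_identical(evaluate_model(10, c(b = 2, a = 1), 3),
                   evaluate_model(10, c(a = 1, b = 2), 3))
})

test_that("domain guards reject undefined evaluations", {
  expect_error(evaluate_model(2, c(a = 1, b = 1), 0),
               class = "pha_domain_error")
  expect_error(evaluate_model(1, c(a = 1, b = -0.5), 0),
               class = "pha_domain_error")
  # structure 9 with a non-integer power needs b*(x - c) >= 0
  expect_error(evaluate_model(9, c(a = 1, b = 1, c = 5, d = 0.5), 1),
               class = "pha_domain_error")
  expect_silent(evaluate_model(9, c(a = 1, b = 1, c = 5, d = 0.5), 6))
})

test_that("analytic derivatives agree with central finite differences", {
  expect_identical(model_derivative(10, c(a = 3, b = -0.7), 12.3), -0.7)
  # exponential-rise slope at the origin is a*b
  expect_equal(model_derivative(4, c(a = 5, b = 0.2), 0), 1, tolerance = 1e-12)
  expect_equal(model_derivative(7, phb_params, 30), fd_slope(7, phb_params, 30),
               tolerance = 1e-6)
  set.seed(101)
  for (i in 1:100) {
    tr <- random_feasible_triple()
    expect_slope_match(tr$id, tr$params, tr$x)
  }
})

test_that("evaluation is continuous on the guard region", {
  set.seed(202)
  for (i in 1:30) {
    tr <- random_feasible_triple()
    h <- c(1e-2, 1e-4, 1e-6)
    gaps <- abs(evaluate_model(tr$id, tr$params, tr$x + h) -
                  evaluate_model(tr$id, tr$params, tr$x))
    expect_true(all(diff(gaps) <= 1e-8 + 0.01 * abs(gaps[-3])),
                label = sprintf("structure %d shrinkage", tr$id))
    expect_lt(gaps[3], 1e-4 * max(1, abs(evaluate_model(tr$id, tr$params, tr$x))))
  }
})

test_that("polynomial structures nest exactly", {
  x <- seq(0, 60, by = 2.5)
  p <- c(a = 0.3, b = -0.12, c = 0.045, d = 0, e = 0)
  q13 <- evaluate_model(13, p, x)
  expect_equal(q13, evaluate_model(12, p[c("a", "b", "c", "d")], x),
               tolerance = 1e-12)
  expect_equal(q13, evaluate_model(11, p[c("a", "b", "c")], x),
               tolerance = 1e-12)
  p2 <- c(a = 1.5, b = 0.8, c = 0, d = 0, e = 0)
  expect_equal(evaluate_model(13, p2, x),
               evaluate_model(10, p2[c("a", "b")], x), tolerance = 1e-12)
})

test_that("initial guesses are deterministic, feasible, and sensible", {
  d <- calibration_set(od = c(0, 1), pha = c(0, 1))
  expect_equal(initial_guess(10, d), c(a = 0, b = 1), tolerance = 1e-12)

  d4 <- calibration_set(od = c(1, 2, 4, 8), pha = c(1, 2.5, 4, 5))
  g4 <- initial_guess(4, d4)
  expect_equal(g4[["a"]], 5.5)               # 1.1 * max(y)
  expect_equal(g4[["b"]], 1 / median(c(1, 2, 4, 8)))

  # log-log regression is exact on noiseless power-law data
  d1 <- noiseless_set(1, c(a = 0.04, b = 1.43), od = c(2, 5, 10, 20, 40))
  g1 <- initial_guess(1, d1)
  expect_equal(g1[["a"]], 0.04, tolerance = 0.2 * 0.04)
  expect_equal(g1[["b"]], 1.43, tolerance = 0.2 * 1.43)

  for (id in 1:13) {
    d <- noiseless_set(7, phb_params)
    g <- initial_guess(id, d)
    expect_named(g, model_structure(id)$param_names)
    expect_true(is.finite(rss(id, g, d)),
                label = sprintf("structure %d guess feasible", id))
    expect_identical(g, initial_guess(id, d))
  }
  expect_error(initial_guess(4, calibration_set(numeric(0), numeric(0))),
               class = "pha_input_error")
})
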