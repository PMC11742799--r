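test_that("rss and weighted_rss follow the least-squares definitions", {
  d <- calibration_set(od = c(1, 2), pha = c(1, 3))
  expect_identical(rss(10, c(a = 0, b = 1), d), 1)
  # perfect fit scores exactly zero
  expect_identical(rss(10, c(a = -1, b = 2), d), 0)
  d1 <- noiseless_set(1, phbv_params, od = c(1, 5, 10, 20, 30))
  expect_lt(rss(1, phbv_params, d1), 1e-18)

  dw <- calibration_set(od = 2, pha = 5, weight = 5)
  expect_identical(weighted_rss(10, c(a = 1, b = 1), dw), 5 * 2^2)
  expect_identical(weighted_rss(10, c(a = 0, b = 1), d), rss(10, c(a = 0, b = 1), d))
})

test_that("integer weights equal physical row replication", {
  set.seed(11)
  od <- runif(10, 1, 40)
  pha <- pmax(0.1 * od + rnorm(10, sd = 0.4), 0)
  w <- sample(1:4, 10, replace = TRUE)
  weighted <- calibration_set(od = od, pha = pha, weight = w)
  replicated <- calibration_set(od = rep(od, w), pha = rep(pha, w))
  for (p in list(c(a = 0, b = 0.1), c(a = 0.3, b = 0.08))) {
    expect_identical(weighted_rss(10, p, weighted), rss(10, p, replicated))
  }
})

test_that("infeasible parameters score +Inf instead of raising", {
  d <- calibration_set(od = c(0, 1, 2), pha = c(0, 1, 2))
  expect_identical(rss(2, c(a = 1, b = 1), d), Inf)  # log(0) point
  expect_identical(weighted_rss(2, c(a = 1, b = 1), d), Inf)
})

test_that("aicc matches the published reference values and identities", {
  expect_equal(aicc(34.907, 24, 2), 8.476, tolerance = 0.01)
  expect_equal(aicc(0.133, 24, 2), -49.582, tolerance = 0.01)
  # scaling RSS tenfold at fixed n shifts AICc by exactly n (base-10 log)
  expect_equal(aicc(1.0, 24, 3) + 24, aicc(10.0, 24, 3), tolerance = 1e-10)
  # strictly increasing in M at fixed n, RSS; and in RSS at fixed n, M
  a_by_m <- vapply(2:6, function(m) aicc(1.0, 24, m), numeric(1))
  expect_true(all(diff(a_by_m) > 0))
  a_by_rss <- vapply(c(0.1, 0.5, 1, 5, 50), function(r) aicc(r, 24, 2),
                     numeric(1))
  expect_true(all(diff(a_by_rss) > 0))
  expect_error(aicc(1.0, 4, 3), class = "pha_input_error")
  expect_warning(expect_identical(aicc(0, 24, 2), -Inf), "perfect fit")
})

test_that("the reference metric table is internally consistent", {
  m <- reference_metrics()
  expect_identical(nrow(m), 26L)
  # AICc reconstruction from printed RSS and M, N = 24, base-10 log
  rebuilt <- mapply(aicc, m$rss, 24, m$M)
  expect_true(all(abs(rebuilt - m$aicc) <= 0.05))
  # within each process, RSS/(1 - R2) implies the same total sum of squares
  for (proc in c("PHB", "PHBV")) {
    sub <- m[m$process == proc & m$r2 < 0.99, ]
    tss <- sub$rss / (1 - sub$r2)
    expect_lt(max(abs(tss - median(tss)) / median(tss)), 0.03,
              label = paste(proc, "implied TSS spread"))
  }
})

test_that("r_squared follows its definition", {
  d <- calibration_set(od = c(1, 2), pha = c(1, 3))
  expect_identical(r_squared(10, c(a = -1, b = 2), d), 1)  # perfect fit
  expect_identical(r_squared(10, c(a = 2, b = 0), d), 0)   # constant at mean
  expect_identical(r_squared(10, c(a = 0, b = 1), d), 0.5) # RSS 1, TSS 2
  expect_error(r_squared(10, c(a = 0, b = 1),
                         calibration_set(od = c(1, 2), pha = c(2, 2))),
               class = "pha_input_error")
})

test_that("simplex fit of the linear structure matches closed-form OLS", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    od <- runif(n, 0, 50)
    pha <- pmax(runif(1, 0, 1) + runif(1, 0, 0.3) * od + rnorm(n, sd = 0.3), 0)
    d <- calibration_set(od = od, pha = pha)
    f <- fit_model(10, d)
    ols <- stats::coef(stats::lm(pha ~ od))
    expect_equal(f$params[["a"]], ols[[1]], tolerance = 1e-6)
    expect_equal(f$params[["b"]], ols[[2]], tolerance = 1e-6)
  }
  # degenerate case: constant response
  dc <- calibration_set(od = c(1, 2, 3, 4), pha = rep(2.5, 4))
  fc <- fit_model(10, dc)
  expect_equal(fc$params[["a"]], 2.5, tolerance = 1e-6)
  expect_equal(fc$params[["b"]], 0, tolerance = 1e-6)
})

test_that("fit recovers known parameters from noiseless data", {
  od <- seq(1, 60, length.out = 24)
  truth <- c(a = 8, b = 0.05)
  f <- fit_model(4, noiseless_set(4, truth, od))
  expect_true(all(abs(f$params - truth) / abs(truth) < 1e-3))
  expect_lt(f$rss, 1e-10)
  expect_true(f$converged)
  # recorded RSS equals RSS recomputed from the stored parameters
  expect_equal(f$rss, rss(4, f$params, noiseless_set(4, truth, od)),
               tolerance = 1e-9)
})

test_that("fit refuses under-determined problems", {
  d <- calibration_set(od = c(1, 2, 3), pha = c(1, 2, 3))
  expect_error(fit_model(11, d), class = "pha_input_error")  # 3 points, M=3
})

test_that("selection ranks by AICc with a parsimony tie-break", {
  m <- reference_metrics()
  phb <- rank_metrics(m[m$process == "PHB", ])
  expect_identical(attr(phb, "best_by_aicc"), 7L)
  expect_identical(attr(phb, "chosen"), 7L)
  phbv <- rank_metrics(m[m$process == "PHBV", ])
  expect_identical(attr(phbv, "best_by_aicc"), 1L)
  expect_identical(attr(phbv, "best_by_r2"), 13L)
  # structures 1 (M=2) and 6 (M=3) tie within 2 AICc units: parsimony wins
  expect_identical(attr(phbv, "chosen"), 1L)

  # synthetic tie: identical AICc, different parameter counts
  tab <- data.frame(id = c(12L, 4L), M = c(4L, 2L), rss = c(1, 1.2),
                    aicc = c(-20.0, -19.5), r2 = c(0.99, 0.98))
  expect_identical(attr(rank_metrics(tab), "chosen"), 4L)
})

test_that("select_model fits, scores and chooses on real-shaped data", {
  d <- simulate_experiment(simulation_config(seed = 5))
  sel <- select_model(d, candidates = c(1, 4, 7, 10))
  expect_identical(nrow(sel), 4L)
  expect_true(all(c("rss", "aicc", "r2") %in% names(sel)))
  best <- attr(sel, "best_by_aicc")
  expect_identical(sel$aicc[sel$id == best], min(sel$aicc[is.finite(sel$aicc)]))
  fits <- attr(sel, "fits")
  expect_s3_class(fits[[as.character(attr(sel, "chosen"))]], "fitted_pha_model")
  # selection metrics ignore fitting weights
  dw <- d
  dw$weight <- 5
  selw <- select_model(dw, candidates = c(7), options = fit_options())
  expect_equal(selw$rss, rss(7, attr(selw, "fits")[["7"]]$params, d),
               tolerance = 1e-12)
})
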