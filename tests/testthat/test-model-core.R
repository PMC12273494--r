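test_that("reduce_absorbance is the affine map between endpoints", {
  expect_equal(reduce_absorbance(1.7, a0 = 1.7, a_inf = 0.2), 1)
  expect_equal(reduce_absorbance(0.2, a0 = 1.7, a_inf = 0.2), 0)
  expect_equal(reduce_absorbance(0.95, a0 = 1.7, a_inf = 0.2), 0.5)
  # order-preserving when a0 > a_inf
  x <- c(1.7, 1.2, 0.6, 0.2)
  expect_true(all(diff(reduce_absorbance(x, 1.7, 0.2)) < 0))
  expect_error(reduce_absorbance(numeric(0), 1.7, 0.2), "empty")
  expect_error(reduce_absorbance(1, 0.5, 0.5), "degenerate")
})

test_that("weibull_survival has the endpoint, characteristic-time and
           first-order limits", {
  expect_equal(weibull_survival(0, 26.5, 5.1), 1)
  expect_equal(weibull_survival(12, 12, 7.3), exp(-1))
  # 63% decrease at t = alpha, for any shape
  for (b in c(1, 2.3, 5.1, 8)) {
    expect_equal(1 - weibull_survival(20, 20, b), 1 - exp(-1))
  }
  # exponential half-life closed form at beta = 1
  expect_equal(weibull_survival(10 * log(2), 10, 1), 0.5)
  # beta = 1 reduces to first-order kinetics with rate 1/alpha everywhere
  tt <- seq(0, 60, by = 0.5)
  expect_identical(weibull_survival(tt, 15, 1), exp(-tt / 15))
  # strictly decreasing, (0, 1]
  s <- weibull_survival(tt, 22, 3.1)
  expect_true(all(diff(s) < 0) && all(s > 0) && all(s <= 1))
  expect_error(weibull_survival(-1, 10, 2), "non-negative")
  expect_error(weibull_survival(1, -10, 2), "alpha")
  expect_error(weibull_survival(1, 10, 0), "beta")
})

test_that("weibull_pdf matches the closed form and its calculus", {
  expect_equal(weibull_pdf(0, 26.5, 5.1), 0)
  expect_equal(weibull_pdf(11, 26.5, 5.1), 0.005173979249, tolerance = 1e-9)
  expect_error(weibull_pdf(0, 10, 0.7), "singular")
  # explicit formula agreement (independent of dweibull)
  tt <- seq(0.5, 80, by = 0.5)
  for (p in list(c(26.5, 5.1), c(22.3, 2.3), c(15, 1))) {
    manual <- (p[2] / p[1]) * (tt / p[1])^(p[2] - 1) * exp(-(tt / p[1])^p[2])
    expect_equal(weibull_pdf(tt, p[1], p[2]), manual, tolerance = 1e-12)
  }
  # pdf == -d(survival)/dt by central finite difference, 20 random pairs
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 5, 50); b <- runif(1, 1.5, 7)
    tg <- seq(0.05, 3 * a, length.out = 40)
    h <- 1e-6
    fd <- -(weibull_survival(tg + h, a, b) -
              weibull_survival(tg - h, a, b)) / (2 * h)
    expect_equal(weibull_pdf(tg, a, b), fd, tolerance = 1e-5)
  }
  # density integrates to 1 over [0, 10 alpha] for beta in [1, 8]
  for (b in c(1, 2, 4, 8)) {
    int <- stats::integrate(weibull_pdf, 0, 10 * 20, alpha = 20, beta = b,
                            rel.tol = 1e-10)$value
    expect_gte(int, 0.999)
    expect_lte(int, 1.0)
  }
})

test_that("weibull_mode matches the closed form and the grid argmax", {
  expect_equal(weibull_mode(20, 2), 20 * sqrt(0.5))
  expect_equal(weibull_mode(26.5, 5.1), 25.38986, tolerance = 1e-6)
  # beta -> 1+ pushes the mode to 0
  expect_lt(weibull_mode(20, 1.0001), 0.1)
  expect_error(weibull_mode(20, 1), "undefined")
  expect_error(weibull_mode(20, 0.8), "undefined")
  # grid argmax agreement
  tg <- seq(0.01, 60, by = 0.01)
  for (p in list(c(26.5, 5.1), c(16.1, 2.2))) {
    expect_equal(weibull_mode(p[1], p[2]),
                 tg[which.max(weibull_pdf(tg, p[1], p[2]))],
                 tolerance = 1e-2)
  }
})

test_that("solve_lag_phase finds the rising-branch threshold crossing", {
  # printed parameter pairs reproduce the printed lag phases within their CI
  tab <- table2_params()
  for (i in seq_len(nrow(tab))) {
    lp <- solve_lag_phase(tab$alpha[i], tab$beta[i])
    expect_lt(abs(as.numeric(lp) - tab$lagp[i]), tab$lagp_hw[i])
  }
  # frozen grid-scan value
  expect_equal(as.numeric(solve_lag_phase(10, 3)), 1.292388594,
               tolerance = 1e-7)
  # root quality and first-crossing side
  r <- as.numeric(solve_lag_phase(26.5, 5.1))
  expect_lt(abs(weibull_pdf(r, 26.5, 5.1) - 5e-3), 1e-8)
  expect_lte(r, weibull_mode(26.5, 5.1))
  # no induction phase for non-sigmoidal kinetics
  lp1 <- solve_lag_phase(15, 1)
  expect_identical(as.numeric(lp1), 0)
  expect_true(attr(lp1, "no_lag"))
  lp09 <- solve_lag_phase(15, 0.9)
  expect_true(attr(lp09, "no_lag"))
  # already above threshold at the origin's shoulder
  lp_fast <- solve_lag_phase(0.5, 1.0000001)
  expect_identical(as.numeric(lp_fast), 0)
  expect_true(attr(lp_fast, "no_lag"))
  # density maximum below threshold: no crossing exists
  expect_error(solve_lag_phase(1000, 2), "no lag-phase crossing")
  expect_error(solve_lag_phase(10, 3, threshold = -1), "threshold")
})

test_that("solve_lag_phase agrees with the brute-force grid oracle and is
           monotone in the scale parameter", {
  set.seed(7)
  for (i in 1:50) {
    a <- runif(1, 5, 50); b <- runif(1, 1.5, 7)
    expect_lt(abs(as.numeric(solve_lag_phase(a, b)) - lag_grid_scan(a, b)),
              2e-4)
  }
  for (b in c(2.3, 3.8, 5.1)) {
    lags <- vapply(seq(10, 40, by = 2),
                   function(a) as.numeric(solve_lag_phase(a, b)), numeric(1))
    expect_true(all(diff(lags) > 0))
  }
})

test_that("reduced_curve validates its invariants and flags outliers", {
  cv <- reduced_curve(c(0, 1, 2), c(1, 0.6, 0.1))
  expect_s3_class(cv, "reduced_curve")
  expect_identical(attr(cv, "n_out_of_band"), 0L)
  noisy <- reduced_curve(c(0, 1, 2), c(1.2, 0.6, -0.15))
  expect_identical(attr(noisy, "n_out_of_band"), 2L)
  expect_error(reduced_curve(c(0, 1), c(1, 0.5, 0)), "same length")
  expect_error(reduced_curve(c(2, 1), c(1, 0.5)), "increasing")
  expect_error(reduced_curve(numeric(0), numeric(0)), "empty")
})
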