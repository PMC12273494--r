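test_that("estimate_endpoints recovers endpoints and enforces the plateau", {
  # constant tail: a_inf is an exact mean
  cv <- data.frame(time_h = 0:19,
                   absorbance = c(seq(1.7, 0.2, length.out = 10),
                                  rep(0.2, 10)))
  ep <- estimate_endpoints(cv, n_head = 1, n_tail = 5)
  expect_equal(ep$a_inf, 0.2)
  # noiseless generator round trip
  spec <- simulation_spec(20, 4, noise_sd = 0)
  cur <- generate_curve(spec, seed = 1)
  ep2 <- estimate_endpoints(cur[cur$replicate == 1, ])
  expect_equal(ep2$a0, 1.7, tolerance = 1e-3)
  expect_equal(ep2$a_inf, 0.1, tolerance = 1e-2)
  # truncated before the plateau
  trunc <- cur[cur$replicate == 1 & cur$time_h <= 22, ]
  expect_error(estimate_endpoints(trunc), "plateau not reached")
  # a noisy but flat tail passes the exceedance test
  set.seed(5)
  noisy <- cur[cur$replicate == 1, ]
  noisy$absorbance <- noisy$absorbance + rnorm(nrow(noisy), 0, 0.01)
  expect_s3_class(estimate_endpoints(noisy), "endpoint_estimate")
  expect_error(estimate_endpoints(cv[1:10, ]), "at least n_head")
})

test_that("fit_weibull recovers generating parameters from noiseless data", {
  fit <- fit_weibull(noiseless_curve(26.5, 5.1))
  expect_equal(fit$alpha, 26.5, tolerance = 1e-3)
  expect_equal(fit$beta, 5.1, tolerance = 1e-3)
  expect_lt(fit$rmse, 1e-6)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  # model nesting: exponential data give beta = 1
  fit1 <- fit_weibull(noiseless_curve(15, 1))
  expect_equal(fit1$beta, 1, tolerance = 1e-3)
  expect_equal(fit1$alpha, 15, tolerance = 1e-3)
  # round trip across random parameter pairs
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 5, 50); b <- runif(1, 1.5, 7)
    f <- fit_weibull(noiseless_curve(a, b))
    expect_equal(f$alpha, a, tolerance = 1e-3)
    expect_equal(f$beta, b, tolerance = 1e-3)
  }
})

test_that("fit_weibull rejects degenerate inputs", {
  expect_error(fit_weibull(reduced_curve(0:4, rep(0.5, 5))), "time points")
  expect_error(fit_weibull(reduced_curve(0:9, rep(0.5, 10))), "no signal")
  expect_warning(
    fit_weibull(reduced_curve(seq(0.5, 5, by = 0.5),
                              weibull_survival(seq(0.5, 5, by = 0.5) + 30,
                                               26.5, 5.1))),
    "unreliable")
})

test_that("pooling identical replicates keeps estimates, narrows intervals", {
  set.seed(3)
  tt <- simulation_spec(22, 4)$schedule
  one <- reduced_curve(tt, weibull_survival(tt, 22, 4) +
                         rnorm(length(tt), 0, 0.01))
  f1 <- fit_weibull(one)
  f3 <- fit_weibull(list(one, one, one))
  expect_equal(f3$alpha, f1$alpha, tolerance = 1e-6)
  expect_equal(f3$beta, f1$beta, tolerance = 1e-6)
  expect_true(f3$pooled)
  expect_false(f1$pooled)
  expect_lt(diff(f3$ci_alpha), diff(f1$ci_alpha))
  expect_lt(diff(f3$ci_beta), diff(f1$ci_beta))
})

test_that("triplicate noisy fits land inside the printed intervals most of
           the time", {
  tab <- table2_params()
  row <- tab[1L, ]  # strongest-protection condition
  hits <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    spec <- simulation_spec(row$alpha, row$beta, noise_sd = 0.01,
                           condition_label = row$condition)
    cur <- generate_curve(spec, seed = 1000 + r)
    curves <- lapply(1:3, function(k) {
      cv <- cur[cur$replicate == k, ]
      ep <- estimate_endpoints(cv)
      reduced_curve(cv$time_h,
                    reduce_absorbance(cv$absorbance, ep$a0, ep$a_inf))
    })
    f <- fit_weibull(curves)
    if (abs(f$alpha - row$alpha) < 0.3 && abs(f$beta - row$beta) < 0.3) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("goodness_of_fit computes rmse and adjusted R2", {
  cv <- noiseless_curve(20, 3)
  fit <- fit_weibull(cv)
  g <- goodness_of_fit(fit)
  expect_lt(g$rmse, 1e-8)
  expect_equal(g$adj_r2, 1, tolerance = 1e-12)
  # constant offset appears directly as rmse
  off <- reduced_curve(cv$time_h, cv$a_star + 0.05)
  g2 <- goodness_of_fit(fit, off)
  expect_equal(g2$rmse, 0.05, tolerance = 1e-9)
  # rmse tracks the noise level
  set.seed(21)
  tt <- seq(0, 58, by = 2)
  noisy <- reduced_curve(tt, weibull_survival(tt, 25, 4) +
                           rnorm(length(tt), 0, 0.05))
  fr <- fit_weibull(noisy)
  expect_lt(abs(fr$rmse - 0.05) / 0.05, 0.3)
  expect_error(goodness_of_fit(fit, reduced_curve(0:2, c(1, 0.5, 0.2))),
               "insufficient")
})

test_that("residual gradient vanishes at the optimum", {
  set.seed(9)
  tt <- simulation_spec(24, 4.2)$schedule
  cv <- reduced_curve(tt, weibull_survival(tt, 24, 4.2) +
                        rnorm(length(tt), 0, 0.02))
  f <- fit_weibull(cv)
  ssr <- function(p) sum((cv$a_star - weibull_survival(cv$time_h,
                                                       p[1], p[2]))^2)
  h <- 1e-6
  g_a <- (ssr(c(f$alpha + h, f$beta)) - ssr(c(f$alpha - h, f$beta))) / (2 * h)
  g_b <- (ssr(c(f$alpha, f$beta + h)) - ssr(c(f$alpha, f$beta - h))) / (2 * h)
  expect_lt(sqrt(g_a^2 + g_b^2), 1e-4)
})

test_that("Wald intervals behave: nesting, near-zero width, coverage", {
  fit <- fit_weibull(noiseless_curve(26.5, 5.1))
  expect_lt(diff(fit$ci_alpha), 1e-4)
  ci95 <- parameter_confidence_intervals(fit, 0.95)
  ci99 <- parameter_confidence_intervals(fit, 0.99)
  expect_lte(ci99$ci_alpha[1], ci95$ci_alpha[1])
  expect_gte(ci99$ci_alpha[2], ci95$ci_alpha[2])
  expect_error(parameter_confidence_intervals(fit, 1.2), "level")

  # empirical coverage of the true scale parameter
  set.seed(31)
  tt <- seq(0, 58, by = 2)
  n_rep <- 200L
  covered <- 0L
  for (r in seq_len(n_rep)) {
    cv <- reduced_curve(tt, weibull_survival(tt, 25, 4) +
                          rnorm(length(tt), 0, 0.01))
    f <- fit_weibull(cv)
    if (f$ci_alpha[1] <= 25 && 25 <= f$ci_alpha[2]) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.90)
})

test_that("fitted scale and derived lag phase are positively associated
           across a condition panel", {
  panel <- gradient_panel(n = 12, seed = 2)
  fits <- lapply(seq_len(nrow(panel)), function(i) {
    spec <- simulation_spec(panel$alpha[i], panel$beta[i], noise_sd = 0.01)
    cur <- generate_curve(spec, seed = 300 + i)
    curves <- lapply(1:3, function(k) {
      cv <- cur[cur$replicate == k, ]
      ep <- estimate_endpoints(cv)
      reduced_curve(cv$time_h,
                    reduce_absorbance(cv$absorbance, ep$a0, ep$a_inf))
    })
    fit_weibull(curves)
  })
  alpha_hat <- vapply(fits, function(f) f$alpha, numeric(1))
  lag_hat <- vapply(fits, function(f)
    as.numeric(solve_lag_phase(f$alpha, f$beta)), numeric(1))
  expect_gt(cor(alpha_hat, lag_hat), 0.8)
})
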