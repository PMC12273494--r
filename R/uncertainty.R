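#' Monte-Carlo confidence interval for the lag phase
#'
#' Propagates the uncertainty of the fitted Weibull parameters to the lag
#' phase. Parameter pairs are drawn `mc_iterations` times (default 10,000),
#' the lag phase is solved for each draw via [solve_lag_phase()], and the
#' percentile interval of the draws at `level` forms the confidence
#' interval. The reported point value is the lag phase at the fitted point
#' estimate, not a draw summary.
#'
#' Two sampling laws are available:
#' \describe{
#'   \item{`"covariance-normal"`}{bivariate normal with the fit's
#'     delta-method covariance; preserves the alpha-beta correlation and is
#'     the default.}
#'   \item{`"independent-normal"`}{independent normals per parameter with
#'     standard deviation = CI half-width / 1.96; useful when only marginal
#'     confidence intervals are available (e.g. published tables).}
#' }
#' Draws with a non-positive parameter are rejected and resampled. Draws
#' whose density maximum never reaches the threshold have no lag-phase
#' crossing; they are excluded and their fraction reported (an error is
#' thrown if they exceed half the draws). Draws with `beta <= 1` have no
#' induction phase and contribute a lag of 0.
#'
#' @param fit A `weibull_fit`, or a list with elements `alpha`, `beta`,
#'   `ci_alpha`, `ci_beta` (and `covariance` for the covariance mode).
#' @param mc_iterations Number of Monte-Carlo draws (default 10000).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param sampling `"covariance-normal"` or `"independent-normal"`.
#' @param level Confidence level of the percentile interval (default 0.95).
#' @param threshold Density threshold passed to [solve_lag_phase()].
#' @param keep_draws Keep the vector of lag-phase draws in the result
#'   (default TRUE; needed to propagate uncertainty into combination
#'   factors).
#' @return Object of class `lag_phase`: list with `value`, `ci_low`,
#'   `ci_high` (hours), `threshold`, `mc_iterations`, `seed`, `level`,
#'   `sampling`, `no_lag` (flag of the point estimate),
#'   `frac_no_crossing`, and optionally `draws`.
#' @export
lagp_confidence_monte_carlo <- function(fit,
                                        mc_iterations = 10000L,
                                        seed = 1L,
                                        sampling = c("covariance-normal",
                                                     "independent-normal"),
                                        level = 0.95,
                                        threshold = 5e-3,
                                        keep_draws = TRUE) {
  sampling <- match.arg(sampling)
  if (mc_iterations < 1L) stop("'mc_iterations' must be >= 1", call. = FALSE)
  if (!(level > 0 && level < 1)) stop("'level' must be in (0, 1)",
                                      call. = FALSE)
  point <- solve_lag_phase(fit$alpha, fit$beta, threshold)

  draws <- draw_params(fit, mc_iterations, seed, sampling)
  lag_draws <- vapply(seq_len(nrow(draws)), function(i) {
    a <- draws[i, 1L]; b <- draws[i, 2L]
    if (b <= 1) return(0)
    m <- weibull_mode(a, b)
    if (weibull_pdf(m, a, b) < threshold) return(NA_real_)
    as.numeric(solve_lag_phase(a, b, threshold))
  }, numeric(1))

  n_bad <- sum(is.na(lag_draws))
  frac_bad <- n_bad / mc_iterations
  if (frac_bad > 0.5) {
    stop("unstable lag phase: ", round(100 * frac_bad, 1),
         "% of parameter draws have no threshold crossing", call. = FALSE)
  }
  ok <- lag_draws[!is.na(lag_draws)]
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- unname(stats::quantile(ok, probs, type = 7))

  structure(
    list(value = as.numeric(point),
         ci_low = ci[1], ci_high = ci[2],
         threshold = threshold,
         mc_iterations = as.integer(mc_iterations),
         seed = as.integer(seed),
         level = level, sampling = sampling,
         no_lag = isTRUE(attr(point, "no_lag")),
         frac_no_crossing = frac_bad,
         draws = if (keep_draws) ok else NULL),
    class = "lag_phase"
  )
}

#' @export
print.lag_phase <- function(x, ...) {
  cat(sprintf("Lag phase: %.3g h  [%.3g, %.3g] (%d%% MC, %d iterations)\n",
              x$value, x$ci_low, x$ci_high, round(100 * x$level),
              x$mc_iterations))
  if (x$no_lag) cat("  flagged: no induction phase (lag = 0)\n")
  if (x$frac_no_crossing > 0) {
    cat(sprintf("  %.1f%% of draws had no threshold crossing (excluded)\n",
                100 * x$frac_no_crossing))
  }
  invisible(x)
}

# draw parameter pairs, rejecting non-positive values by resampling
draw_params <- function(fit, n, seed, sampling) {
  set.seed(seed)
  mu <- c(fit$alpha, fit$beta)
  rdraw <- if (sampling == "covariance-normal") {
    sigma <- fit$covariance
    if (is.null(sigma)) {
      stop("covariance-normal sampling needs a fit covariance", call. = FALSE)
    }
    function(k) MASS::mvrnorm(k, mu, sigma)
  } else {
    sds <- c(diff(fit$ci_alpha) / 2, diff(fit$ci_beta) / 2) / 1.96
    function(k) cbind(stats::rnorm(k, mu[1], sds[1]),
                      stats::rnorm(k, mu[2], sds[2]))
  }
  out <- matrix(NA_real_, 0L, 2L)
  guard <- 0L
  while (nrow(out) < n) {
    cand <- rdraw(max(n - nrow(out), 2L))
    cand <- cand[cand[, 1L] > 0 & cand[, 2L] > 0, , drop = FALSE]
    out <- rbind(out, cand)
    guard <- guard + 1L
    if (guard > 1000L) {
      stop("rejection sampling failed: parameter draws almost never positive",
           call. = FALSE)
    }
  }
  out[seq_len(n), , drop = FALSE]
}
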