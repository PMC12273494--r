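#' Weibull survival (reduced absorbance) model
#'
#' Evaluates the two-parameter Weibull decay \eqn{A^*(t) = \exp[-(t/\alpha)^\beta]}
#' used to describe the loss of reduced absorbance during lipid oxidation.
#' \code{alpha} is the characteristic time in hours: whatever the shape
#' \code{beta}, the reduced absorbance has dropped by 63\% (to \eqn{e^{-1}})
#' at \code{t = alpha}. \code{beta} is the dimensionless shape; \code{beta = 1}
#' recovers first-order kinetics with rate constant \code{1/alpha}, while
#' \code{beta > 1} gives the sigmoidal, auto-accelerated decay typical of
#' oxidation curves with an induction period.
#'
#' @param t Time(s) in hours, non-negative. Vectorised.
#' @param alpha Scale parameter (hours), > 0.
#' @param beta Shape parameter (dimensionless), > 0.
#' @return Reduced absorbance value(s) in (0, 1].
#' @seealso [weibull_pdf()], [solve_lag_phase()]
#' @examples
#' weibull_survival(0, 26.5, 5.1)     # 1
#' weibull_survival(26.5, 26.5, 5.1)  # exp(-1), the 63% decrease point
#' @export
weibull_survival <- function(t, alpha, beta) {
  check_weibull_params(alpha, beta)
  if (any(t < 0)) {
    stop("'t' must be non-negative (time in hours)", call. = FALSE)
  }
  exp(-(t / alpha)^beta)
}

#' Weibull probability density (oxidation rate curve)
#'
#' The negative time-derivative of [weibull_survival()]:
#' \eqn{f(t) = (\beta/\alpha)(t/\alpha)^{\beta-1}\exp[-(t/\alpha)^\beta]},
#' in units of per hour. Its rising branch describes the acceleration of
#' oxidation at the end of the induction period; the lag phase is defined as
#' the time at which this density first reaches a fixed threshold rate
#' (see [solve_lag_phase()]).
#'
#' @inheritParams weibull_survival
#' @return Density value(s), per hour.
#' @export
weibull_pdf <- function(t, alpha, beta) {
  check_weibull_params(alpha, beta)
  if (any(t < 0)) {
    stop("'t' must be non-negative (time in hours)", call. = FALSE)
  }
  if (beta < 1 && any(t == 0)) {
    stop("density is singular at t = 0 when beta < 1", call. = FALSE)
  }
  # dweibull handles the t = 0, beta = 1 case (1/alpha) and beta > 1 (0)
  stats::dweibull(t, shape = beta, scale = alpha)
}

#' Mode of the Weibull density
#'
#' Closed form \eqn{\alpha((\beta-1)/\beta)^{1/\beta}} for \code{beta > 1}:
#' the time of fastest oxidation. The density is increasing below the mode
#' and decreasing above it, which makes the mode the right bracket when
#' solving for the lag phase on the rising branch.
#'
#' @inheritParams weibull_survival
#' @return Mode location in hours.
#' @export
weibull_mode <- function(alpha, beta) {
  check_weibull_params(alpha, beta)
  if (beta <= 1) {
    stop("mode undefined for beta <= 1 (density is non-increasing)",
         call. = FALSE)
  }
  alpha * ((beta - 1) / beta)^(1 / beta)
}

#' Solve for the lag phase by the density-threshold condition
#'
#' The lag phase (induction period) is defined as the earliest time at which
#' the oxidation rate, measured by [weibull_pdf()], reaches a threshold value
#' (default 5e-3 per hour). Only the rising branch counts: the density also
#' crosses the threshold on its way down, but that second crossing marks the
#' end of oxidation, not the end of the induction period. The root is
#' bracketed on (0, mode) and solved with [stats::uniroot()] to an absolute
#' tolerance well below 1e-4 h.
#'
#' For \code{beta <= 1} the kinetics have no induction phase (the rate is
#' non-increasing), and the function returns 0 flagged \code{no_lag}; the
#' same applies when the density already exceeds the threshold arbitrarily
#' close to zero. If the density never reaches the threshold (its maximum is
#' below it), the curve never oxidises fast enough to define a lag end and
#' an error is thrown.
#'
#' @inheritParams weibull_survival
#' @param threshold Rate threshold in per hour; default 5e-3.
#' @return Lag phase in hours, with attribute \code{no_lag} (logical).
#' @examples
#' solve_lag_phase(26.5, 5.1)  # about 11.0 h
#' @export
solve_lag_phase <- function(alpha, beta, threshold = 5e-3) {
  check_weibull_params(alpha, beta)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("'threshold' must be a single positive rate (per hour)",
         call. = FALSE)
  }
  no_lag <- function(x) structure(x, no_lag = TRUE)
  if (beta <= 1) {
    return(no_lag(0))
  }
  mode_t <- weibull_mode(alpha, beta)
  f <- function(t) weibull_pdf(t, alpha, beta) - threshold
  if (f(mode_t) < 0) {
    stop("density maximum ", signif(weibull_pdf(mode_t, alpha, beta), 4),
         " /h is below the threshold ", threshold,
         " /h: no lag-phase crossing exists", call. = FALSE)
  }
  lo <- mode_t * 1e-12
  if (f(lo) >= 0) {
    return(no_lag(0))
  }
  root <- stats::uniroot(f, lower = lo, upper = mode_t, tol = 1e-12)$root
  structure(root, no_lag = FALSE)
}

#' Reduce raw absorbance to the dimensionless oxidation scale
#'
#' Maps raw absorbance A to \eqn{A^* = (A - A_\infty)/(A_0 - A_\infty)},
#' the reduced absorbance running from 1 (unoxidised) to 0 (fully oxidised).
#' \code{a0} and \code{a_inf} are the initial and plateau (infinite-time)
#' absorbance values of the run; see [estimate_endpoints()].
#'
#' @param absorbance Numeric vector of raw absorbance readings (optical
#'   density); must be non-empty.
#' @param a0 Initial absorbance.
#' @param a_inf Infinite-time (plateau) absorbance. Must differ from `a0`.
#' @return Numeric vector of reduced absorbance values.
#' @export
reduce_absorbance <- function(absorbance, a0, a_inf) {
  if (length(absorbance) == 0L) {
    stop("empty absorbance series", call. = FALSE)
  }
  if (!is.numeric(absorbance)) {
    stop("'absorbance' must be numeric", call. = FALSE)
  }
  if (a0 == a_inf) {
    stop("degenerate normalisation: a0 == a_inf", call. = FALSE)
  }
  (absorbance - a_inf) / (a0 - a_inf)
}

#' Construct a reduced-absorbance curve
#'
#' A `reduced_curve` is a data frame with columns `time_h`, `a_star`, `well`
#' and `replicate`, validated so that times are strictly increasing and the
#' reduced absorbance is (up to noise) on the [0, 1] scale. Values outside
#' the tolerance band [-0.1, 1.1] are permitted but flagged through the
#' `n_out_of_band` attribute, since fitting does not clamp them.
#'
#' @param time_h Strictly increasing times in hours, >= 0.
#' @param a_star Reduced absorbance values, same length as `time_h`.
#' @param well Well label.
#' @param replicate Integer replicate label.
#' @return A data frame of class `reduced_curve`.
#' @export
reduced_curve <- function(time_h, a_star, well = "A1", replicate = 1L) {
  if (length(time_h) != length(a_star)) {
    stop("'time_h' and 'a_star' must have the same length", call. = FALSE)
  }
  if (length(time_h) == 0L) {
    stop("empty curve", call. = FALSE)
  }
  if (any(time_h < 0) || any(diff(time_h) <= 0)) {
    stop("'time_h' must be non-negative and strictly increasing",
         call. = FALSE)
  }
  out <- data.frame(
    time_h = as.numeric(time_h),
    a_star = as.numeric(a_star),
    well = as.character(well),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  attr(out, "n_out_of_band") <- sum(a_star < -0.1 | a_star > 1.1)
  class(out) <- c("reduced_curve", "data.frame")
  out
}

# shared parameter validation
check_weibull_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("'alpha' must be a single positive number (hours)", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0) {
    stop("'beta' must be a single positive number (dimensionless)",
         call. = FALSE)
  }
  invisible(TRUE)
}
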