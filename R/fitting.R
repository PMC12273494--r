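#' Estimate endpoint absorbance values of an oxidation run
#'
#' The reduced-absorbance transform needs the initial (`a0`) and plateau
#' (`a_inf`) absorbance of each run. These are taken as the mean of the first
#' `n_head` and last `n_tail` readings. A run only has a usable plateau if
#' oxidation has finished: the absolute slope of a straight line through the
#' last `n_tail` readings must be below `plateau_tol` (absorbance units per
#' hour), otherwise the run was truncated too early and an error is thrown.
#'
#' With noisy instrument data the estimated tail slope is itself uncertain,
#' so the plateau test is an exceedance test: the run fails only when the
#' tail slope exceeds the tolerance by more than three standard errors
#' (|slope| > `plateau_tol` + 3 se). A flat tail read with noise therefore
#' passes, while a run truncated mid-decay fails.
#'
#' @param curve Data frame with columns `time_h` and `absorbance` (one well).
#' @param n_head Number of initial readings averaged for `a0` (default 3).
#' @param n_tail Number of final readings averaged for `a_inf` (default 10).
#' @param plateau_tol Tail slope tolerance, AU/h (default 1e-3).
#' @return List of class `endpoint_estimate` with elements `a0`, `a_inf`,
#'   `n_head`, `n_tail` and `tail_slope`.
#' @export
estimate_endpoints <- function(curve, n_head = 3L, n_tail = 10L,
                               plateau_tol = 1e-3) {
  stopifnot(is.data.frame(curve),
            all(c("time_h", "absorbance") %in% names(curve)))
  n <- nrow(curve)
  if (n < n_head + n_tail) {
    stop("curve has ", n, " points; need at least n_head + n_tail = ",
         n_head + n_tail, call. = FALSE)
  }
  curve <- curve[order(curve$time_h), , drop = FALSE]
  tail_idx <- seq.int(n - n_tail + 1L, n)
  tail_lm <- stats::lm(absorbance ~ time_h,
                       data = curve[tail_idx, , drop = FALSE])
  tail_slope <- unname(stats::coef(tail_lm)[2L])
  # suppressWarnings: summary.lm warns on zero-residual (noiseless) tails
  tail_se <- tryCatch(
    suppressWarnings(
      summary(tail_lm)$coefficients["time_h", "Std. Error"]),
    error = function(e) 0)
  if (!is.finite(tail_se)) tail_se <- 0
  if (abs(tail_slope) > plateau_tol + 3 * tail_se) {
    stop("plateau not reached: tail slope ", signif(tail_slope, 3),
         " AU/h exceeds tolerance ", plateau_tol,
         " AU/h; extend the kinetic run", call. = FALSE)
  }
  a0 <- mean(curve$absorbance[seq_len(n_head)])
  a_inf <- mean(curve$absorbance[tail_idx])
  if (a0 <= a_inf) {
    stop("invalid oxidation run: initial absorbance (", signif(a0, 4),
         ") not above plateau (", signif(a_inf, 4), ")", call. = FALSE)
  }
  structure(
    list(a0 = a0, a_inf = a_inf, n_head = as.integer(n_head),
         n_tail = as.integer(n_tail), tail_slope = tail_slope),
    class = "endpoint_estimate"
  )
}

#' Fit the Weibull decay model to reduced absorbance kinetics
#'
#' Estimates the scale `alpha` (hours) and shape `beta` by unweighted
#' nonlinear least squares on the reduced-absorbance scale. Replicates are
#' pooled into a single objective by default: all points from all supplied
#' curves enter one fit, which matches plotting a single fitted curve over
#' the replicate cloud. The parameters are optimised on the log scale to
#' enforce positivity (Levenberg-Marquardt via [minpack.lm::nlsLM()]) and
#' reported on the natural scale with a delta-method covariance.
#'
#' Starting values: `alpha` from linear interpolation of the time at which
#' the curve crosses \eqn{e^{-1}} (the definition of the characteristic
#' time), `beta = 2`.
#'
#' @param curves A `reduced_curve`, a plain data frame with `time_h` and
#'   `a_star` columns, or a list of such objects (replicates, pooled).
#' @param init Optional list with elements `alpha`, `beta` overriding the
#'   automatic starting values.
#' @param level Confidence level for the Wald parameter intervals
#'   (default 0.95).
#' @return Object of class `weibull_fit`: a list with `alpha`, `beta`,
#'   `ci_alpha`, `ci_beta`, `covariance` (2x2, natural scale), `rmse`,
#'   `adj_r2`, `n_points`, `pooled`, `level`, and the `data` used.
#' @examples
#' tt <- c(seq(0, 2, by = 1/6), 3:40)
#' cv <- reduced_curve(tt, weibull_survival(tt, 26.5, 5.1))
#' fit <- fit_weibull(cv)
#' coef(fit)
#' @export
fit_weibull <- function(curves, init = NULL, level = 0.95) {
  dat <- pool_curves(curves)
  n <- nrow(dat)
  if (length(unique(dat$time_h)) < 6L) {
    stop("need at least 6 distinct time points to fit two parameters",
         call. = FALSE)
  }
  if (stats::sd(dat$a_star) < 1e-8) {
    stop("no signal: reduced absorbance is constant", call. = FALSE)
  }
  span <- range(dat$a_star)
  if (span[1] > 0.2 || span[2] < 0.9) {
    warning("reduced absorbance spans [", signif(span[1], 3), ", ",
            signif(span[2], 3),
            "]; fits are unreliable unless the data cover at least [0.2, 0.9]",
            call. = FALSE)
  }
  start <- if (is.null(init)) init_weibull(dat) else
    list(alpha = init$alpha, beta = init$beta)
  check_weibull_params(start$alpha, start$beta)

  # Levenberg-Marquardt on log-scale parameters with an analytic Jacobian;
  # residual r = y - exp(-u), u = (t/alpha)^beta
  resid_fn <- function(p) {
    dat$a_star - exp(-(dat$time_h / exp(p[1]))^exp(p[2]))
  }
  jac_fn <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    u <- (dat$time_h / a)^b
    s <- exp(-u)
    lt <- ifelse(dat$time_h > 0, log(dat$time_h / a), 0)
    cbind(la = -s * u * b, lb = s * u * b * lt)
  }
  fit <- minpack.lm::nls.lm(
    par = c(la = log(start$alpha), lb = log(start$beta)),
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!fit$info %in% 1:4) {
    stop("nonlinear least squares did not converge: ", fit$message,
         call. = FALSE)
  }
  alpha <- exp(fit$par[["la"]])
  beta <- exp(fit$par[["lb"]])
  res <- fit$fvec
  sigma2 <- sum(res^2) / (n - 2L)
  vc_log <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(vc_log) || any(!is.finite(vc_log))) {
    stop("unidentifiable fit: singular parameter covariance", call. = FALSE)
  }
  # delta method to the natural scale: d(exp(x))/dx = exp(x)
  jac <- diag(c(alpha, beta))
  covariance <- jac %*% vc_log %*% jac
  dimnames(covariance) <- list(c("alpha", "beta"), c("alpha", "beta"))

  gof <- gof_metrics(dat$a_star, res, n, p = 2L)

  out <- structure(
    list(alpha = alpha, beta = beta,
         covariance = covariance,
         rmse = gof$rmse, adj_r2 = gof$adj_r2,
         n_points = n, pooled = n_curves(curves) > 1L,
         level = level, data = dat),
    class = "weibull_fit"
  )
  ci <- parameter_confidence_intervals(out, level = level)
  out$ci_alpha <- ci$ci_alpha
  out$ci_beta <- ci$ci_beta
  out
}

#' Fit-quality metrics on the reduced-absorbance scale
#'
#' Root-mean-square error \eqn{\sqrt{SSR/n}} of the reduced absorbance and
#' the adjusted coefficient of determination
#' \eqn{1 - (1 - R^2)(n-1)/(n-p-1)} with p = 2 model parameters.
#'
#' @param fit A `weibull_fit`.
#' @param curves Optional curves to evaluate against; defaults to the data
#'   the fit was produced from.
#' @return List with `rmse` and `adj_r2`.
#' @export
goodness_of_fit <- function(fit, curves = NULL) {
  stopifnot(inherits(fit, "weibull_fit"))
  dat <- if (is.null(curves)) fit$data else pool_curves(curves)
  n <- nrow(dat)
  if (n <= 3L) {
    stop("insufficient data: need n > p + 1 = 3 points", call. = FALSE)
  }
  res <- dat$a_star - weibull_survival(dat$time_h, fit$alpha, fit$beta)
  gof_metrics(dat$a_star, res, n, p = 2L)
}

#' Wald confidence intervals for the Weibull parameters
#'
#' Symmetric intervals `estimate +/- t(level, n - 2) * se`, with standard
#' errors from the diagonal of the natural-scale parameter covariance.
#'
#' @param fit A `weibull_fit`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return List with `ci_alpha` and `ci_beta`, each `c(low, high)` in the
#'   parameter's units.
#' @export
parameter_confidence_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (!(level > 0 && level < 1)) {
    stop("'level' must be in (0, 1)", call. = FALSE)
  }
  se <- sqrt(diag(fit$covariance))
  if (any(!is.finite(se))) {
    stop("unidentifiable fit: singular parameter covariance", call. = FALSE)
  }
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$n_points - 2L)
  list(
    ci_alpha = fit$alpha + c(-1, 1) * tq * se["alpha"],
    ci_beta = fit$beta + c(-1, 1) * tq * se["beta"]
  )
}

#' @export
coef.weibull_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
vcov.weibull_fit <- function(object, ...) object$covariance

#' @export
predict.weibull_fit <- function(object, time_h = NULL, ...) {
  if (is.null(time_h)) time_h <- object$data$time_h
  weibull_survival(time_h, object$alpha, object$beta)
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Weibull oxidation kinetics fit",
      if (x$pooled) "(pooled replicates)" else "", "\n")
  cat(sprintf("  alpha = %.3g h   [%.3g, %.3g]\n",
              x$alpha, x$ci_alpha[1], x$ci_alpha[2]))
  cat(sprintf("  beta  = %.3g     [%.3g, %.3g]\n",
              x$beta, x$ci_beta[1], x$ci_beta[2]))
  cat(sprintf("  RMSE (A*) = %.4g   adj. R2 = %.4g   n = %d\n",
              x$rmse, x$adj_r2, x$n_points))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

gof_metrics <- function(y, res, n, p) {
  ssr <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - ssr / sst
  list(rmse = sqrt(ssr / n),
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

pool_curves <- function(curves) {
  if (is.data.frame(curves)) curves <- list(curves)
  if (!length(curves)) stop("no curves supplied", call. = FALSE)
  dat <- do.call(rbind, lapply(curves, function(cv) {
    stopifnot(all(c("time_h", "a_star") %in% names(cv)))
    data.frame(time_h = cv$time_h, a_star = cv$a_star)
  }))
  dat[is.finite(dat$time_h) & is.finite(dat$a_star), , drop = FALSE]
}

n_curves <- function(curves) if (is.data.frame(curves)) 1L else length(curves)

# characteristic-time start value: interpolated crossing of exp(-1)
init_weibull <- function(dat) {
  agg <- stats::aggregate(a_star ~ time_h, data = dat, FUN = mean)
  agg <- agg[order(agg$time_h), ]
  target <- exp(-1)
  below <- which(agg$a_star <= target)
  alpha0 <- if (length(below) && below[1] > 1L) {
    i <- below[1]
    # a_star decreases with time; order the bracket for interpolation
    stats::approx(agg$a_star[c(i, i - 1L)], agg$time_h[c(i, i - 1L)],
                  xout = target, ties = "ordered")$y
  } else if (length(below)) {
    agg$time_h[below[1]]
  } else {
    max(agg$time_h)  # curve never reaches exp(-1); start high
  }
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- stats::median(agg$time_h)
  list(alpha = alpha0, beta = 2)
}
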