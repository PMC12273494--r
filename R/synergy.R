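#' Combination factor for an antioxidant pair
#'
#' The combination factor (CF) compares the lag phase achieved by a
#' combination of two antioxidants with the sum of the lag phases each
#' confers alone: \eqn{CF = LagP_{combo} / (LagP_A + LagP_B)}. CF > 1
#' indicates synergy, CF < 1 antagonism, and CF = 1 an additive effect.
#'
#' @param lagp_combo Lag phase of the combination, hours, >= 0.
#' @param lagp_a,lagp_b Solo lag phases of the two components, hours, >= 0.
#'   Their sum must be positive. A component with no induction phase
#'   contributes 0.
#' @return The dimensionless combination factor.
#' @examples
#' combination_factor(11, 4, 3)  # 1.571: synergistic
#' @export
combination_factor <- function(lagp_combo, lagp_a, lagp_b) {
  vals <- c(lagp_combo, lagp_a, lagp_b)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("lag phases must be finite and non-negative", call. = FALSE)
  }
  denom <- lagp_a + lagp_b
  if (denom <= 0) {
    stop("combination factor undefined: both solo lag phases are zero",
         call. = FALSE)
  }
  lagp_combo / denom
}

#' Classify an antioxidant interaction from its combination factor
#'
#' With a confidence interval: synergistic if the whole interval lies above
#' 1, antagonistic if it lies below 1, additive otherwise. Without one, the
#' point rule applies with a tolerance band: |CF - 1| <= `tol` is called
#' additive, since floating-point CF values are never exactly 1.
#'
#' @param cf Combination factor (dimensionless, > 0).
#' @param cf_ci Optional `c(low, high)` confidence interval for CF.
#' @param tol Half-width of the additive band for the point rule
#'   (default 0.05).
#' @return One of `"synergistic"`, `"additive"`, `"antagonistic"`.
#' @export
classify_interaction <- function(cf, cf_ci = NULL, tol = 0.05) {
  if (!is.finite(cf) || cf <= 0) {
    stop("'cf' must be a positive number", call. = FALSE)
  }
  if (!is.null(cf_ci)) {
    stopifnot(length(cf_ci) == 2L, cf_ci[1] <= cf_ci[2])
    if (cf_ci[1] > 1) return("synergistic")
    if (cf_ci[2] < 1) return("antagonistic")
    return("additive")
  }
  if (abs(cf - 1) <= tol) return("additive")
  if (cf > 1) "synergistic" else "antagonistic"
}

#' Interaction result for one antioxidant combination
#'
#' Combines three lag-phase estimates (combination, solo primary, solo
#' secondary) into the combination factor, the antioxidant efficiency (AE:
#' the combination's absolute lag phase in hours), a CF confidence interval
#' when Monte-Carlo draws are available, and the interaction class.
#'
#' When all three `lag_phase` objects carry draw vectors, the CF interval is
#' obtained by pushing the draws through the CF formula. Draws are paired by
#' iteration when the vectors have equal length (e.g. shared seeds);
#' otherwise they are truncated to the shortest length and a warning is
#' issued, which approximates independent propagation.
#'
#' @param combo,solo_a,solo_b `lag_phase` objects (see
#'   [lagp_confidence_monte_carlo()]) or plain numbers in hours.
#' @param labels Character vector of length 3 naming the combination and the
#'   two components.
#' @param level Confidence level for the CF percentile interval.
#' @param tol Additive tolerance band for the point rule, used when no
#'   interval can be formed.
#' @return Object of class `interaction_result`: list with `cf`, `cf_ci`
#'   (or NULL), `ae`, `components` (named solo lag phases), `labels`,
#'   `classification`.
#' @export
interaction_result <- function(combo, solo_a, solo_b,
                               labels = c("combination", "A", "B"),
                               level = 0.95, tol = 0.05) {
  val <- function(x) if (inherits(x, "lag_phase")) x$value else as.numeric(x)
  drw <- function(x) if (inherits(x, "lag_phase")) x$draws else NULL
  cf <- combination_factor(val(combo), val(solo_a), val(solo_b))
  ae <- val(combo)

  d <- list(drw(combo), drw(solo_a), drw(solo_b))
  cf_ci <- NULL
  if (!any(vapply(d, is.null, logical(1)))) {
    lens <- lengths(d)
    if (length(unique(lens)) > 1L) {
      warning("lag-phase draw vectors differ in length; truncating to ",
              min(lens), " for CF propagation", call. = FALSE)
      d <- lapply(d, function(x) x[seq_len(min(lens))])
    }
    denom <- d[[2]] + d[[3]]
    keep <- denom > 0
    if (any(keep)) {
      cf_draws <- d[[1]][keep] / denom[keep]
      probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
      cf_ci <- unname(stats::quantile(cf_draws, probs, type = 7))
    }
  }
  structure(
    list(cf = cf, cf_ci = cf_ci, ae = ae,
         components = stats::setNames(c(val(solo_a), val(solo_b)),
                                      labels[2:3]),
         labels = labels,
         classification = classify_interaction(cf, cf_ci, tol)),
    class = "interaction_result"
  )
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("%s: CF = %.3g", x$labels[1], x$cf))
  if (!is.null(x$cf_ci)) {
    cat(sprintf(" [%.3g, %.3g]", x$cf_ci[1], x$cf_ci[2]))
  }
  cat(sprintf("  AE = %.3g h  -> %s\n", x$ae, x$classification))
  invisible(x)
}

#' Classify the trend of efficiency and combination factor across ratios
#'
#' Given antioxidant efficiency (AE, the lag phase in hours) and combination
#' factor (CF) measured at three or more increasing molar ratios of the
#' secondary antioxidant, assigns one of four qualitative trend types:
#' \describe{
#'   \item{T1}{AE and CF both rise across the series, maxima at the largest
#'     ratio (concentration-dependent synergy).}
#'   \item{T2}{AE and CF rise up to an interior optimum ratio then flatten or
#'     decline (synergy up to a threshold beyond which prooxidant pathways
#'     may appear).}
#'   \item{T3}{AE rises while CF stays flat (additive behaviour near
#'     CF = 1).}
#'   \item{T4}{AE and CF both decline (prooxidant).}
#' }
#' Changes are judged against a relative tolerance `delta` (default 5\% of
#' the series mean magnitude); series that fit none of the patterns, or have
#' fewer than three ratios, are `"indeterminate"`. Decisions use the
#' ordinary least-squares slope times the ratio span, which is invariant to
#' affine re-labelling of the ratio axis.
#'
#' @param ratio Strictly increasing numeric molar ratios (>= 3 values).
#' @param ae Antioxidant efficiency (hours) at each ratio.
#' @param cf Combination factor at each ratio.
#' @param delta Relative tolerance for calling a change real (default 0.05).
#' @return Object of class `trend_assessment`: list with `trend`,
#'   `ae_slope`, `cf_slope` (per ratio unit), `peak_ratio` (ratio of the
#'   joint AE/CF optimum for T2, else NA), `rationale`.
#' @export
classify_trend <- function(ratio, ae, cf, delta = 0.05) {
  n <- length(ratio)
  stopifnot(length(ae) == n, length(cf) == n)
  if (n >= 2L && any(diff(ratio) <= 0)) {
    stop("'ratio' must be strictly increasing", call. = FALSE)
  }
  mk <- function(trend, rationale, peak = NA_real_) {
    slopes <- if (n >= 2L) {
      c(ae = ols_slope(ratio, ae), cf = ols_slope(ratio, cf))
    } else c(ae = NA_real_, cf = NA_real_)
    structure(
      list(trend = trend, ae_slope = unname(slopes["ae"]),
           cf_slope = unname(slopes["cf"]), peak_ratio = peak,
           rationale = rationale),
      class = "trend_assessment"
    )
  }
  if (n < 3L) {
    warning("fewer than 3 ratios: trend indeterminate", call. = FALSE)
    return(mk("indeterminate", "fewer than 3 ratios supplied"))
  }

  span <- diff(range(ratio))
  # scale-free signed change across the series (slope x span / mean size);
  # invariant to affine relabelling of the ratio axis
  rel_change <- function(y) ols_slope(ratio, y) * span / mean(abs(y))
  ae_ch <- rel_change(ae)
  cf_ch <- rel_change(cf)
  cf_flat <- (max(cf) - min(cf)) / mean(abs(cf)) < delta
  peak_interior <- function(y) {
    k <- which.max(y)
    k > 1L && (y[k] - y[n]) / mean(abs(y)) > delta / 2 &&
      (y[k] - y[1L]) / mean(abs(y)) > delta / 2
  }
  at_last <- function(y) which.max(y) == n

  if (ae_ch < -delta && cf_ch < -delta) {
    return(mk("T4", "AE and CF both decline with increasing ratio"))
  }
  if (ae_ch > delta && cf_flat) {
    return(mk("T3", "AE rises while CF is flat (additive regime)"))
  }
  if (ae_ch > delta && cf_ch > delta && at_last(ae) && at_last(cf)) {
    return(mk("T1", "AE and CF both rise, maxima at the largest ratio"))
  }
  if (peak_interior(cf) && ae_ch > delta / 2 && max(ae) > ae[1L]) {
    k <- which.max(cf)
    return(mk("T2",
              "AE and CF rise to an interior optimum ratio then decline",
              peak = ratio[k]))
  }
  mk("indeterminate", "series matches none of the trend patterns")
}

#' @export
print.trend_assessment <- function(x, ...) {
  cat("Trend:", x$trend, "-", x$rationale, "\n")
  if (!is.na(x$peak_ratio)) cat("  optimum at ratio", x$peak_ratio, "\n")
  invisible(x)
}

#' Quadrant report of combination factor versus antioxidant efficiency
#'
#' Arranges interaction results for a CF-versus-AE quadrant display: one row
#' per condition with its AE (hours), CF, interaction class and the AE gain
#' over the reference antioxidant alone. The additive horizontal reference
#' (CF = 1) and the vertical reference at the solo reference lag phase are
#' attached as attributes for plotting.
#'
#' @param results List of `interaction_result` objects (may be empty).
#' @param solo_ref_lagp Lag phase (hours) of the reference antioxidant
#'   alone, used as the vertical reference and for the AE difference.
#' @return Data frame with columns `condition`, `ae`, `cf`, `class`,
#'   `delta_ae`, plus attributes `cf_reference` (1) and `ae_reference`.
#' @export
quadrant_table <- function(results, solo_ref_lagp = NA_real_) {
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "interaction_result"))
    data.frame(condition = r$labels[1], ae = r$ae, cf = r$cf,
               class = r$classification,
               delta_ae = r$ae - solo_ref_lagp,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(), ae = numeric(), cf = numeric(),
               class = character(), delta_ae = numeric(),
               stringsAsFactors = FALSE)
  attr(out, "cf_reference") <- 1
  attr(out, "ae_reference") <- solo_ref_lagp
  out
}

ols_slope <- function(x, y) {
  unname(stats::coef(stats::lm(y ~ x))[2L])
}
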