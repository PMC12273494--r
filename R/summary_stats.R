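#' Group summaries for summary-statistic hypothesis tests
#'
#' Kinetic parameters are routinely reported as mean, dispersion and
#' replicate count per condition rather than as raw replicate values. The
#' tests in this module operate directly on such summaries.
#'
#' @param label Character group labels.
#' @param mean Group means, in the parameter's units.
#' @param sd Group standard deviations (>= 0).
#' @param n Group sizes (each >= 2).
#' @return Data frame of class `group_summary`.
#' @export
group_summary <- function(label, mean, sd, n) {
  k <- length(label)
  stopifnot(length(mean) == k, length(sd) == k, length(n) == k)
  if (any(sd < 0)) stop("'sd' must be non-negative", call. = FALSE)
  if (any(n < 2)) {
    stop("insufficient replication: every group needs n >= 2", call. = FALSE)
  }
  out <- data.frame(label = as.character(label), mean = as.numeric(mean),
                    sd = as.numeric(sd), n = as.integer(n),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' One-way ANOVA from group summaries
#'
#' Computes the between-group sum of squares
#' \eqn{SSB = \sum n_i(\bar y_i - \bar y)^2}, the within-group sum of
#' squares \eqn{SSW = \sum (n_i - 1)s_i^2}, and the F statistic
#' \eqn{F = (SSB/(k-1))/(SSW/(N-k))} with its p-value. These closed forms
#' reproduce exactly what a raw-data one-way ANOVA would give on any data
#' realising the same summaries.
#'
#' @param groups A `group_summary` (or data frame with columns `label`,
#'   `mean`, `sd`, `n`); at least two groups.
#' @return List with `ssb`, `ssw`, `df_between`, `df_within`, `msb`, `msw`,
#'   `f_statistic`, `p_value`.
#' @export
anova_from_summary <- function(groups) {
  groups <- as_group_summary(groups)
  k <- nrow(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  N <- sum(groups$n)
  grand <- sum(groups$n * groups$mean) / N
  ssb <- sum(groups$n * (groups$mean - grand)^2)
  ssw <- sum((groups$n - 1) * groups$sd^2)
  df_b <- k - 1L
  df_w <- N - k
  msb <- ssb / df_b
  msw <- ssw / df_w
  f <- msb / msw
  list(ssb = ssb, ssw = ssw, df_between = df_b, df_within = df_w,
       msb = msb, msw = msw, f_statistic = f,
       p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

#' Tukey HSD comparisons and compact letter display from summaries
#'
#' All pairwise comparisons with the studentized-range statistic
#' \eqn{q = |\bar y_i - \bar y_j| / \sqrt{(MSW/2)(1/n_i + 1/n_j)}}
#' (Tukey-Kramer for unequal n), p-values from [stats::ptukey()] with the
#' ANOVA's within-group degrees of freedom, and a compact letter display in
#' which groups sharing a letter are not significantly different at
#' `1 - level`.
#'
#' @inheritParams anova_from_summary
#' @param level Confidence level (default 0.95; comparisons are significant
#'   when p < 1 - level).
#' @return List with `comparisons` (data frame: `a`, `b`, `diff`, `q`,
#'   `p_value`, `significant`) and `letters` (named character vector, one
#'   letter string per group, ordered by decreasing mean).
#' @export
tukey_hsd_from_summary <- function(groups, level = 0.95) {
  groups <- as_group_summary(groups)
  an <- anova_from_summary(groups)
  k <- nrow(groups)
  pairs <- utils::combn(k, 2L)
  cmp <- data.frame(
    a = groups$label[pairs[1L, ]],
    b = groups$label[pairs[2L, ]],
    diff = groups$mean[pairs[1L, ]] - groups$mean[pairs[2L, ]],
    stringsAsFactors = FALSE
  )
  se_q <- sqrt(an$msw / 2 *
                 (1 / groups$n[pairs[1L, ]] + 1 / groups$n[pairs[2L, ]]))
  cmp$q <- abs(cmp$diff) / se_q
  cmp$p_value <- stats::ptukey(cmp$q, nmeans = k, df = an$df_within,
                               lower.tail = FALSE)
  cmp$significant <- cmp$p_value < (1 - level)
  list(comparisons = cmp,
       letters = compact_letters(groups$label, cmp))
}

#' Two-sample t-tests from group summaries
#'
#' Independent groups use the Welch statistic with Satterthwaite degrees of
#' freedom. Paired comparisons reconstruct the standard deviation of the
#' differences from the marginal summaries and a correlation assumption:
#' \eqn{s_d^2 = s_a^2 + s_b^2 - 2 r s_a s_b}. The correlation of paired
#' replicate measurements is not recoverable from marginal summaries, so it
#' defaults to 0 and must be supplied explicitly for real paired designs.
#'
#' @param a,b Single-row `group_summary` objects or lists with `mean`, `sd`,
#'   `n`.
#' @param paired Logical; paired comparisons require equal n.
#' @param correlation Assumed correlation between paired measurements
#'   (default 0).
#' @return List with `t`, `df`, `p_value` (two-sided).
#' @export
t_tests_from_summary <- function(a, b, paired = FALSE, correlation = 0) {
  g <- function(x) {
    if (is.data.frame(x)) x <- as.list(x[1L, ])
    stopifnot(all(c("mean", "sd", "n") %in% names(x)))
    if (x$n < 2) stop("each group needs n >= 2", call. = FALSE)
    x
  }
  a <- g(a); b <- g(b)
  if (paired) {
    if (a$n != b$n) {
      stop("paired comparison requires equal sample sizes", call. = FALSE)
    }
    if (abs(correlation) > 1) stop("'correlation' must be in [-1, 1]",
                                   call. = FALSE)
    sd_d <- sqrt(a$sd^2 + b$sd^2 - 2 * correlation * a$sd * b$sd)
    t <- (a$mean - b$mean) / (sd_d / sqrt(a$n))
    df <- a$n - 1
  } else {
    v <- a$sd^2 / a$n + b$sd^2 / b$n
    t <- (a$mean - b$mean) / sqrt(v)
    df <- v^2 / ((a$sd^2 / a$n)^2 / (a$n - 1) + (b$sd^2 / b$n)^2 / (b$n - 1))
  }
  list(t = t, df = df,
       p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Convert a reported confidence-interval half-width to a standard deviation
#'
#' Published kinetic tables often report `mean +/- half-width` where the
#' half-width is a 95\% confidence interval, not a standard deviation. For
#' use as test inputs the half-width is back-converted via
#' \eqn{s = hw \sqrt{n} / t_{1-(1-level)/2, n-1}}. The conversion is exact
#' only if the interval was a t-interval from those n replicates; treat
#' results as approximate.
#'
#' @param half_width CI half-width(s), same units as the mean.
#' @param n Number of replicates behind the interval.
#' @param level Confidence level of the reported interval (default 0.95).
#' @return Standard deviation estimate(s).
#' @export
ci_halfwidth_to_sd <- function(half_width, n, level = 0.95) {
  if (any(half_width < 0)) stop("'half_width' must be >= 0", call. = FALSE)
  if (any(n < 2)) stop("'n' must be >= 2", call. = FALSE)
  half_width * sqrt(n) / stats::qt(1 - (1 - level) / 2, df = n - 1)
}

# ---- internal ---------------------------------------------------------------

as_group_summary <- function(groups) {
  if (!inherits(groups, "group_summary")) {
    stopifnot(is.data.frame(groups),
              all(c("label", "mean", "sd", "n") %in% names(groups)))
    groups <- group_summary(groups$label, groups$mean, groups$sd, groups$n)
  }
  groups
}

# insert-and-absorb compact letter display (Piepho-style): start from one
# letter covering all groups, split on every significant pair, absorb
# redundant columns. Groups share a letter iff no significant difference
# separates them within that column.
compact_letters <- function(labels, comparisons) {
  k <- length(labels)
  idx <- stats::setNames(seq_len(k), labels)
  cols <- list(seq_len(k))
  absorb <- function(cols) {
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) {
      for (j in seq_along(cols)) {
        if (i != j && keep[i] && keep[j] &&
            all(cols[[i]] %in% cols[[j]]) &&
            (length(cols[[i]]) < length(cols[[j]]) || i > j)) {
          keep[i] <- FALSE
        }
      }
    }
    cols[keep]
  }
  sig_pairs <- comparisons[comparisons$significant, , drop = FALSE]
  for (r in seq_len(nrow(sig_pairs))) {
    i <- idx[[sig_pairs$a[r]]]
    j <- idx[[sig_pairs$b[r]]]
    new_cols <- list()
    for (cc in cols) {
      if (i %in% cc && j %in% cc) {
        new_cols <- c(new_cols, list(setdiff(cc, i)), list(setdiff(cc, j)))
      } else {
        new_cols <- c(new_cols, list(cc))
      }
    }
    cols <- absorb(new_cols)
  }
  # stable letter order: first appearance of each column's smallest member
  cols <- cols[order(vapply(cols, min, integer(1)))]
  lets <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(cols, function(cc) g %in% cc, logical(1)))],
           collapse = "")
  }, character(1))
  stats::setNames(lets, labels)
}
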