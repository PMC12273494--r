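# shared fixtures: printed kinetic parameter table for the carnosic-acid /
# alpha-tocopherol ratio series (lag phase, scale, shape, 95% CI half-widths)
table2_params <- function() {
  data.frame(
    condition = c("ni_3x", "ni_1x", "ni_0.3x", "fe_3x", "fe_1x", "fe_0.3x"),
    alpha = c(26.5, 32.6, 20.6, 24.1, 22.3, 16.1),
    beta = c(5.1, 3.8, 4.5, 5.0, 2.3, 2.2),
    lagp = c(11.0, 10.9, 7.1, 9.6, 2.1, 1.2),
    lagp_hw = c(0.6, 1.1, 0.4, 0.4, 0.7, 0.3),
    stringsAsFactors = FALSE
  )
}

# independent brute-force oracle: first threshold crossing of the density on
# a dense grid over (0, mode]
lag_grid_scan <- function(alpha, beta, threshold = 5e-3, dt = 1e-4) {
  m <- alpha * ((beta - 1) / beta)^(1 / beta)
  tg <- seq(dt, m, by = dt)
  dens <- (beta / alpha) * (tg / alpha)^(beta - 1) * exp(-(tg / alpha)^beta)
  tg[which(dens >= threshold)[1L]]
}

# noiseless reduced curve on the plate-reader schedule
noiseless_curve <- function(alpha, beta) {
  spec <- simulation_spec(alpha, beta, noise_sd = 0)
  reduced_curve(spec$schedule, weibull_survival(spec$schedule, alpha, beta))
}

# condition panel along a protection gradient: alpha and beta rise together,
# as they do between metal-induced and non-induced conditions
gradient_panel <- function(n = 12, jitter_sd = 0.05, seed = 1) {
  set.seed(seed)
  s <- seq(0, 1, length.out = n)
  data.frame(
    alpha = (16 + 17 * s) * exp(rnorm(n, 0, jitter_sd)),
    beta = (2.2 + 2.9 * s) * exp(rnorm(n, 0, jitter_sd))
  )
}
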