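#' Default microplate sampling schedule
#'
#' Readings every 10 minutes for the first 2 hours, then hourly until the
#' horizon. This mirrors the cadence of kinetic plate-reader runs that
#' resolve the early induction period densely and the slow approach to the
#' plateau coarsely.
#'
#' @param horizon_h End of the run in hours (> 2).
#' @return Strictly increasing numeric vector of times in hours.
#' @export
cat_schedule <- function(horizon_h = 48) {
  stopifnot(horizon_h > 2)
  c(seq(0, 2, by = 1 / 6), seq(3, ceiling(horizon_h), by = 1))
}

#' Specify a synthetic oxidation condition
#'
#' Ground truth for the generator: Weibull parameters, raw absorbance scale,
#' noise level, replication and sampling schedule. Defaults emulate a
#' tung-oil nanoemulsion oxidation assay read at 273 nm: initial absorbance
#' about 1.7, plateau near zero, triplicate wells, additive homoscedastic
#' Gaussian instrument noise. When no schedule is given, one is built with
#' [cat_schedule()] and the horizon is extended until the true reduced
#' absorbance falls below 0.01, so every run reaches its plateau.
#'
#' @param alpha,beta True Weibull parameters (hours; dimensionless).
#' @param a0 Initial raw absorbance (default 1.7).
#' @param a_inf Plateau raw absorbance (default 0.1).
#' @param noise_sd Standard deviation of additive Gaussian noise on raw
#'   absorbance (default 0.01 AU).
#' @param n_replicates Number of replicate wells (default 3).
#' @param schedule Optional time grid in hours (strictly increasing).
#' @param condition_label Free-text condition label.
#' @param antioxidant Primary/secondary antioxidant names (metadata).
#' @param ratio Molar ratio of secondary antioxidant per unit of primary
#'   (numeric, metadata).
#' @param iron Logical, metal-induced oxidation flag (metadata).
#' @param a234_initial Optional initial 234 nm reading; when NULL one is
#'   drawn uniformly on [0.05, 0.25], below the 0.3 quality-control bound
#'   for unoxidised oil.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(alpha, beta, a0 = 1.7, a_inf = 0.1,
                            noise_sd = 0.01, n_replicates = 3L,
                            schedule = NULL,
                            condition_label = "condition",
                            antioxidant = c("aTOH", ""),
                            ratio = NA_real_, iron = FALSE,
                            a234_initial = NULL) {
  check_weibull_params(alpha, beta)
  if (a0 <= a_inf) stop("'a0' must exceed 'a_inf'", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1", call. = FALSE)
  if (is.null(schedule)) {
    # run until oxidation is over AND the raw curve is genuinely flat:
    # survival < 0.01 and |d(raw)/dt| = (a0 - a_inf) * density < 5e-4 AU/h
    # on the falling branch, so plateau checks see a settled tail
    horizon <- alpha * (-log(0.01))^(1 / beta)
    margin <- 2.5e-4 / (a0 - a_inf)
    lo <- if (beta > 1) weibull_mode(alpha, beta) else alpha
    if (weibull_pdf(lo, alpha, beta) > margin) {
      flat_t <- stats::uniroot(
        function(t) weibull_pdf(t, alpha, beta) - margin,
        lower = lo, upper = alpha * 50, tol = 1e-6)$root
      # + 5 h so a trailing window of hourly readings sits wholly on the flat
      horizon <- max(horizon, flat_t + 5)
    }
    schedule <- cat_schedule(max(horizon, 3))
  }
  if (any(diff(schedule) <= 0)) {
    stop("'schedule' must be strictly increasing", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta, a0 = a0, a_inf = a_inf,
         noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
         schedule = schedule, condition_label = condition_label,
         antioxidant = antioxidant, ratio = ratio, iron = isTRUE(iron),
         a234_initial = a234_initial),
    class = "simulation_spec"
  )
}

#' Generate synthetic absorbance curves for one condition
#'
#' Raw absorbance is \code{a_inf + (a0 - a_inf) * survival(t)} plus
#' independent Gaussian noise per replicate and time point. Noisy values
#' below zero are clipped to zero (physical non-negativity) and counted in
#' the `n_clipped` attribute. Output is a long-format data frame,
#' reproducible given the seed.
#'
#' @param spec A `simulation_spec`.
#' @param seed Integer seed.
#' @param well_prefix Prefix for generated well labels.
#' @return Data frame with columns `well`, `time_h`, `absorbance`,
#'   `replicate`, `condition`, `a234_initial`; attribute `n_clipped`.
#' @export
generate_curve <- function(spec, seed = 1L, well_prefix = "W") {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)
  tt <- spec$schedule
  mu <- spec$a_inf + (spec$a0 - spec$a_inf) *
    weibull_survival(tt, spec$alpha, spec$beta)
  rows <- lapply(seq_len(spec$n_replicates), function(r) {
    ab <- mu + stats::rnorm(length(tt), 0, spec$noise_sd)
    a234 <- if (is.null(spec$a234_initial)) {
      stats::runif(1, 0.05, 0.25)
    } else spec$a234_initial
    data.frame(well = paste0(well_prefix, r),
               time_h = tt, absorbance = ab, replicate = r,
               condition = spec$condition_label,
               a234_initial = a234,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_clipped <- sum(out$absorbance < 0)
  out$absorbance <- pmax(out$absorbance, 0)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Generate a full synthetic assay (curves plus plate map)
#'
#' Takes a panel of conditions and emits the long-format curve table and the
#' matching plate map that [run_pipeline()] consumes. The panel is a list of
#' entries, each with a `spec` (a [simulation_spec()]) and a `role`
#' (`"solo_primary"`, `"solo_secondary"`, `"combination"` or `"control"`);
#' combination entries name their solo counterparts through `solo_primary`
#' and `solo_secondary` (condition labels), and the design is rejected if a
#' referenced solo condition is missing. Wells are assigned
#' plate-style labels (`A1`, `A2`, ...) row by row; duplicate condition
#' labels are a design error.
#'
#' @param panel List of panel entries (see Details).
#' @param seed Integer seed; each condition gets a deterministic sub-seed.
#' @return List with `curves` (long data frame) and `plate_map` (data
#'   frame: `well`, `sample_id`, `role`, `antioxidant_primary`,
#'   `antioxidant_secondary`, `molar_ratio`, `iron`, `replicate_group`,
#'   `solo_primary`, `solo_secondary`).
#' @export
generate_assay <- function(panel, seed = 1L) {
  if (!length(panel)) {
    return(list(curves = empty_curves(), plate_map = empty_plate_map()))
  }
  labs <- vapply(panel, function(p) p$spec$condition_label, character(1))
  if (anyDuplicated(labs)) {
    stop("duplicate condition labels in panel: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  }
  roles <- vapply(panel, function(p) p$role %||% "combination", character(1))
  for (i in which(roles == "combination")) {
    for (ref in c("solo_primary", "solo_secondary")) {
      target <- panel[[i]][[ref]]
      if (is.null(target) || !target %in% labs) {
        stop("combination '", labs[i], "' lacks its ", ref,
             " condition in the panel", call. = FALSE)
      }
    }
  }
  plate_rows <- row_letters()
  curves <- list()
  map <- list()
  well_no <- 0L
  for (i in seq_along(panel)) {
    p <- panel[[i]]
    wells <- vapply(seq_len(p$spec$n_replicates), function(r) {
      w <- well_no + r
      paste0(plate_rows[(w - 1L) %/% 12L + 1L], (w - 1L) %% 12L + 1L)
    }, character(1))
    cv <- generate_curve(p$spec, seed = seed + i, well_prefix = "tmp")
    cv$well <- wells[cv$replicate]
    curves[[i]] <- cv
    map[[i]] <- data.frame(
      well = wells,
      sample_id = labs[i],
      role = roles[i],
      antioxidant_primary = p$spec$antioxidant[1],
      antioxidant_secondary = p$spec$antioxidant[2],
      molar_ratio = p$spec$ratio,
      iron = p$spec$iron,
      replicate_group = labs[i],
      solo_primary = p$solo_primary %||% NA_character_,
      solo_secondary = p$solo_secondary %||% NA_character_,
      stringsAsFactors = FALSE
    )
    well_no <- well_no + p$spec$n_replicates
  }
  list(curves = do.call(rbind, curves),
       plate_map = do.call(rbind, map))
}

#' Ground-truth record for a synthetic panel
#'
#' One row per condition with the true Weibull parameters and the lag phase
#' they imply through the density-threshold definition, for scoring
#' parameter recovery.
#'
#' @param panel As in [generate_assay()].
#' @param threshold Density threshold for the true lag phase.
#' @return Data frame with columns `condition`, `alpha`, `beta`,
#'   `lagp_true`, `no_lag`.
#' @export
truth_table <- function(panel, threshold = 5e-3) {
  rows <- lapply(panel, function(p) {
    lp <- solve_lag_phase(p$spec$alpha, p$spec$beta, threshold)
    data.frame(condition = p$spec$condition_label,
               alpha = p$spec$alpha, beta = p$spec$beta,
               lagp_true = as.numeric(lp),
               no_lag = isTRUE(attr(lp, "no_lag")),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(condition = character(), alpha = numeric(),
                      beta = numeric(), lagp_true = numeric(),
                      no_lag = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# ---- internal ---------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

row_letters <- function() {
  one <- LETTERS
  two <- as.vector(outer(LETTERS, LETTERS, paste0))
  c(one, two)
}

empty_curves <- function() {
  data.frame(well = character(), time_h = numeric(), absorbance = numeric(),
             replicate = integer(), condition = character(),
             a234_initial = numeric(), stringsAsFactors = FALSE)
}

empty_plate_map <- function() {
  data.frame(well = character(), sample_id = character(), role = character(),
             antioxidant_primary = character(),
             antioxidant_secondary = character(), molar_ratio = numeric(),
             iron = logical(), replicate_group = character(),
             solo_primary = character(), solo_secondary = character(),
             stringsAsFactors = FALSE)
}
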