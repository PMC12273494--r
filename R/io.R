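#' Pipeline configuration
#'
#' Collects every tunable of the analysis pipeline with its default:
#' the lag-phase density threshold (5e-3 per hour), the number of
#' Monte-Carlo iterations (10,000), the confidence level (0.95), the
#' endpoint-estimation window sizes, the replicate pooling mode, the
#' additive tolerance band for point-rule interaction calls and the relative
#' tolerance of the trend rule.
#'
#' @param threshold Lag-phase density threshold, per hour.
#' @param mc_iterations Monte-Carlo iterations for lag-phase intervals.
#' @param seed Integer master seed; per-condition seeds are derived from it.
#' @param ci_level Confidence level for all intervals.
#' @param n_head,n_tail Endpoint-estimation window sizes.
#' @param plateau_tol Plateau slope tolerance, AU/h.
#' @param pooling `"pooled"` (all replicates in one fit) or
#'   `"per-replicate"`.
#' @param delta_cf Additive tolerance band for point-rule classification.
#' @param delta_trend Relative tolerance of the trend rule.
#' @return List of class `run_config`.
#' @export
run_config <- function(threshold = 5e-3, mc_iterations = 10000L, seed = 1L,
                       ci_level = 0.95, n_head = 3L, n_tail = 10L,
                       plateau_tol = 1e-3, pooling = c("pooled",
                                                      "per-replicate"),
                       delta_cf = 0.05, delta_trend = 0.05) {
  pooling <- match.arg(pooling)
  stopifnot(threshold > 0, mc_iterations >= 1, ci_level > 0, ci_level < 1)
  structure(
    list(threshold = threshold, mc_iterations = as.integer(mc_iterations),
         seed = as.integer(seed), ci_level = ci_level,
         n_head = as.integer(n_head), n_tail = as.integer(n_tail),
         plateau_tol = plateau_tol, pooling = pooling,
         delta_cf = delta_cf, delta_trend = delta_trend),
    class = "run_config"
  )
}

#' Read a configuration file, with optional overrides
#'
#' Reads a YAML file whose keys match the arguments of [run_config()] and
#' merges any overrides on top (overrides win, matching the convention that
#' command-line flags beat the configuration file).
#'
#' @param path Path to a YAML configuration file, or NULL for defaults.
#' @param overrides Named list of values overriding the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading config files requires the 'yaml' package", call. = FALSE)
    }
    vals <- yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Read absorbance kinetics from a comma-separated table
#'
#' Long format (canonical) needs columns `time_h`, `well`, `absorbance`,
#' `replicate` (plus optional `condition` and `a234_initial`). Wide format
#' (typical plate-reader export) has the time axis in the first column and
#' one column per well, and is converted to long on read. Times may be
#' supplied in minutes with `time_unit = "minutes"`; they are converted to
#' hours, never guessed. Validation errors name the offending rows; an
#' initial 234 nm reading at or above 0.3 raises a quality-control warning
#' (pre-oxidised oil).
#'
#' @param path CSV file path.
#' @param format `"long"` or `"wide"`.
#' @param time_unit `"hours"` (default) or `"minutes"`.
#' @return Long-format data frame of curves (`well`, `time_h`,
#'   `absorbance`, `replicate`, ...).
#' @export
read_curves <- function(path, format = c("long", "wide"),
                        time_unit = c("hours", "minutes")) {
  format <- match.arg(format)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "wide") {
    if (ncol(raw) < 2L) {
      stop("wide format needs a time column plus at least one well column",
           call. = FALSE)
    }
    time_col <- raw[[1L]]
    wells <- names(raw)[-1L]
    raw <- data.frame(
      time_h = rep(time_col, times = length(wells)),
      well = rep(wells, each = length(time_col)),
      absorbance = unlist(raw[-1L], use.names = FALSE),
      replicate = 1L,
      stringsAsFactors = FALSE
    )
  }
  required <- c("time_h", "well", "absorbance", "replicate")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("time_h", "absorbance")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop("non-numeric values in '", col, "' at data row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- v
  }
  if (time_unit == "minutes") raw$time_h <- raw$time_h / 60
  key <- paste(raw$well, raw$time_h)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (well, time) pairs at data row(s) ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  for (w in unique(raw$well)) {
    tw <- raw$time_h[raw$well == w]
    if (any(diff(tw) <= 0)) {
      stop("time axis not strictly increasing in well ", w, call. = FALSE)
    }
  }
  if ("a234_initial" %in% names(raw)) {
    hot <- unique(raw$well[raw$a234_initial >= 0.3])
    if (length(hot)) {
      warning("initial 234 nm absorbance >= 0.3 in well(s) ",
              paste(hot, collapse = ", "),
              ": oil may be pre-oxidised", call. = FALSE)
    }
  }
  raw
}

#' Run the full kinetics-to-interaction pipeline
#'
#' For every condition in the plate map: estimate endpoints per well, reduce
#' to the dimensionless scale, fit the Weibull model (replicates pooled),
#' and compute the lag phase with its Monte-Carlo confidence interval. For
#' every combination condition: the combination factor with a propagated
#' confidence interval and interaction class. Combinations sharing all
#' metadata except the molar ratio form ratio series and receive a trend
#' call when at least three ratios are present. Deterministic given
#' `config$seed`: each condition draws from a sub-seed derived from the
#' master seed and the condition's rank in the plate map.
#'
#' @param curves Long-format curves as from [read_curves()] or
#'   [generate_assay()].
#' @param plate_map Plate map data frame (see [generate_assay()] for the
#'   columns).
#' @param config A [run_config()].
#' @return List of class `oxkin_results` with data frames `fits`,
#'   `interactions`, `trends`, `quadrant`, plus `config` and `log`
#'   (character vector of stage messages).
#' @export
run_pipeline <- function(curves, plate_map, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  required <- c("well", "sample_id", "role")
  stopifnot(all(required %in% names(plate_map)))
  unknown_wells <- setdiff(plate_map$well, curves$well)
  if (length(unknown_wells)) {
    stop("plate map wells absent from curve data: ",
         paste(unknown_wells, collapse = ", "), call. = FALSE)
  }
  log_lines <- character()
  note <- function(...) {
    log_lines[[length(log_lines) + 1L]] <<- paste0(...)
  }

  conditions <- unique(plate_map$sample_id)
  note("pipeline start: ", length(conditions), " conditions, ",
       length(unique(plate_map$well)), " wells")

  # combination rows must have resolvable solo conditions
  comb_rows <- plate_map[plate_map$role == "combination", , drop = FALSE]
  for (i in seq_len(nrow(comb_rows))) {
    for (ref in c("solo_primary", "solo_secondary")) {
      tgt <- comb_rows[[ref]][i]
      if (is.null(tgt) || is.na(tgt) || !tgt %in% conditions) {
        stop("combination '", comb_rows$sample_id[i],
             "' lacks a ", ref, " condition in the plate map", call. = FALSE)
      }
    }
  }

  fits <- list()
  lags <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    wells <- plate_map$well[plate_map$sample_id == cond]
    reduced <- lapply(seq_along(wells), function(wi) {
      cv <- curves[curves$well == wells[wi], , drop = FALSE]
      cv <- cv[order(cv$time_h), , drop = FALSE]
      ep <- estimate_endpoints(cv, config$n_head, config$n_tail,
                               config$plateau_tol)
      reduced_curve(cv$time_h,
                    reduce_absorbance(cv$absorbance, ep$a0, ep$a_inf),
                    well = wells[wi], replicate = wi)
    })
    fit <- withCallingHandlers(
      fit_weibull(reduced, level = config$ci_level),
      warning = function(w) {
        note("condition ", cond, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    lag <- lagp_confidence_monte_carlo(
      fit, mc_iterations = config$mc_iterations,
      seed = config$seed * 1000L + ci,
      level = config$ci_level, threshold = config$threshold
    )
    lags[[cond]] <- lag
    meta <- plate_map[plate_map$sample_id == cond, , drop = FALSE][1L, ]
    fits[[ci]] <- data.frame(
      condition = cond, role = meta$role,
      alpha = fit$alpha, alpha_lo = fit$ci_alpha[1],
      alpha_hi = fit$ci_alpha[2],
      beta = fit$beta, beta_lo = fit$ci_beta[1], beta_hi = fit$ci_beta[2],
      rmse = fit$rmse, adj_r2 = fit$adj_r2, n_points = fit$n_points,
      lagp = lag$value, lagp_lo = lag$ci_low, lagp_hi = lag$ci_high,
      no_lag = lag$no_lag, frac_no_crossing = lag$frac_no_crossing,
      stringsAsFactors = FALSE
    )
    note("condition ", cond, ": fitted n=", fit$n_points,
         ", alpha=", signif(fit$alpha, 4), ", beta=", signif(fit$beta, 4),
         ", lagp=", signif(lag$value, 4))
  }
  fits <- do.call(rbind, fits)

  # interactions for combination conditions
  comb_conditions <- unique(comb_rows$sample_id)
  inter_objs <- list()
  inter <- list()
  for (cond in comb_conditions) {
    meta <- plate_map[plate_map$sample_id == cond, , drop = FALSE][1L, ]
    res <- interaction_result(
      lags[[cond]], lags[[meta$solo_primary]], lags[[meta$solo_secondary]],
      labels = c(cond, meta$solo_primary, meta$solo_secondary),
      level = config$ci_level, tol = config$delta_cf
    )
    inter_objs[[cond]] <- res
    inter[[cond]] <- data.frame(
      condition = cond,
      solo_primary = meta$solo_primary,
      solo_secondary = meta$solo_secondary,
      molar_ratio = meta$molar_ratio %||% NA_real_,
      iron = meta$iron %||% NA,
      cf = res$cf,
      cf_lo = if (is.null(res$cf_ci)) NA_real_ else res$cf_ci[1],
      cf_hi = if (is.null(res$cf_ci)) NA_real_ else res$cf_ci[2],
      ae = res$ae,
      classification = res$classification,
      stringsAsFactors = FALSE
    )
    note("combination ", cond, ": CF=", signif(res$cf, 4), " -> ",
         res$classification)
  }
  interactions <- if (length(inter)) do.call(rbind, inter) else
    data.frame(condition = character(), solo_primary = character(),
               solo_secondary = character(), molar_ratio = numeric(),
               iron = logical(), cf = numeric(), cf_lo = numeric(),
               cf_hi = numeric(), ae = numeric(),
               classification = character(), stringsAsFactors = FALSE)
  rownames(interactions) <- NULL

  # trend calls per ratio series (same solos + iron status, varying ratio)
  trends <- list()
  if (nrow(interactions)) {
    series_key <- paste(interactions$solo_primary,
                        interactions$solo_secondary, interactions$iron)
    for (key in unique(series_key)) {
      sub <- interactions[series_key == key & !is.na(interactions$molar_ratio),
                          , drop = FALSE]
      if (nrow(sub) < 3L) next
      sub <- sub[order(sub$molar_ratio), , drop = FALSE]
      tr <- classify_trend(sub$molar_ratio, sub$ae, sub$cf,
                           delta = config$delta_trend)
      trends[[key]] <- data.frame(
        solo_primary = sub$solo_primary[1L],
        solo_secondary = sub$solo_secondary[1L],
        iron = sub$iron[1L],
        n_ratios = nrow(sub),
        trend = tr$trend, ae_slope = tr$ae_slope, cf_slope = tr$cf_slope,
        peak_ratio = tr$peak_ratio, rationale = tr$rationale,
        stringsAsFactors = FALSE
      )
      note("trend ", key, ": ", tr$trend)
    }
  }
  trends <- if (length(trends)) do.call(rbind, trends) else
    data.frame(solo_primary = character(), solo_secondary = character(),
               iron = logical(), n_ratios = integer(), trend = character(),
               ae_slope = numeric(), cf_slope = numeric(),
               peak_ratio = numeric(), rationale = character(),
               stringsAsFactors = FALSE)
  rownames(trends) <- NULL

  # quadrant rows grouped by each combination's solo reference
  quadrant <- list()
  for (ref in unique(interactions$solo_primary)) {
    objs <- inter_objs[interactions$condition[
      interactions$solo_primary == ref]]
    quadrant[[ref]] <- quadrant_table(objs, lags[[ref]]$value)
  }
  quadrant <- if (length(quadrant)) do.call(rbind, quadrant) else
    quadrant_table(list())
  rownames(quadrant) <- NULL

  structure(
    list(fits = fits, interactions = interactions, trends = trends,
         quadrant = quadrant, config = config, log = log_lines),
    class = "oxkin_results"
  )
}

#' @export
print.oxkin_results <- function(x, ...) {
  cat("oxkin pipeline results: ", nrow(x$fits), " conditions, ",
      nrow(x$interactions), " combinations, ", nrow(x$trends),
      " trend series\n", sep = "")
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Emits `fits.csv`, `interactions.csv` and `trends.csv` plus a
#' machine-readable `manifest.json` echoing the configuration, seed and
#' package version, so a run can be reproduced from its output directory
#' alone.
#'
#' @param results An `oxkin_results` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(inherits(results, "oxkin_results"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(
    fits = file.path(out_dir, "fits.csv"),
    interactions = file.path(out_dir, "interactions.csv"),
    trends = file.path(out_dir, "trends.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.csv(results$fits, paths["fits"], row.names = FALSE)
  utils::write.csv(results$interactions, paths["interactions"],
                   row.names = FALSE)
  utils::write.csv(results$trends, paths["trends"], row.names = FALSE)
  manifest <- list(
    package = "oxkin",
    version = as.character(utils::packageVersion("oxkin")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(results$config)
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
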