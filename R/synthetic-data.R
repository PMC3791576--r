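# Synthetic instrument: seeded generators for every input the validation
# pipeline consumes (calibration tables, stress tables, chromatogram traces).

#' Linear detector response model
#'
#' Describes the "true" instrument used by the synthetic-data generators:
#' a linear peak-area response \eqn{y = m x + b} with level-dependent
#' multiplicative noise.  Replicate areas at concentration \eqn{x} are drawn
#' from a normal distribution with mean \eqn{m x + b} and standard deviation
#' \code{rsd/100} times that mean, truncated at zero so areas stay positive.
#' The relative SD for a level is looked up in \code{noise_rsd_by_level};
#' levels absent from the map use the nearest mapped level.
#'
#' Defaults mirror a validated diltiazem assay: slope 44446.17 area units
#' per ug/mL, intercept 5597.38 area units, and intraday replicate RSDs of
#' 0.96, 1.34, 0.78 and 1.46 % at 0.5, 5, 10 and 50 ug/mL.
#'
#' @param true_slope True response slope, area units per (ug/mL). Must be
#'   positive.
#' @param true_intercept True response intercept, area units.
#' @param noise_rsd_by_level Named numeric vector mapping concentration
#'   levels (names, ug/mL) to replicate relative standard deviations (%).
#'   All values must be non-negative.
#' @param seed Integer seed; mandatory so that identical parameters always
#'   reproduce identical tables.
#' @return An object of class \code{"response_model"}.
#' @seealso [generate_calibration_tables()]
#' @export
#' @examples
#' m <- response_model(seed = 1)
#' tabs <- generate_calibration_tables(m, curves = 1)
#' tabs[[1]]
response_model <- function(true_slope = 44446.17,
                           true_intercept = 5597.38,
                           noise_rsd_by_level = c("0.5" = 0.96, "5" = 1.34,
                                                  "10" = 0.78, "50" = 1.46),
                           seed) {
  if (missing(seed) || is.null(seed)) {
    stop("response_model() requires an explicit integer `seed`", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (!is.numeric(true_slope) || length(true_slope) != 1L || true_slope <= 0) {
    stop("`true_slope` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(noise_rsd_by_level) || length(noise_rsd_by_level) < 1L ||
      is.null(names(noise_rsd_by_level)) ||
      anyNA(suppressWarnings(as.numeric(names(noise_rsd_by_level))))) {
    stop("`noise_rsd_by_level` must be a named numeric vector with numeric level names",
         call. = FALSE)
  }
  if (any(noise_rsd_by_level < 0)) {
    stop("all `noise_rsd_by_level` values must be >= 0", call. = FALSE)
  }
  structure(
    list(true_slope = true_slope,
         true_intercept = true_intercept,
         noise_rsd_by_level = noise_rsd_by_level,
         seed = seed),
    class = "response_model"
  )
}

# nearest-level RSD lookup (vectorised over levels)
.noise_rsd_at <- function(model, levels) {
  ref <- as.numeric(names(model$noise_rsd_by_level))
  idx <- vapply(levels, function(x) which.min(abs(ref - x)), integer(1))
  unname(model$noise_rsd_by_level[idx])
}

# normal draw with mean mu, sd mu*rsd/100, truncated at zero by redrawing
.draw_areas <- function(mu, rsd_pct) {
  sd <- mu * rsd_pct / 100
  x <- stats::rnorm(length(mu), mu, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mu[bad], sd[bad])
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Generate replicate calibration-curve area tables
#'
#' Draws one peak-area table per calibration curve from a
#' [response_model()].  Each table has one column per concentration level
#' (header row = the levels) and one row per replicate injection, matching
#' the delimited layout written by [write_area_table()].
#'
#' @param model A [response_model()].
#' @param levels Concentration levels (ug/mL); all must be positive.
#'   Default: the six working-standard levels 0.5--50 ug/mL.
#' @param curves Number of independent calibration curves (default 5).
#' @param replicates_per_point Replicate injections per level per curve.
#' @return A list of `curves` data frames (class
#'   \code{"calibration_tables"}), column names the levels.  The generating
#'   model is attached as attribute \code{"model"}.
#' @export
generate_calibration_tables <- function(model,
                                        levels = c(0.5, 1, 5, 10, 20, 50),
                                        curves = 5,
                                        replicates_per_point = 1) {
  stopifnot(inherits(model, "response_model"))
  if (length(levels) == 0L) stop("`levels` must be non-empty", call. = FALSE)
  bad <- levels[levels <= 0]
  if (length(bad) > 0L) {
    stop(sprintf("non-positive concentration level(s) not allowed: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (curves < 1L) stop("`curves` must be >= 1", call. = FALSE)
  if (replicates_per_point < 1L) {
    stop("`replicates_per_point` must be >= 1", call. = FALSE)
  }

  set.seed(model$seed)
  mu <- model$true_slope * levels + model$true_intercept
  rsd <- .noise_rsd_at(model, levels)
  out <- vector("list", curves)
  for (k in seq_len(curves)) {
    tab <- vapply(seq_along(levels), function(j) {
      .draw_areas(rep(mu[j], replicates_per_point), rsd[j])
    }, numeric(replicates_per_point))
    tab <- matrix(tab, nrow = replicates_per_point)
    df <- as.data.frame(tab)
    names(df) <- as.character(levels)
    out[[k]] <- df
  }
  names(out) <- paste0("curve_", seq_len(curves))
  structure(out, class = "calibration_tables", model = model)
}

#' Forced-degradation stress condition
#'
#' First-order decay of the parent drug into one or two impurity channels:
#' the mean remaining fraction after `duration` hours is
#' \eqn{\exp(-k_{deg} \cdot t)} and the lost mass is split across the
#' impurity channels.  Replicate scatter is multiplicative at
#' `replicate_rsd` percent.
#'
#' @param condition_label One of `"photolytic"`, `"acidic"`,
#'   `"neutral-heat"`, `"oxidative"`, `"basic"`.
#' @param rate_constant First-order degradation rate constant, per hour
#'   (>= 0).
#' @param duration Stress duration, hours (>= 0).
#' @param impurity_channels Number of distinct impurity peaks formed (1 or
#'   2).
#' @param replicate_rsd Relative SD (%) of replicate areas.
#' @return An object of class \code{"degradation_spec"}.
#' @seealso [rate_from_remaining()] to invert a target remaining percentage
#'   into a rate constant; [generate_stress_table()].
#' @export
degradation_spec <- function(condition_label,
                             rate_constant,
                             duration,
                             impurity_channels = 1L,
                             replicate_rsd = 0) {
  allowed <- c("photolytic", "acidic", "neutral-heat", "oxidative", "basic")
  condition_label <- match.arg(condition_label, allowed)
  if (!is.numeric(rate_constant) || rate_constant < 0) {
    stop("`rate_constant` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(duration) || duration < 0) {
    stop("`duration` must be >= 0", call. = FALSE)
  }
  impurity_channels <- as.integer(impurity_channels)
  if (!impurity_channels %in% c(1L, 2L)) {
    stop("`impurity_channels` must be 1 or 2", call. = FALSE)
  }
  if (replicate_rsd < 0) stop("`replicate_rsd` must be >= 0", call. = FALSE)
  structure(
    list(condition_label = condition_label, rate_constant = rate_constant,
         duration = duration, impurity_channels = impurity_channels,
         replicate_rsd = replicate_rsd),
    class = "degradation_spec"
  )
}

#' Invert a first-order remaining fraction into a rate constant
#'
#' @param remaining_pct Percent of parent remaining (0 < remaining <= 100).
#' @param duration Stress duration in hours (> 0).
#' @return Rate constant in 1/h such that
#'   \eqn{100\exp(-k t) = \mathrm{remaining\_pct}}.
#' @export
#' @examples
#' rate_from_remaining(16.67, 12) # ~0.1493 per hour
rate_from_remaining <- function(remaining_pct, duration) {
  if (any(remaining_pct <= 0) || any(remaining_pct > 100)) {
    stop("`remaining_pct` must be in (0, 100]", call. = FALSE)
  }
  if (any(duration <= 0)) stop("`duration` must be > 0", call. = FALSE)
  -log(remaining_pct / 100) / duration
}

#' Simulate a forced-degradation replicate table
#'
#' Generates replicate parent and impurity areas after stressing
#' `initial_concentration` for `spec$duration` hours under first-order
#' decay.  Areas are reported on the concentration-proportional scale
#' (unit response), so downstream recovered-percent summaries are
#' scale-free.  Noise is multiplicative: each cell is its deterministic
#' mean times a truncated N(1, rsd/100) factor.  With `replicate_rsd = 0`
#' the parent plus summed impurities mass-balance the initial amount
#' exactly.
#'
#' @param spec A [degradation_spec()].
#' @param initial_concentration Starting parent concentration (ug/mL).
#' @param replicates Number of replicate determinations (>= 1).
#' @param seed Integer seed for the replicate noise.
#' @param impurity_split Optional fractions (summing to 1, length
#'   `spec$impurity_channels`) dividing the degraded mass between impurity
#'   channels; equal split by default.
#' @return A data frame (class \code{"stress_table"}) with columns
#'   \code{parent} and \code{impurity_1}\[, \code{impurity_2}\]; attributes
#'   \code{control_mean_area} (the unstressed response),
#'   \code{remaining_fraction} (the deterministic mean) and \code{spec}.
#' @export
generate_stress_table <- function(spec, initial_concentration = 100,
                                  replicates = 3, seed,
                                  impurity_split = NULL) {
  stopifnot(inherits(spec, "degradation_spec"))
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  if (initial_concentration <= 0) {
    stop("`initial_concentration` must be > 0", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) {
    stop("generate_stress_table() requires `seed`", call. = FALSE)
  }
  nchan <- spec$impurity_channels
  if (is.null(impurity_split)) {
    impurity_split <- rep(1 / nchan, nchan)
  }
  if (length(impurity_split) != nchan ||
      abs(sum(impurity_split) - 1) > 1e-12 || any(impurity_split < 0)) {
    stop("`impurity_split` must be non-negative fractions of length ",
         nchan, " summing to 1", call. = FALSE)
  }

  set.seed(as.integer(seed))
  remaining <- exp(-spec$rate_constant * spec$duration)
  parent_mean <- initial_concentration * remaining
  imp_means <- initial_concentration * (1 - remaining) * impurity_split

  noisy <- function(mean_val) {
    if (spec$replicate_rsd == 0 || mean_val == 0) {
      rep(mean_val, replicates)
    } else {
      .draw_areas(rep(mean_val, replicates), spec$replicate_rsd)
    }
  }
  out <- data.frame(parent = noisy(parent_mean))
  for (ch in seq_len(nchan)) {
    out[[paste0("impurity_", ch)]] <- noisy(imp_means[ch])
  }
  structure(out,
            class = c("stress_table", "data.frame"),
            control_mean_area = initial_concentration,
            remaining_fraction = remaining,
            spec = spec)
}

#' Chromatographic peak specification
#'
#' Describes a single peak for [synthesize_chromatogram()].  The Gaussian
#' core width is tied to the column efficiency through
#' \eqn{\sigma = t_R / \sqrt{N}}; the tailed shape is an exponentially
#' modified Gaussian whose exponential time constant is found by 1-D
#' root-finding so that the measured USP tailing factor equals
#' `tailing_factor`.
#'
#' @param retention_time Apex retention time, minutes (> 0).
#' @param area Peak area, area units (> 0).
#' @param plate_count Theoretical plate count (> 0).
#' @param tailing_factor USP tailing factor; must equal 1 for the pure
#'   Gaussian model and be >= 1 for the tailed model.
#' @param model `"gaussian"` or `"emg"`; by default chosen from
#'   `tailing_factor` (1 -> Gaussian, > 1 -> EMG).
#' @return An object of class \code{"peak_spec"}.
#' @export
peak_spec <- function(retention_time, area, plate_count,
                      tailing_factor = 1, model = NULL) {
  if (retention_time <= 0) stop("`retention_time` must be > 0", call. = FALSE)
  if (area <= 0) stop("`area` must be > 0", call. = FALSE)
  if (plate_count <= 0) stop("`plate_count` must be > 0", call. = FALSE)
  if (is.null(model)) {
    model <- if (tailing_factor > 1) "emg" else "gaussian"
  }
  model <- match.arg(model, c("gaussian", "emg"))
  if (model == "gaussian" && tailing_factor != 1) {
    stop("pure-Gaussian peaks must have `tailing_factor` = 1", call. = FALSE)
  }
  if (model == "emg" && tailing_factor < 1) {
    stop("tailed peaks must have `tailing_factor` >= 1", call. = FALSE)
  }
  structure(
    list(retention_time = retention_time, area = area,
         plate_count = plate_count, tailing_factor = tailing_factor,
         model = model),
    class = "peak_spec"
  )
}

# exponentially modified Gaussian profile, numerically stable in log space:
# f(x) = lam/2 exp(lam(mu - x) + lam^2 s^2/2) erfc((mu + lam s^2 - x)/(sqrt(2) s))
# with erfc(z) = 2*pnorm(-sqrt(2) z); lam = 1/tau
.emg_profile <- function(t, mu, sigma, tau, area = 1) {
  lam <- 1 / tau
  logf <- log(lam) + lam * (mu - t) + lam^2 * sigma^2 / 2 +
    stats::pnorm((t - mu - lam * sigma^2) / sigma, log.p = TRUE)
  area * exp(logf)
}

.gauss_profile <- function(t, mu, sigma, area = 1) {
  area * stats::dnorm(t, mu, sigma)
}

# linear-interpolated crossing times of `level` nearest the apex index
.edge_crossings <- function(t, y, apex_idx, level) {
  level <- unname(level)
  lead <- NA_real_
  for (i in seq(apex_idx, 2L)) {
    if (y[i - 1] <= level && y[i] > level) {
      lead <- t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
      break
    }
  }
  trail <- NA_real_
  n <- length(y)
  if (apex_idx < n) {
    for (i in seq(apex_idx, n - 1L)) {
      if (y[i] > level && y[i + 1] <= level) {
        trail <- t[i] + (y[i] - level) / (y[i] - y[i + 1]) * (t[i + 1] - t[i])
        break
      }
    }
  }
  c(lead = lead, trail = trail)
}

# apex time and USP tailing factor of a noise-free EMG, measured numerically
.emg_shape <- function(mu, sigma, tau) {
  t <- seq(mu - 6 * sigma, mu + 6 * sigma + 12 * tau, length.out = 6000L)
  y <- .emg_profile(t, mu, sigma, tau)
  i <- which.max(y)
  cr <- .edge_crossings(t, y, i, 0.05 * y[i])
  list(apex = t[i],
       tailing = (cr["trail"] - cr["lead"]) / (2 * (t[i] - cr["lead"])))
}

# tau such that the measured USP tailing factor equals `tailing`
.emg_tau_for_tailing <- function(sigma, tailing) {
  if (tailing <= 1) return(1e-3 * sigma)
  f <- function(tau) .emg_shape(0, sigma, tau)$tailing - tailing
  stats::uniroot(f, c(1e-3 * sigma, 8 * sigma), tol = 1e-6 * sigma)$root
}

#' Synthesize a chromatogram trace from peak specifications
#'
#' Builds a time--intensity trace as the sum of the peak shapes plus
#' optional Gaussian baseline noise.  Pure-Gaussian peaks use
#' \eqn{\sigma = t_R/\sqrt{N}}; tailed peaks use an exponentially modified
#' Gaussian whose tail constant reproduces the requested USP tailing
#' factor, shifted so the apex lands at the requested retention time.
#'
#' @param peaks A [peak_spec()] or list of them.
#' @param duration Trace length, minutes.
#' @param sampling_interval Sampling interval, minutes (> 0).  The default
#'   0.002 min gives > 50 samples across the narrowest realistic peak.
#' @param baseline_noise_sd SD of additive baseline noise, intensity units.
#' @param seed Integer seed; required when `baseline_noise_sd > 0`.
#' @return A [chromatogram()] (data frame with columns \code{time_min},
#'   \code{intensity}).
#' @export
synthesize_chromatogram <- function(peaks, duration,
                                    sampling_interval = 0.002,
                                    baseline_noise_sd = 0,
                                    seed = NULL) {
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  stopifnot(length(peaks) >= 1L,
            all(vapply(peaks, inherits, logical(1), "peak_spec")))
  if (sampling_interval <= 0) {
    stop("`sampling_interval` must be > 0", call. = FALSE)
  }
  rts <- vapply(peaks, `[[`, numeric(1), "retention_time")
  if (any(rts < 0 | rts > duration)) {
    stop("peak retention_time outside [0, duration]", call. = FALSE)
  }
  peaks <- peaks[order(rts)]

  times <- seq(0, duration, by = sampling_interval)
  intensity <- numeric(length(times))
  for (p in peaks) {
    sigma <- p$retention_time / sqrt(p$plate_count)
    if (p$model == "gaussian") {
      intensity <- intensity + .gauss_profile(times, p$retention_time, sigma, p$area)
    } else {
      tau <- .emg_tau_for_tailing(sigma, p$tailing_factor)
      # EMG apex sits later than mu; translate so the apex hits t_R exactly
      mu <- p$retention_time - (.emg_shape(0, sigma, tau)$apex)
      intensity <- intensity + .emg_profile(times, mu, sigma, tau, p$area)
    }
  }
  if (baseline_noise_sd > 0) {
    if (is.null(seed)) {
      stop("`seed` is required when `baseline_noise_sd` > 0", call. = FALSE)
    }
    set.seed(as.integer(seed))
    intensity <- intensity + stats::rnorm(length(times), 0, baseline_noise_sd)
  }
  chromatogram(times, intensity)
}

#' Write / read a replicate area table
#'
#' Delimited-text interchange format for replicate area tables: a comma
#' separated file whose header row holds the concentration levels and whose
#' rows are replicate injections.  Missing values are not permitted.
#'
#' @param table A data frame as produced by [generate_calibration_tables()]
#'   (one element) with levels as column names.
#' @param path File path.
#' @return `write_area_table()` returns `path` invisibly;
#'   `read_area_table()` returns the data frame with numeric level column
#'   names preserved.
#' @export
write_area_table <- function(table, path) {
  if (anyNA(table)) stop("area tables must not contain missing values", call. = FALSE)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_area_table
#' @export
read_area_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (anyNA(df)) stop("area table contains missing values: ", path, call. = FALSE)
  df
}
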