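# ICH-style validation statistics: precision RSDs, accuracy, spiked
# recovery, two-wavelength peak-purity F factor, stress-test summaries and
# robustness evaluation.

#' Relative standard deviation (percent)
#'
#' `100 * sd(values) / mean(values)` with the sample (n - 1) denominator.
#'
#' @param values At least two numeric values with non-zero mean.
#' @return RSD in percent.
#' @export
#' @examples
#' rsd(c(1, 2, 3)) # 50
rsd <- function(values) {
  if (length(values) < 2L) stop("`rsd()` needs >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("`rsd()` undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Accuracy as percent of nominal
#'
#' @param measured_mean Mean measured concentration (ug/mL).
#' @param nominal Nominal (target) concentration, > 0.
#' @return `100 * measured_mean / nominal`; vectorised.
#' @export
accuracy_pct <- function(measured_mean, nominal) {
  if (any(nominal <= 0)) stop("`nominal` must be > 0", call. = FALSE)
  100 * measured_mean / nominal
}

#' Truncate a percentage for display
#'
#' Reported percentages follow the truncating display convention
#' (101.666... prints as 101.66, not 101.67).  Internal arithmetic is
#' never truncated; use this only at the reporting layer.
#'
#' @param x Numeric.
#' @param digits Decimal places kept (default 2).
#' @return `x` truncated (towards zero) to `digits` decimals.
#' @export
#' @examples
#' trunc_pct(18.30 / 18.00 * 100) # 101.66
trunc_pct <- function(x, digits = 2) {
  p <- 10^digits
  trunc(round(x * p, 6)) / p
}

#' Spiked-recovery experiment
#'
#' @param target_concentration Nominal spiked concentration (ug/mL), > 0.
#' @param measured_concentrations Replicate measured concentrations.
#' @return Object of class \code{"recovery_experiment"} carrying the
#'   individual recoveries (`100 * measured / target`), their mean and SD.
#' @export
recovery_experiment <- function(target_concentration, measured_concentrations) {
  if (target_concentration <= 0) {
    stop("`target_concentration` must be > 0", call. = FALSE)
  }
  if (length(measured_concentrations) == 0L) {
    stop("`measured_concentrations` must be non-empty", call. = FALSE)
  }
  rec <- 100 * measured_concentrations / target_concentration
  structure(
    list(target_concentration = target_concentration,
         measured_concentrations = measured_concentrations,
         recoveries = rec,
         recovery_pct = mean(rec),
         recovery_sd = if (length(rec) >= 2L) stats::sd(rec) else NA_real_),
    class = "recovery_experiment"
  )
}

#' Summarise spiked-recovery experiments
#'
#' Per-level recovery is the accuracy of the level mean; the grand mean
#' averages the level recoveries.  The relative SD of recovery,
#' \eqn{s(\eta)}, feeds the accuracy component of the uncertainty budget:
#' by default it is the RSD of all individual recoveries pooled across
#' levels (`pooling = "global"`); `pooling = "per_level"` averages the
#' within-level RSDs instead.  With fewer than two individual recoveries
#' \eqn{s(\eta)} is undefined and reported as `NA`, not zero.
#'
#' @param experiments A list of [recovery_experiment()] objects (a single
#'   experiment is accepted).
#' @param pooling `"global"` or `"per_level"`.
#' @return A list with \code{mean_recovery} (%), \code{per_level} (data
#'   frame: target, recovery_pct, recovery_sd, n), \code{s_eta} (%), and
#'   \code{n} (total individual recoveries).
#' @export
recovery_summary <- function(experiments, pooling = c("global", "per_level")) {
  pooling <- match.arg(pooling)
  if (inherits(experiments, "recovery_experiment")) experiments <- list(experiments)
  if (length(experiments) == 0L) stop("no recovery experiments", call. = FALSE)
  stopifnot(all(vapply(experiments, inherits, logical(1), "recovery_experiment")))

  per_level <- do.call(rbind, lapply(experiments, function(e) {
    data.frame(target = e$target_concentration,
               recovery_pct = e$recovery_pct,
               recovery_sd = e$recovery_sd,
               n = length(e$recoveries))
  }))
  all_rec <- unlist(lapply(experiments, `[[`, "recoveries"))
  s_eta <- if (length(all_rec) >= 2L) {
    if (pooling == "global") {
      rsd(all_rec)
    } else {
      mean(vapply(experiments, function(e) 100 * e$recovery_sd / e$recovery_pct,
                  numeric(1)))
    }
  } else NA_real_
  list(mean_recovery = mean(per_level$recovery_pct),
       per_level = per_level,
       s_eta = s_eta,
       n = length(all_rec))
}

#' Two-wavelength peak-purity F factor
#'
#' The ratio of the peak areas at 240 nm and 260 nm,
#' \eqn{F = A(240)/A(260)}.  A stressed peak whose F factor agrees with
#' the standard's within the tolerance is taken as spectrally pure.
#'
#' @param area_240,area_260 Peak areas at 240 and 260 nm; both > 0.
#' @return The ratio (dimensionless).
#' @seealso [f_factor_consistent()]
#' @export
f_factor <- function(area_240, area_260) {
  if (any(area_260 <= 0)) stop("`area_260` must be > 0", call. = FALSE)
  if (any(area_240 <= 0)) stop("`area_240` must be > 0", call. = FALSE)
  area_240 / area_260
}

#' @rdname f_factor
#' @param f Observed F factor (e.g. of a stressed solution).
#' @param reference Reference F factor (the standard's).
#' @param tolerance Agreement tolerance, default +/- 0.05 (chosen from an
#'   observed spread of 3.52--3.55 being treated as identical).
#' @return `f_factor_consistent()` returns a list with \code{consistent}
#'   (logical), \code{difference} and \code{tolerance}.
#' @export
f_factor_consistent <- function(f, reference, tolerance = 0.05) {
  d <- abs(f - reference)
  list(consistent = d <= tolerance, difference = d, tolerance = tolerance)
}

#' Summarise a forced-degradation run
#'
#' Recovered parent percent is `100 * mean(stressed areas) / control`,
#' with the RSD of the replicate recovered fractions and the impurity
#' peak count passed through.
#'
#' @param parent_areas Replicate stressed parent areas (or a
#'   [generate_stress_table()] whose `parent` column and attributes are
#'   used).
#' @param control_mean_area Mean unstressed (control) area, > 0.
#' @param impurity_peak_count Number of impurity peaks observed.
#' @param condition_label Condition name carried into the result.
#' @return Object of class \code{"stress_result"}: fields
#'   \code{condition_label}, \code{recovered_pct_mean},
#'   \code{recovered_pct_rsd}, \code{impurity_count}.
#' @export
summarize_stress <- function(parent_areas, control_mean_area = NULL,
                             impurity_peak_count = NULL,
                             condition_label = "stress") {
  if (inherits(parent_areas, "stress_table")) {
    tab <- parent_areas
    if (is.null(control_mean_area)) {
      control_mean_area <- attr(tab, "control_mean_area")
    }
    if (is.null(impurity_peak_count)) {
      imp_cols <- grep("^impurity_", names(tab), value = TRUE)
      impurity_peak_count <- sum(vapply(imp_cols,
                                        function(cl) mean(tab[[cl]]) > 0,
                                        logical(1)))
    }
    condition_label <- attr(tab, "spec")$condition_label
    parent_areas <- tab$parent
  }
  if (length(parent_areas) == 0L) stop("empty parent series", call. = FALSE)
  if (is.null(control_mean_area) || control_mean_area <= 0) {
    stop("`control_mean_area` must be > 0", call. = FALSE)
  }
  recovered <- 100 * parent_areas / control_mean_area
  structure(
    list(condition_label = condition_label,
         recovered_pct_mean = mean(recovered),
         recovered_pct_rsd = if (length(recovered) >= 2L) rsd(recovered) else NA_real_,
         impurity_count = as.integer(impurity_peak_count)),
    class = "stress_result"
  )
}

#' @export
print.stress_result <- function(x, ...) {
  cat(sprintf("%s: recovered %.2f %% (RSD %.2f %%), %d impurit%s\n",
              x$condition_label, x$recovered_pct_mean, x$recovered_pct_rsd,
              x$impurity_count, if (x$impurity_count == 1) "y" else "ies"))
  invisible(x)
}

#' Evaluate a robustness grid
#'
#' One chromatographic factor (flow rate, column temperature, mobile-phase
#' pH, ...) is varied per row.  For each factor the assay RSD across its
#' levels must stay below `assay_rsd_max`, and every row must satisfy the
#' suitability criteria (resolution, plates, tailing).  Defaults reflect
#' achieved-method outcomes used as criteria: assay RSD < 2 %, resolution
#' > 9, plates > 11500, tailing < 1.2.
#'
#' @param grid Data frame with columns \code{factor}, \code{level},
#'   \code{assay_pct}, \code{resolution}, \code{plates}, \code{tailing};
#'   each row one condition.
#' @param assay_rsd_max,resolution_min,plates_min,tailing_max Criteria.
#' @return A list with \code{pass} (logical) and \code{per_factor} (data
#'   frame: factor, assay_rsd and one logical column per criterion).
#' @export
evaluate_robustness <- function(grid, assay_rsd_max = 2, resolution_min = 9,
                                plates_min = 11500, tailing_max = 1.2) {
  need <- c("factor", "level", "assay_pct", "resolution", "plates", "tailing")
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    stop("`grid` must be a non-empty data frame", call. = FALSE)
  }
  missing_cols <- setdiff(need, names(grid))
  if (length(missing_cols) > 0L) {
    stop("`grid` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(grid$factor)) {
    stop("every robustness row must name exactly one varied factor", call. = FALSE)
  }
  per_factor <- do.call(rbind, lapply(split(grid, grid$factor), function(g) {
    arsd <- if (nrow(g) >= 2L) rsd(g$assay_pct) else 0
    data.frame(
      factor = g$factor[1],
      assay_rsd = arsd,
      assay_ok = arsd < assay_rsd_max,
      resolution_ok = all(g$resolution > resolution_min),
      plates_ok = all(g$plates > plates_min),
      tailing_ok = all(g$tailing < tailing_max)
    )
  }))
  rownames(per_factor) <- NULL
  per_factor$pass <- per_factor$assay_ok & per_factor$resolution_ok &
    per_factor$plates_ok & per_factor$tailing_ok
  list(pass = all(per_factor$pass), per_factor = per_factor)
}
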