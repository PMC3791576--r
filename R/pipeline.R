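# End-to-end orchestration: generate -> integrate -> calibrate -> validate
# -> budget, with a consolidated, seeded, file-based report bundle.

#' Default run configuration
#'
#' Builds the full configuration for [run_full_validation()], mirroring a
#' validated diltiazem assay: six-level calibration (0.5--50 ug/mL, five
#' curves) on the response line y = 44446.17 x + 5597.38 with
#' level-dependent replicate RSDs; intraday/interday precision at 0.5, 5,
#' 10 and 50 ug/mL (n = 5); triplicate placebo-spike accuracy; spiked-gel
#' recovery at 12, 14 and 18 ug/mL; five forced-degradation conditions
#' parameterised by their target remaining percentages; a certified
#' standard purity of 99.50 %; coverage factor k = 2; and a sample assay
#' at a nominal 9.30 ug/mL.
#'
#' @param seed Integer master seed (mandatory: every stochastic stage
#'   derives its own logged sub-seed from it).
#' @param output_dir Directory for the report bundle.
#' @return A named list (class \code{"run_config"}).
#' @export
default_run_config <- function(seed, output_dir = "chromval-run") {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(list(
    seed = as.integer(seed),
    output_dir = output_dir,
    response = list(
      true_slope = 44446.17,
      true_intercept = 5597.38,
      noise_rsd_by_level = c("0.5" = 0.96, "5" = 1.34, "10" = 0.78, "50" = 1.46)
    ),
    calibration = list(levels = c(0.5, 1, 5, 10, 20, 50), curves = 5,
                       replicates_per_point = 1),
    precision = list(
      levels = c(0.5, 5, 10, 50), replicates = 5,
      interday_rsd_by_level = c("0.5" = 2.40, "5" = 1.53, "10" = 1.18, "50" = 1.19)
    ),
    accuracy = list(levels = c(0.5, 5, 10, 50), replicates = 3),
    recovery = list(targets = c(12, 14, 18), replicates = 3,
                    rsd_by_target = c("12" = 0.13, "14" = 0.07, "18" = 0.29)),
    stress = data.frame(
      condition = c("photolytic", "acidic", "neutral-heat", "oxidative", "basic"),
      remaining_pct = c(48.86, 16.67, 84.57, 89.01, 10.47),
      duration_h = c(4, 12, 12, 4, 12),
      impurities = c(1L, 1L, 1L, 1L, 2L),
      replicate_rsd = c(1.48, 1.95, 0.86, 1.74, 2.10),
      stringsAsFactors = FALSE
    ),
    stress_replicates = 3,
    stress_initial_concentration = 100,
    suitability = list(
      duration = 8, sampling_interval = 0.002, baseline_noise_sd = 0,
      impurity = list(retention_time = 4.2, area = 20000, plate_count = 16000,
                      tailing_factor = 1),
      main = list(retention_time = 5.8, area = 450059, plate_count = 11511,
                  tailing_factor = 1.1)
    ),
    robustness = list(
      factors = c("flow_rate", "temperature", "pH"),
      base = list(assay_pct = 100, resolution = 9.3, plates = 11700,
                  tailing = 1.1),
      shift_rsd = 0.5
    ),
    standard = list(purity_pct = 99.50, preparation_u = NULL),
    coverage_factor = 2,
    sample = list(nominal_concentration = 9.30, replicates = 3),
    blank_response = 500,
    criteria = list(precision_rsd_max = 2, precision_levels_min = 5,
                    resolution_min = 3, plates_min = 1200)
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File path; `.yaml`/`.yml` requires the \pkg{yaml} package,
#'   `.json` uses \pkg{jsonlite}.
#' @return A \code{"run_config"} list merged over [default_run_config()]
#'   defaults (the file must at least provide `seed`).
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the `yaml` package; use JSON instead", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  }
  if (is.null(raw$seed)) stop("config must provide `seed`", call. = FALSE)
  cfg <- default_run_config(seed = raw$seed)
  for (nm in setdiff(names(raw), "seed")) {
    if (nm == "stress") {
      cfg$stress <- as.data.frame(raw$stress)
    } else if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], raw[[nm]])
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  # level->RSD maps may arrive as named lists from JSON/YAML
  cfg$response$noise_rsd_by_level <- unlist(cfg$response$noise_rsd_by_level)
  cfg$precision$interday_rsd_by_level <- unlist(cfg$precision$interday_rsd_by_level)
  cfg$recovery$rsd_by_target <- unlist(cfg$recovery$rsd_by_target)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a run configuration
#'
#' Violations are returned as data, not thrown; an empty character vector
#' means the configuration is valid.  Each violation names the offending
#' field and the rule it breaks.
#'
#' @param config A \code{"run_config"} list.
#' @return Character vector of violations (possibly empty).
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed)))) {
    add("seed: must be present and integer")
  }
  cal <- config$calibration
  if (is.null(cal$levels) || length(cal$levels) == 0L) {
    add("calibration$levels: must be non-empty")
  } else if (any(cal$levels <= 0)) {
    add("calibration$levels: all levels must be > 0")
  }
  if (!is.null(cal$curves) && cal$curves < 1) add("calibration$curves: must be >= 1")
  if (is.null(config$response$true_slope) || config$response$true_slope <= 0) {
    add("response$true_slope: must be > 0")
  }
  if (any(config$response$noise_rsd_by_level < 0)) {
    add("response$noise_rsd_by_level: RSDs must be >= 0")
  }
  for (blk in c("precision", "accuracy")) {
    if (length(config[[blk]]$levels) == 0L) {
      add(paste0(blk, "$levels: must be non-empty"))
    }
  }
  if (length(config$recovery$targets) == 0L) add("recovery$targets: must be non-empty")
  st <- config$stress
  if (is.null(st) || nrow(st) == 0L) {
    add("stress: must define at least one condition")
  } else {
    for (i in seq_len(nrow(st))) {
      lab <- st$condition[i]
      if (st$duration_h[i] < 0) {
        add(sprintf("stress[%s]$duration_h: must be >= 0", lab))
      }
      if (st$remaining_pct[i] <= 0 || st$remaining_pct[i] > 100) {
        add(sprintf("stress[%s]$remaining_pct: must be in (0, 100]", lab))
      }
      if (!st$impurities[i] %in% c(1L, 2L)) {
        add(sprintf("stress[%s]$impurities: must be 1 or 2", lab))
      }
    }
  }
  p <- config$standard$purity_pct
  if (is.null(p) || p <= 0 || p > 100) add("standard$purity_pct: must be in (0, 100]")
  if (is.null(config$coverage_factor) || config$coverage_factor <= 0) {
    add("coverage_factor: must be > 0")
  }
  if (is.null(config$sample$nominal_concentration) ||
      config$sample$nominal_concentration <= 0) {
    add("sample$nominal_concentration: must be > 0")
  }
  v
}

# draw replicate areas at given levels from a response model view of the
# config, using an explicit stage seed
.stage_areas <- function(config, levels, replicates, seed,
                         rsd_map = config$response$noise_rsd_by_level) {
  model <- response_model(config$response$true_slope,
                          config$response$true_intercept,
                          rsd_map, seed = seed)
  tabs <- generate_calibration_tables(model, levels = levels, curves = 1,
                                      replicates_per_point = replicates)
  tabs[[1]]
}

#' Run the full validation and uncertainty pipeline
#'
#' Executes generate -> integrate -> calibrate -> validate -> budget under
#' a single master seed and writes a consolidated report bundle: the
#' calibration tables and pooled fit record, the synthetic chromatogram
#' with its peak table and suitability metrics, a validation summary
#' (precision / accuracy / recovery), a forced-degradation summary, the
#' uncertainty budget, and a machine-readable `results.json` that logs the
#' per-stage seed lineage.  Every stochastic stage derives its own seed
#' from the master seed, so identical configurations produce
#' byte-identical bundles.
#'
#' Invalid configurations fail before anything is written, with every
#' violation listed (condition class `chromval_config_error`).
#'
#' @param config A \code{"run_config"}, e.g. [default_run_config()].
#' @param out_dir Output directory (default `config$output_dir`).
#' @return Invisibly, a list with elements \code{fit}, \code{suitability},
#'   \code{precision}, \code{accuracy}, \code{loq}, \code{recovery},
#'   \code{stress}, \code{budget}, \code{robustness}, \code{criteria}
#'   (pass/fail flags, including overall \code{pass}), \code{seeds} and
#'   \code{files}.
#' @export
run_full_validation <- function(config, out_dir = config$output_dir) {
  violations <- validate_config(config)
  if (length(violations) > 0L) {
    cond <- structure(
      class = c("chromval_config_error", "error", "condition"),
      list(message = paste0("invalid configuration:\n  ",
                            paste(violations, collapse = "\n  ")),
           call = sys.call(-1), violations = violations)
    )
    stop(cond)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  # seed lineage: one sub-seed per stochastic stage, all derived from the
  # master seed so any single table can be regenerated in isolation
  set.seed(config$seed)
  stage_names <- c("calibration", "suitability", "precision_intraday",
                   "precision_interday", "accuracy", "recovery", "stress",
                   "sample", "robustness")
  seeds <- stats::setNames(sample.int(.Machine$integer.max - 1L,
                                      length(stage_names)), stage_names)

  ## -- generate + calibrate -------------------------------------------------
  model <- response_model(config$response$true_slope,
                          config$response$true_intercept,
                          config$response$noise_rsd_by_level,
                          seed = seeds[["calibration"]])
  tabs <- generate_calibration_tables(model,
                                      levels = config$calibration$levels,
                                      curves = config$calibration$curves,
                                      replicates_per_point = config$calibration$replicates_per_point)
  for (k in seq_along(tabs)) {
    emit(tabs[[k]], sprintf("calibration_curve_%d.csv", k))
  }
  long <- do.call(rbind, lapply(seq_along(tabs), function(k) {
    df <- tabs[[k]]
    data.frame(curve = k,
               concentration = rep(as.numeric(names(df)), each = nrow(df)),
               response = unlist(df, use.names = FALSE))
  }))
  fit <- fit_calibration(long$concentration, long$response, curve = long$curve)
  emit(fit_record(fit), "fit_record.csv")

  ## -- integrate (system suitability) --------------------------------------
  su <- config$suitability
  chrom <- synthesize_chromatogram(
    list(do.call(peak_spec, su$impurity), do.call(peak_spec, su$main)),
    duration = su$duration, sampling_interval = su$sampling_interval,
    baseline_noise_sd = su$baseline_noise_sd, seed = seeds[["suitability"]])
  write_chromatogram(chrom, file.path(out_dir, "chromatogram.csv"))
  files <- c(files, file.path(out_dir, "chromatogram.csv"))
  peaks <- detect_and_integrate(chrom)
  emit(as.data.frame(peaks), "peaks.csv")
  suitability <- list(
    plates_main = theoretical_plates(peaks[nrow(peaks), ]),
    tailing_main = tailing_factor(peaks[nrow(peaks), ]),
    resolution = if (nrow(peaks) >= 2L) {
      resolution(peaks[1, ], peaks[2, ])
    } else NA_real_
  )

  ## -- precision ------------------------------------------------------------
  plev <- config$precision$levels
  intra <- .stage_areas(config, plev, config$precision$replicates,
                        seeds[["precision_intraday"]])
  inter <- .stage_areas(config, plev, config$precision$replicates,
                        seeds[["precision_interday"]],
                        rsd_map = config$precision$interday_rsd_by_level)
  precision <- data.frame(
    level = plev,
    intraday_rsd = vapply(intra, rsd, numeric(1)),
    interday_rsd = vapply(inter, rsd, numeric(1))
  )

  ## -- accuracy on spiked placebo -------------------------------------------
  alev <- config$accuracy$levels
  acc_tab <- .stage_areas(config, alev, config$accuracy$replicates,
                          seeds[["accuracy"]])
  to_conc <- function(y) (y - fit$intercept) / fit$slope
  accuracy <- do.call(rbind, lapply(seq_along(alev), function(j) {
    conc <- to_conc(acc_tab[[j]])
    data.frame(level = alev[j],
               accuracy_mean = accuracy_pct(mean(conc), alev[j]),
               accuracy_rsd = rsd(conc),
               mean_response = mean(acc_tab[[j]]))
  }))

  loq_row <- accuracy[which.min(accuracy$level), ]
  loq <- qualify_loq(loq_row$accuracy_mean, loq_row$accuracy_rsd,
                     loq_row$mean_response, config$blank_response)

  ## -- recovery on spiked gel ----------------------------------------------
  targets <- config$recovery$targets
  rec_tab <- .stage_areas(config, targets, config$recovery$replicates,
                          seeds[["recovery"]],
                          rsd_map = config$recovery$rsd_by_target)
  recovery <- recovery_summary(lapply(seq_along(targets), function(j) {
    recovery_experiment(targets[j], to_conc(rec_tab[[j]]))
  }))

  ## -- forced degradation ---------------------------------------------------
  st <- config$stress
  stress <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    k_deg <- rate_from_remaining(st$remaining_pct[i], st$duration_h[i])
    spec <- degradation_spec(st$condition[i], k_deg, st$duration_h[i],
                             impurity_channels = st$impurities[i],
                             replicate_rsd = st$replicate_rsd[i])
    tab <- generate_stress_table(spec, config$stress_initial_concentration,
                                 replicates = config$stress_replicates,
                                 seed = seeds[["stress"]] + i)
    s <- summarize_stress(tab)
    data.frame(condition = s$condition_label,
               recovered_pct_mean = s$recovered_pct_mean,
               recovered_pct_rsd = s$recovered_pct_rsd,
               impurities = s$impurity_count)
  }))
  emit(data.frame(condition = stress$condition,
                  recovered_pct = trunc_pct(stress$recovered_pct_mean),
                  rsd_pct = trunc_pct(stress$recovered_pct_rsd),
                  impurities = stress$impurities),
       "stress_summary.csv")

  ## -- sample assay and uncertainty budget ----------------------------------
  nom <- config$sample$nominal_concentration
  samp_tab <- .stage_areas(config, nom, config$sample$replicates,
                           seeds[["sample"]])
  est <- invert_calibration(fit, samp_tab[[1]])
  sample_concs <- to_conc(samp_tab[[1]])
  budget <- expanded_uncertainty(
    u_standard = u_standard(u_stock(config$standard$purity_pct),
                            config$standard$preparation_u),
    u_calibration = relative_calibration_uncertainty(est),
    u_precision = u_precision(values = sample_concs),
    u_accuracy = u_accuracy(recovery$s_eta, recovery$n),
    k = config$coverage_factor,
    concentration = est$x0
  )
  emit(budget_report(budget), "budget.csv")

  ## -- robustness -----------------------------------------------------------
  rb <- config$robustness
  set.seed(seeds[["robustness"]])
  grid <- do.call(rbind, lapply(rb$factors, function(f) {
    do.call(rbind, lapply(c("low", "nominal", "high"), function(lv) {
      jitter <- function(x) x * (1 + stats::rnorm(1, 0, rb$shift_rsd / 100))
      data.frame(factor = f, level = lv,
                 assay_pct = jitter(rb$base$assay_pct),
                 resolution = jitter(rb$base$resolution),
                 plates = jitter(rb$base$plates),
                 tailing = jitter(rb$base$tailing))
    }))
  }))
  robustness <- evaluate_robustness(grid)

  ## -- consolidated report --------------------------------------------------
  nrow_vs <- max(nrow(precision), nrow(recovery$per_level))
  pad <- function(x) { length(x) <- nrow_vs; x }
  validation_summary <- data.frame(
    level = pad(precision$level),
    intraday_rsd = pad(trunc_pct(precision$intraday_rsd)),
    interday_rsd = pad(trunc_pct(precision$interday_rsd)),
    accuracy_mean = pad(trunc_pct(accuracy$accuracy_mean)),
    accuracy_rsd = pad(trunc_pct(accuracy$accuracy_rsd)),
    target = pad(recovery$per_level$target),
    calculated = pad(trunc_pct(recovery$per_level$target *
                                 recovery$per_level$recovery_pct / 100)),
    recovery_pct = pad(trunc_pct(recovery$per_level$recovery_pct)),
    recovery_sd = pad(round(recovery$per_level$recovery_sd, 2))
  )
  emit(validation_summary, "validation_summary.csv")

  crit <- config$criteria
  hi <- precision$level >= crit$precision_levels_min
  criteria <- list(
    precision_ok = all(precision$intraday_rsd[hi] < crit$precision_rsd_max) &&
      all(precision$interday_rsd[hi] < crit$precision_rsd_max),
    loq_ok = loq$pass,
    robustness_ok = robustness$pass,
    suitability_ok = !is.na(suitability$resolution) &&
      suitability$resolution > crit$resolution_min &&
      suitability$plates_main > crit$plates_min
  )
  criteria$pass <- all(unlist(criteria))

  results <- list(
    seed = config$seed, seeds = as.list(seeds),
    fit = fit[c("slope", "intercept", "r_squared", "residual_sd", "n")],
    slope_rsd = slope_rsd(fit),
    suitability = suitability,
    precision = precision, accuracy = accuracy,
    loq = loq,
    recovery = list(mean_recovery = recovery$mean_recovery,
                    s_eta = recovery$s_eta, n = recovery$n,
                    per_level = recovery$per_level),
    stress = stress,
    sample = list(x0 = est$x0, s_x0 = est$s_x0, N = est$N),
    budget = unclass(budget),
    robustness = robustness,
    criteria = criteria
  )
  json_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(results, json_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  files <- c(files, json_path)

  invisible(c(results, list(files = files)))
}
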