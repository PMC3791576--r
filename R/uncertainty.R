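# Four-component ISO-GUM uncertainty budget on the relative (%) scale and
# its expanded form with coverage factor k.

#' Standard uncertainty of the stock standard purity
#'
#' A certified purity `P` percent carries a rectangular-distribution
#' tolerance of `100 - P`; the corresponding standard uncertainty is
#' \eqn{u_{stock} = (100 - P)/\sqrt{3}} percent.
#'
#' @param purity_pct Certified purity P in percent, 0 < P <= 100.
#' @return Standard uncertainty in percent.
#' @export
#' @examples
#' u_stock(99.50) # 0.2887
u_stock <- function(purity_pct) {
  if (any(purity_pct <= 0) || any(purity_pct > 100)) {
    stop("`purity_pct` must be in (0, 100]", call. = FALSE)
  }
  (100 - purity_pct) / sqrt(3)
}

#' Standard uncertainty of the measurement standard
#'
#' Quadratic addition of the stock and preparation components,
#' \eqn{u_{std} = \sqrt{u_{stock}^2 + u_{prep}^2}}.  When independent
#' standard preparations are made at each level the preparation term is
#' eliminated; pass `NULL` and the stock value is returned unchanged.
#'
#' @param u_stock Stock standard uncertainty, percent (>= 0).
#' @param u_preparation Preparation uncertainty, percent, or `NULL` when
#'   absorbed by independent preparations.
#' @return Percent.
#' @export
u_standard <- function(u_stock, u_preparation = NULL) {
  if (u_stock < 0) stop("`u_stock` must be >= 0", call. = FALSE)
  if (is.null(u_preparation) || is.na(u_preparation)) return(u_stock)
  if (u_preparation < 0) stop("`u_preparation` must be >= 0", call. = FALSE)
  sqrt(u_stock^2 + u_preparation^2)
}

#' Standard uncertainty of precision
#'
#' The precision component is the relative standard uncertainty of the
#' mean of the precision replicates: the replicate RSD divided by
#' \eqn{\sqrt{n}}.  Supply either the raw replicate `values`, or a
#' pre-computed `rsd_pct` together with `n`.
#'
#' @param values Replicate measurements (>= 2), or `NULL`.
#' @param rsd_pct Replicate RSD in percent (used when `values` is `NULL`).
#' @param n Number of replicates (used with `rsd_pct`).
#' @return Percent.
#' @export
#' @examples
#' u_precision(rsd_pct = 2.26, n = 5) # 1.0107
u_precision <- function(values = NULL, rsd_pct = NULL, n = NULL) {
  if (!is.null(values)) {
    if (length(values) < 2L) stop("need >= 2 precision replicates", call. = FALSE)
    return(rsd(values) / sqrt(length(values)))
  }
  if (is.null(rsd_pct) || is.null(n)) {
    stop("supply `values`, or both `rsd_pct` and `n`", call. = FALSE)
  }
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (rsd_pct < 0) stop("`rsd_pct` must be >= 0", call. = FALSE)
  rsd_pct / sqrt(n)
}

#' Standard uncertainty of accuracy (recovery)
#'
#' \eqn{u_{acc} = s(\eta)/\sqrt{n}} where \eqn{s(\eta)} is the relative
#' standard deviation of the individual recoveries and `n` the number of
#' recovery assays.
#'
#' @param s_eta Relative SD of recovery, percent (>= 0).
#' @param n Number of recovery assays (>= 1).
#' @return Percent.
#' @export
u_accuracy <- function(s_eta, n) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (s_eta < 0) stop("`s_eta` must be >= 0", call. = FALSE)
  s_eta / sqrt(n)
}

#' Expanded uncertainty budget
#'
#' Combines the four relative components in quadrature and applies the
#' coverage factor:
#' \deqn{U_{rel} = k \sqrt{u_{std}^2 + u_{cal}^2 + u_{prec}^2 + u_{acc}^2},}
#' with the absolute expanded uncertainty
#' \eqn{U_{abs} = U_{rel} \cdot c / 100} at the analyte concentration `c`.
#' `k = 2` corresponds to approximately 95 % coverage.
#'
#' @param u_standard,u_calibration,u_precision,u_accuracy The four
#'   relative components in percent, all >= 0.
#' @param k Coverage factor, > 0 (default 2).
#' @param concentration Analyte concentration `c` in ug/mL, > 0.
#' @return An object of class \code{"uncertainty_budget"} echoing the
#'   inputs plus \code{expanded_relative} (%) and \code{expanded_absolute}
#'   (ug/mL), and \code{dominant} naming the largest component.
#' @export
#' @examples
#' b <- expanded_uncertainty(0.29, 2.58, 1.01, 0.39, k = 2, concentration = 9.30)
#' round(b$expanded_relative, 2) # 5.63
expanded_uncertainty <- function(u_standard, u_calibration, u_precision,
                                 u_accuracy, k = 2, concentration) {
  comp <- c(standard = u_standard, calibration = u_calibration,
            precision = u_precision, accuracy = u_accuracy)
  if (any(comp < 0)) stop("uncertainty components must be >= 0", call. = FALSE)
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  if (concentration <= 0) stop("`concentration` must be > 0", call. = FALSE)
  rel <- k * sqrt(sum(comp^2))
  structure(
    list(u_standard = u_standard, u_calibration = u_calibration,
         u_precision = u_precision, u_accuracy = u_accuracy,
         coverage_factor = k, concentration = concentration,
         expanded_relative = rel,
         expanded_absolute = rel * concentration / 100,
         dominant = names(comp)[which.max(comp)]),
    class = "uncertainty_budget"
  )
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  print(budget_report(x), row.names = FALSE)
  cat(sprintf("(k = %g; dominant component: %s)\n", x$coverage_factor, x$dominant))
  invisible(x)
}

#' Tabular uncertainty-budget report
#'
#' Seven rows in budget order -- the four partial uncertainties, the
#' expanded relative and absolute values, and the concentration -- with
#' values displayed at two decimals.  [parse_budget_report()] reverses the
#' serialisation at display precision.
#'
#' @param budget An [expanded_uncertainty()] result.
#' @return A data frame with columns \code{quantity}, \code{unit},
#'   \code{value} (numeric, rounded to 2 decimals) and \code{display}
#'   (character, fixed 2-decimal format).
#' @export
budget_report <- function(budget) {
  stopifnot(inherits(budget, "uncertainty_budget"))
  vals <- c(budget$u_standard, budget$u_calibration, budget$u_precision,
            budget$u_accuracy, budget$expanded_relative,
            budget$expanded_absolute, budget$concentration)
  data.frame(
    quantity = c("U_standard", "U_calibration", "U_precision", "U_accuracy",
                 "U_expanded", "U_expanded", "concentration"),
    unit = c("%", "%", "%", "%", "%", "ug/mL", "ug/mL"),
    value = round(vals, 2),
    display = sprintf("%.2f", vals)
  )
}

#' @rdname budget_report
#' @param report A data frame produced by [budget_report()] (or read back
#'   from its delimited serialisation).
#' @param k Coverage factor used when the budget was built (not stored in
#'   the table).
#' @return `parse_budget_report()` returns an \code{uncertainty_budget}
#'   whose components equal the reported ones at display precision.
#' @export
parse_budget_report <- function(report, k = 2) {
  v <- as.numeric(report$display)
  expanded_uncertainty(v[1], v[2], v[3], v[4], k = k, concentration = v[7])
}
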