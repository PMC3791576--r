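# Linear calibration: OLS fit, linearity summaries, inverse prediction with
# its standard error, relative calibration uncertainty, and the LOQ rule.

#' Fit the linear calibration model
#'
#' Ordinary (unweighted) least squares of peak area on concentration.  The
#' returned fit carries every design quantity needed by the
#' inverse-prediction standard error: the residual SD
#' \eqn{s(r) = \sqrt{\sum (y_i - m x_i - b)^2 / (n - 2)}}, the number of
#' calibration points \eqn{n}, the mean concentration \eqn{\bar x}, the
#' mean response \eqn{\bar y} and \eqn{S_{xx} = \sum (x_i - \bar x)^2}.
#' When `curve` ids are supplied the replicate curves are additionally
#' fitted separately and their slopes stored, which supports the
#' slope-RSD linearity diagnostic and the replicate-curve confidence
#' interval (see [confint.calibration_fit()]).
#'
#' By convention \eqn{n} counts every point entering the pooled fit (30
#' when five 6-point curves are pooled), the same \eqn{n} whose \eqn{n-2}
#' scales \eqn{s(r)}.
#'
#' @param concentration Standard concentrations (ug/mL).
#' @param response Peak areas, same length.
#' @param curve Optional curve identifiers (replicate calibration curves);
#'   same length as `concentration`.
#' @return An object of class \code{"calibration_fit"} with fields
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{residual_sd},
#'   \code{n}, \code{x_bar}, \code{y_bar}, \code{sxx},
#'   \code{per_curve_slopes}.
#' @export
#' @examples
#' x <- c(0.5, 1, 5, 10, 20, 50)
#' fit <- fit_calibration(x, 44446.17 * x + 5597.38)
#' fit$slope
fit_calibration <- function(concentration, response, curve = NULL) {
  x <- as.numeric(concentration)
  y <- as.numeric(response)
  if (length(x) != length(y)) {
    stop("`concentration` and `response` must have the same length", call. = FALSE)
  }
  if (length(unique(x)) < 3L) {
    stop("need at least 3 distinct concentration levels", call. = FALSE)
  }
  n <- length(x)
  x_bar <- mean(x); y_bar <- mean(y)
  sxx <- sum((x - x_bar)^2)
  if (sxx <= 0) stop("zero spread in concentrations", call. = FALSE)
  m <- sum((x - x_bar) * (y - y_bar)) / sxx
  b <- y_bar - m * x_bar
  sse <- sum((y - m * x - b)^2)
  ssy <- sum((y - y_bar)^2)
  r2 <- if (ssy > 0) max(0, min(1, 1 - sse / ssy)) else 1
  sr <- sqrt(max(0, sse) / (n - 2))

  per_curve <- NULL
  if (!is.null(curve)) {
    if (length(curve) != n) {
      stop("`curve` must match the data length", call. = FALSE)
    }
    per_curve <- vapply(split(seq_len(n), curve), function(ix) {
      xb <- mean(x[ix]); yb <- mean(y[ix])
      sum((x[ix] - xb) * (y[ix] - yb)) / sum((x[ix] - xb)^2)
    }, numeric(1))
  }

  structure(
    list(slope = m, intercept = b, r_squared = r2, residual_sd = sr,
         n = n, x_bar = x_bar, y_bar = y_bar, sxx = sxx,
         per_curve_slopes = per_curve),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Linear calibration fit (n = %d points)\n", x$n))
  cat(sprintf("  y = %.4f x + %.4f   r^2 = %.5f   s(r) = %.4f\n",
              x$slope, x$intercept, x$r_squared, x$residual_sd))
  if (!is.null(x$per_curve_slopes)) {
    cat(sprintf("  %d replicate curves, slope RSD = %.3f %%\n",
                length(x$per_curve_slopes), slope_rsd(x)))
  }
  invisible(x)
}

#' Confidence interval for the calibration slope
#'
#' Two interval constructions are offered.  `"classical"` is the textbook
#' homoscedastic OLS t-interval, \eqn{m \pm t_{n-2} s(r)/\sqrt{S_{xx}}}.
#' `"per_curve"` treats the replicate-curve slopes as independent
#' estimates and uses their mean \eqn{\pm t_{c-1} \mathrm{SD}/\sqrt{c}};
#' it remains valid when the detector noise is relative
#' (heteroscedastic), where the classical interval undercovers.  The
#' default `"auto"` uses the replicate-curve interval whenever at least
#' three replicate curves were fitted, and the classical interval
#' otherwise.
#'
#' @param object A [fit_calibration()] result.
#' @param parm Ignored; only the slope interval is provided.
#' @param level Confidence level.
#' @param method `"auto"`, `"classical"` or `"per_curve"`.
#' @param ... Unused.
#' @return A 1 x 2 matrix of lower/upper bounds, as [stats::confint()].
#' @export
confint.calibration_fit <- function(object, parm = "slope", level = 0.95,
                                    method = c("auto", "classical", "per_curve"),
                                    ...) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (!is.null(object$per_curve_slopes) &&
                  length(object$per_curve_slopes) >= 3L) "per_curve" else "classical"
  }
  a <- (1 - level) / 2
  if (method == "per_curve") {
    sl <- object$per_curve_slopes
    if (is.null(sl) || length(sl) < 2L) {
      stop("per-curve interval needs >= 2 replicate curves", call. = FALSE)
    }
    c_n <- length(sl)
    centre <- mean(sl)
    hw <- stats::qt(1 - a, c_n - 1) * stats::sd(sl) / sqrt(c_n)
  } else {
    centre <- object$slope
    hw <- stats::qt(1 - a, object$n - 2) * object$residual_sd / sqrt(object$sxx)
  }
  out <- matrix(c(centre - hw, centre + hw), nrow = 1,
                dimnames = list("slope", sprintf("%.1f %%", 100 * c(a, 1 - a))))
  out
}

#' Relative standard deviation of the replicate-curve slopes
#'
#' @param fit A [fit_calibration()] result fitted with curve ids.
#' @return Slope RSD in percent.
#' @export
slope_rsd <- function(fit) {
  sl <- fit$per_curve_slopes
  if (is.null(sl) || length(sl) < 2L) {
    stop("fit has no replicate-curve slopes", call. = FALSE)
  }
  100 * stats::sd(sl) / mean(sl)
}

#' Inverse prediction with its standard deviation
#'
#' Estimates the concentration of an unknown from the mean of its `N`
#' replicate responses, \eqn{x_0 = (\bar y_0 - b)/m}, together with the
#' standard deviation of that estimate,
#' \deqn{s_{x_0} = \frac{s(r)}{m}\sqrt{\frac{1}{N} + \frac{1}{n} +
#'   \frac{(\bar y_0 - \bar y)^2}{m^2 \sum_i (x_i - \bar x)^2}}.}
#'
#' @param fit A [fit_calibration()] result.
#' @param unknown_responses Replicate peak areas of the unknown sample.
#' @return An object of class \code{"concentration_estimate"} with fields
#'   \code{x0}, \code{y0_bar}, \code{N}, \code{s_x0}.
#' @export
invert_calibration <- function(fit, unknown_responses) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (length(unknown_responses) == 0L) {
    stop("`unknown_responses` must be non-empty", call. = FALSE)
  }
  if (fit$slope == 0) stop("calibration slope is zero", call. = FALSE)
  N <- length(unknown_responses)
  y0_bar <- mean(unknown_responses)
  x0 <- (y0_bar - fit$intercept) / fit$slope
  s_x0 <- (fit$residual_sd / fit$slope) *
    sqrt(1 / N + 1 / fit$n +
           (y0_bar - fit$y_bar)^2 / (fit$slope^2 * fit$sxx))
  structure(list(x0 = x0, y0_bar = y0_bar, N = N, s_x0 = s_x0),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("x0 = %.4f ug/mL (s_x0 = %.4f, N = %d)\n", x$x0, x$s_x0, x$N))
  invisible(x)
}

#' Relative calibration uncertainty
#'
#' The calibration component of the uncertainty budget,
#' \eqn{u_{cal} = 100 \, s_{x_0} / x_0} percent.
#'
#' @param estimate A [invert_calibration()] result (or any list with
#'   fields \code{x0} and \code{s_x0}).
#' @return Percent relative uncertainty.
#' @export
relative_calibration_uncertainty <- function(estimate) {
  x0 <- estimate$x0
  if (is.null(x0) || x0 <= 0) {
    stop("`x0` must be > 0 for a relative uncertainty", call. = FALSE)
  }
  100 * estimate$s_x0 / x0
}

#' Limit-of-quantification qualification rule
#'
#' A concentration level qualifies as the LOQ when its replicate RSD is
#' strictly below 5 %, its accuracy lies within 100 +/- 5 %, and its mean
#' response is at least ten times the blank response.  All three checks
#' are evaluated and every violated criterion is reported.
#'
#' @param level_accuracy_pct Accuracy of the level, percent of nominal.
#' @param level_rsd_pct Replicate RSD of the level, percent.
#' @param level_mean_response Mean peak area at the level.
#' @param blank_response Blank peak area (>= 0).
#' @return A list with \code{pass} (logical) and \code{reasons} (character
#'   vector of violated criteria, empty on pass).
#' @export
#' @examples
#' qualify_loq(96.67, 0.91, 27820, 500)$pass
qualify_loq <- function(level_accuracy_pct, level_rsd_pct,
                        level_mean_response, blank_response) {
  if (blank_response < 0) stop("`blank_response` must be >= 0", call. = FALSE)
  reasons <- character(0)
  if (!(level_rsd_pct < 5)) {
    reasons <- c(reasons, sprintf("RSD %.2f %% is not lower than 5 %%", level_rsd_pct))
  }
  if (abs(level_accuracy_pct - 100) > 5) {
    reasons <- c(reasons, sprintf("accuracy %.2f %% outside 100 +/- 5 %%",
                                  level_accuracy_pct))
  }
  if (level_mean_response < 10 * blank_response) {
    reasons <- c(reasons, sprintf(
      "mean response %.1f below 10x blank response (%.1f)",
      level_mean_response, blank_response))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Flat key-value record of a calibration fit
#'
#' Serialises the fit summary in the delimited key--value layout used by
#' the pipeline outputs (slope, intercept, r^2, s(r), n, x_bar, sxx).
#'
#' @param fit A [fit_calibration()] result.
#' @return A two-column data frame (`key`, `value`).
#' @export
fit_record <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  data.frame(
    key = c("slope", "intercept", "r_squared", "residual_sd", "n",
            "x_bar", "sxx"),
    value = c(fit$slope, fit$intercept, fit$r_squared, fit$residual_sd,
              fit$n, fit$x_bar, fit$sxx)
  )
}
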