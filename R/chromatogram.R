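# Peak detection, integration and USP system-suitability metrics.

#' Chromatogram container
#'
#' A two-column time--intensity trace.  Times must be strictly increasing
#' and at least two samples long.
#'
#' @param times Sample times, minutes.
#' @param intensities Detector response at each time, same length.
#' @return A data frame with columns \code{time_min}, \code{intensity} and
#'   class \code{"chromatogram"}.
#' @export
chromatogram <- function(times, intensities) {
  if (length(times) < 2L || length(times) != length(intensities)) {
    stop("need >= 2 samples and equal-length times/intensities", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(time_min = times, intensity = intensities),
            class = c("chromatogram", "data.frame"))
}

#' @rdname chromatogram
#' @param chrom A chromatogram.
#' @param path File path; the format is comma-delimited with columns
#'   \code{time_min}, \code{intensity}.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  utils::write.csv(as.data.frame(chrom), path, row.names = FALSE)
  invisible(path)
}

#' @rdname chromatogram
#' @export
read_chromatogram <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "intensity") %in% names(df))) {
    stop("chromatogram file must have columns time_min, intensity", call. = FALSE)
  }
  chromatogram(df$time_min, df$intensity)
}

.empty_peak_table <- function() {
  structure(
    data.frame(retention_time = numeric(0), area = numeric(0),
               height = numeric(0), width_half = numeric(0),
               width_5pct = numeric(0), leading_5pct = numeric(0)),
    class = c("peak_table", "data.frame")
  )
}

# parabolic apex refinement through three samples around index i
.refine_apex <- function(t, y, i) {
  if (i <= 1L || i >= length(y)) return(c(rt = t[i], h = y[i]))
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom >= 0) return(c(rt = t[i], h = y2))
  d <- 0.5 * (y1 - y3) / denom
  d <- max(-0.5, min(0.5, d))
  c(rt = t[i] + d * (t[i + 1] - t[i]),
    h = y2 - 0.25 * (y1 - y3) * d)
}

#' Detect and integrate peaks in a chromatogram
#'
#' Baseline is assumed flat at the 5th percentile of the trace intensity.
#' Local maxima of the baseline-subtracted signal exceeding
#' `min_height_fraction` of the global maximum are taken as peak apexes;
#' candidate apexes not separated by a valley dropping below half the
#' smaller apex are merged.  Peak bounds are the nearest baseline
#' crossings (0.1 % of apex height) around each apex, with overlapping
#' peaks split at the valley minimum.  Areas are trapezoidal integrals of
#' the baseline-subtracted signal between the bounds; widths at 50 % and
#' 5 % of apex height come from linear interpolation of the edge
#' crossings.
#'
#' @param trace A [chromatogram()].
#' @param min_height_fraction Detection threshold as a fraction of the
#'   tallest signal, in (0, 1).
#' @return A \code{peak_table} data frame (possibly zero rows) with columns
#'   \code{retention_time}, \code{area}, \code{height}, \code{width_half},
#'   \code{width_5pct}, \code{leading_5pct}, ordered by retention time.
#' @seealso [theoretical_plates()], [tailing_factor()], [resolution()]
#' @export
detect_and_integrate <- function(trace, min_height_fraction = 0.01) {
  if (!inherits(trace, "chromatogram")) {
    trace <- chromatogram(trace$time_min, trace$intensity)
  }
  t <- trace$time_min
  if (any(diff(t) <= 0)) stop("non-monotone time axis", call. = FALSE)
  if (min_height_fraction <= 0 || min_height_fraction >= 1) {
    stop("`min_height_fraction` must be in (0, 1)", call. = FALSE)
  }
  baseline <- as.numeric(stats::quantile(trace$intensity, 0.05))
  y <- trace$intensity - baseline
  n <- length(y)
  smax <- max(y)
  if (smax <= 0) return(.empty_peak_table())
  thr <- min_height_fraction * smax

  i <- 2:(n - 1)
  apex <- i[y[i] > thr & y[i] > y[i - 1] & y[i] >= y[i + 1]]
  if (length(apex) == 0L) return(.empty_peak_table())

  # merge apexes not separated by a deep valley (< 50 % of the lower apex)
  if (length(apex) > 1L) {
    keep <- apex[1]
    for (a in apex[-1]) {
      prev <- keep[length(keep)]
      valley <- min(y[prev:a])
      if (valley < 0.5 * min(y[prev], y[a])) {
        keep <- c(keep, a)
      } else if (y[a] > y[prev]) {
        keep[length(keep)] <- a
      }
    }
    apex <- keep
  }

  rows <- lapply(seq_along(apex), function(k) {
    a <- apex[k]
    cross_tol <- 1e-3 * y[a]
    # left bound: baseline crossing, or valley minimum towards previous apex
    lb <- a
    lim <- if (k > 1L) {
      prev <- apex[k - 1]
      prev + which.min(y[prev:a]) - 1L
    } else 1L
    while (lb > lim && y[lb - 1] > cross_tol) lb <- lb - 1L
    rb <- a
    lim <- if (k < length(apex)) {
      nxt <- apex[k + 1]
      a + which.min(y[a:nxt]) - 1L
    } else n
    while (rb < lim && y[rb + 1] > cross_tol) rb <- rb + 1L

    ap <- .refine_apex(t, y, a)
    h <- unname(ap["h"])
    seg_t <- t[lb:rb]; seg_y <- y[lb:rb]
    area <- sum(diff(seg_t) * (utils::head(seg_y, -1) + utils::tail(seg_y, -1)) / 2)
    half <- .edge_crossings(seg_t, seg_y, a - lb + 1L, 0.5 * h)
    five <- .edge_crossings(seg_t, seg_y, a - lb + 1L, 0.05 * h)
    data.frame(retention_time = unname(ap["rt"]), area = area,
               height = unname(h),
               width_half = unname(half["trail"] - half["lead"]),
               width_5pct = unname(five["trail"] - five["lead"]),
               leading_5pct = unname(ap["rt"] - five["lead"]))
  })
  out <- do.call(rbind, rows)
  out <- out[stats::complete.cases(out), , drop = FALSE]
  out <- out[order(out$retention_time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("peak_table", "data.frame"))
}

#' @rdname detect_and_integrate
#' @param peaks A peak table.
#' @param path File path for the comma-delimited peak table.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}

.peak_field <- function(peak, field) {
  v <- peak[[field]]
  if (is.null(v)) stop("peak is missing field `", field, "`", call. = FALSE)
  v
}

#' Theoretical plate count (USP half-height convention)
#'
#' \eqn{N = 5.54 (t_R / W_{1/2})^2}, where \eqn{W_{1/2}} is the full peak
#' width at half height.
#'
#' @param peak A single peak: one row of a [detect_and_integrate()] peak
#'   table, or any list with fields \code{retention_time} and
#'   \code{width_half}.
#' @return Plate count (dimensionless); vectorised over peak-table rows.
#' @export
#' @examples
#' theoretical_plates(list(retention_time = 10, width_half = 1)) # 554
theoretical_plates <- function(peak) {
  tr <- .peak_field(peak, "retention_time")
  wh <- .peak_field(peak, "width_half")
  if (any(wh <= 0)) stop("`width_half` must be > 0", call. = FALSE)
  5.54 * (tr / wh)^2
}

#' USP tailing (symmetry) factor
#'
#' \eqn{T = W_{0.05} / (2 f)}: full width at 5 % of peak height divided by
#' twice the apex-to-leading-edge distance at the same height.  Exactly 1
#' for a symmetric peak.
#'
#' @inheritParams theoretical_plates
#' @return Tailing factor (dimensionless).
#' @export
tailing_factor <- function(peak) {
  w5 <- .peak_field(peak, "width_5pct")
  f <- .peak_field(peak, "leading_5pct")
  if (any(f <= 0)) stop("`leading_5pct` must be > 0", call. = FALSE)
  w5 / (2 * f)
}

#' Resolution between two adjacent peaks (half-height convention)
#'
#' \eqn{R_s = 1.18 (t_{R,2} - t_{R,1}) / (W_{1/2,1} + W_{1/2,2})}.  The
#' first argument must elute before the second; swapped arguments are
#' rejected so the result is never negative.
#'
#' @param earlier,later Single peaks (see [theoretical_plates()]);
#'   `earlier` must have the smaller retention time.
#' @return Resolution (dimensionless, >= 0).
#' @export
resolution <- function(earlier, later) {
  t1 <- .peak_field(earlier, "retention_time")
  t2 <- .peak_field(later, "retention_time")
  if (t2 < t1) {
    stop("`earlier` must elute before `later`: got retention times ",
         t1, " and ", t2, call. = FALSE)
  }
  w1 <- .peak_field(earlier, "width_half")
  w2 <- .peak_field(later, "width_half")
  if (any(c(w1, w2) <= 0)) stop("half-height widths must be > 0", call. = FALSE)
  1.18 * (t2 - t1) / (w1 + w2)
}
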