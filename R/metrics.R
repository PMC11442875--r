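#' A cell-index time series for one well
#'
#' One well's impedance trace: strictly increasing timestamps (hours),
#' finite CI values, and the condition metadata needed by the metrics and
#' the fitter.
#'
#' @param times numeric vector of timestamps in hours, strictly increasing.
#' @param ci numeric vector of cell-index values, same length as `times`.
#' @param condition label, e.g. `"no_effector"` or `"effector"`.
#' @param et_ratio effector-to-target ratio (0 for a no-effector well).
#' @param t_treat treatment time in hours, or `NA` for growth-only wells.
#' @param ci0 optional explicit initial model CI used by the fitter instead
#'   of the default convention (first observed CI).
#' @return An object of class `ci_series`.
#' @export
ci_series <- function(times, ci, condition = "no_effector", et_ratio = 0,
                      t_treat = NA_real_, ci0 = NULL) {
  times <- as.numeric(times); ci <- as.numeric(ci)
  if (length(times) != length(ci))
    stop("times and ci must have the same length")
  if (length(times) == 0L) stop("empty series")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (anyNA(ci) || any(!is.finite(ci))) stop("ci values must be finite")
  if (et_ratio < 0) stop("et_ratio must be nonnegative")
  structure(list(times = times, ci = ci, condition = condition,
                 et_ratio = et_ratio, t_treat = t_treat, ci0 = ci0),
            class = "ci_series")
}

#' @export
print.ci_series <- function(x, ...) {
  cat(sprintf("Cell-index series: '%s' (E:T = %g), %d samples, t in [%g, %g] h%s\n",
              x$condition, x$et_ratio, length(x$times), x$times[1],
              x$times[length(x$times)],
              if (is.finite(x$t_treat)) sprintf(", treated at %g h", x$t_treat) else ""))
  invisible(x)
}

#' Normalize a cell-index series to its pre-treatment value
#'
#' Divides every CI value by the CI of the last sample at or before the
#' treatment time, the value measured just before effector addition, so the
#' reference sample maps to 1.0.  This is the normalisation convention of
#' the RTCA instrument software.
#'
#' @param series a [ci_series()].
#' @param t_treat treatment time in hours; defaults to the series metadata.
#' @return A new `ci_series` with normalized CI values.
#' @export
normalize_ci <- function(series, t_treat = series$t_treat) {
  stopifnot(inherits(series, "ci_series"))
  if (!is.finite(t_treat)) stop("a treatment time is required for normalization")
  idx <- which(series$times <= t_treat)
  if (length(idx) == 0L) stop("no sample at or before the treatment time")
  ref <- series$ci[max(idx)]
  if (ref <= 0) stop(sprintf("reference CI at t = %g h is %g; must be positive",
                             series$times[max(idx)], ref))
  out <- series
  out$ci <- series$ci / ref
  out$t_treat <- t_treat
  out
}

#' Percent cytolysis over time
#'
#' At each shared post-treatment time, computes
#' `(CI_no_effector - CI_effector) / CI_no_effector * 100`.  Both series are
#' normalized to their pre-treatment reference first (the convention in which
#' killing curves are reported) unless `normalized = FALSE`.  Negative values
#' (effector well grew more than the control) are reported as computed, not
#' clamped.  If the two wells were sampled on different grids, the effector
#' series is linearly interpolated onto the no-effector grid over the
#' overlapping span.
#'
#' @param no_effector,effector [ci_series()] objects for the control and
#'   effector wells.
#' @param t_treat treatment time in hours; defaults to the effector series
#'   metadata.
#' @param normalized normalize both series before comparing (default `TRUE`).
#' @return An object of class `cytolysis_curve` with fields `times` (hours
#'   since treatment, strictly increasing), `cytolysis` (percent, <= 100)
#'   and `et_ratio`.
#' @export
percent_cytolysis <- function(no_effector, effector,
                              t_treat = effector$t_treat, normalized = TRUE) {
  stopifnot(inherits(no_effector, "ci_series"), inherits(effector, "ci_series"))
  if (!is.finite(t_treat)) stop("a treatment time is required")
  if (normalized) {
    no_effector <- normalize_ci(no_effector, t_treat)
    effector <- normalize_ci(effector, t_treat)
  }
  # post-treatment portion of the no-effector grid, restricted to overlap
  tmax <- min(max(no_effector$times), max(effector$times))
  keep <- no_effector$times > t_treat & no_effector$times <= tmax + 1e-9
  tt <- no_effector$times[keep]
  if (length(tt) == 0L) stop("no overlapping post-treatment times")
  ci_no <- no_effector$ci[keep]
  same_grid <- length(effector$times) == length(no_effector$times) &&
    isTRUE(all(abs(effector$times - no_effector$times) < 1e-9))
  if (same_grid) {
    ci_eff <- effector$ci[keep]
  } else {
    ci_eff <- stats::approx(effector$times, effector$ci, xout = tt)$y
  }
  if (any(ci_no == 0))
    stop("no-effector CI is zero at an evaluated time; percent cytolysis undefined")
  pct <- (ci_no - ci_eff) / ci_no * 100
  cytolysis_curve(tt - t_treat, pct, et_ratio = effector$et_ratio)
}

#' @rdname percent_cytolysis
#' @param times hours since treatment, strictly increasing.
#' @param cytolysis percent cytolysis values (<= 100; may be negative).
#' @param et_ratio effector-to-target ratio of the underlying well.
#' @export
cytolysis_curve <- function(times, cytolysis, et_ratio = NA_real_) {
  if (length(times) != length(cytolysis)) stop("length mismatch")
  if (length(times) == 0L) stop("empty cytolysis curve")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(cytolysis > 100 + 1e-9))
    stop("percent cytolysis cannot exceed 100")
  structure(list(times = as.numeric(times), cytolysis = as.numeric(cytolysis),
                 et_ratio = et_ratio),
            class = "cytolysis_curve")
}

#' Killing Time: earliest time a cytolysis threshold is reached
#'
#' The Killing Time KT_p is the earliest post-treatment time at which the
#' percent-cytolysis curve first reaches the threshold p, found by linear
#' interpolation between the bracketing samples (first crossing wins).  If
#' the curve never reaches the threshold within the observation window the
#' result is flagged "not detected" (ND), mirroring how KT values that
#' cannot be determined are reported.
#'
#' @param curve a `cytolysis_curve` (times in hours since treatment).
#' @param threshold percent cytolysis threshold in (0, 100].
#' @return A list of class `killing_time_result` with fields `threshold`,
#'   `et_ratio`, `kt` (hours since treatment, `NA` when not detected) and
#'   `detected` (logical).
#' @examples
#' cv <- cytolysis_curve(c(0, 2, 4, 6), c(0, 30, 40, 80), et_ratio = 1)
#' killing_time(cv, 50)$kt  # 4.5
#' @export
killing_time <- function(curve, threshold) {
  stopifnot(inherits(curve, "cytolysis_curve"))
  if (!(threshold > 0 && threshold <= 100))
    stop("threshold must lie in (0, 100]")
  tt <- curve$times; v <- curve$cytolysis
  kt <- NA_real_
  if (v[1] >= threshold) {
    kt <- tt[1]
  } else {
    above <- which(v >= threshold)
    if (length(above) > 0L) {
      j <- above[1]
      kt <- tt[j - 1] + (tt[j] - tt[j - 1]) * (threshold - v[j - 1]) / (v[j] - v[j - 1])
    }
  }
  structure(list(threshold = threshold, et_ratio = curve$et_ratio,
                 kt = kt, detected = is.finite(kt)),
            class = "killing_time_result")
}

#' @export
print.killing_time_result <- function(x, ...) {
  cat(sprintf("KT_%g at E:T %g: %s\n", x$threshold, x$et_ratio,
              if (x$detected) sprintf("%.3g h", x$kt) else "ND"))
  invisible(x)
}

#' Killing-time table for a panel of wells
#'
#' Computes one Killing Time per (E:T ratio, threshold) pair from a panel
#' containing exactly one no-effector well and one or more effector wells.
#' Not-detected entries are preserved (`kt_h = NA`, `detected = FALSE`).
#'
#' @param panel a list of [ci_series()]: one with `et_ratio == 0` (the
#'   no-effector control) and at least one effector well.
#' @param thresholds percent thresholds (default `c(20, 50, 60, 80)`).
#' @param t_treat treatment time; defaults to the effector wells' metadata.
#' @param normalized passed to [percent_cytolysis()].
#' @return A data frame with columns `et_ratio`, `threshold_pct`, `kt_h`,
#'   `detected`.
#' @export
killing_time_table <- function(panel, thresholds = c(20, 50, 60, 80),
                               t_treat = NULL, normalized = TRUE) {
  stopifnot(is.list(panel), length(panel) >= 2L)
  ratios <- vapply(panel, function(s) s$et_ratio, 1.0)
  ctrl <- which(ratios == 0)
  if (length(ctrl) != 1L)
    stop("panel must contain exactly one no-effector series (et_ratio == 0)")
  eff <- panel[-ctrl]
  rows <- list()
  for (s in eff) {
    tt <- if (is.null(t_treat)) s$t_treat else t_treat
    cv <- percent_cytolysis(panel[[ctrl]], s, t_treat = tt,
                            normalized = normalized)
    for (p in thresholds) {
      kt <- killing_time(cv, p)
      rows[[length(rows) + 1L]] <- data.frame(
        et_ratio = s$et_ratio, threshold_pct = p,
        kt_h = kt$kt, detected = kt$detected)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
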