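#' Settings of the adaptive Runge-Kutta integrator
#'
#' The model is solved with a classic fourth-order Runge-Kutta scheme using
#' step-doubling error control: each step is taken once at full size and
#' twice at half size, the discrepancy (scaled by 1/15) drives acceptance and
#' the step-size update, and the accepted state is the locally extrapolated
#' two-half-steps solution.  Steps whose accepted state would leave the
#' nonnegative orthant are rejected and halved; components with magnitude
#' below 1e-12 are floored to zero.
#'
#' @param rtol relative tolerance on the local error (default 1e-6).
#' @param atol absolute tolerance (default 1e-9, CI units).
#' @param h_init initial step size (hours).
#' @param h_min,h_max smallest and largest permitted step (hours).  The
#'   default cap of 1/12 h (5 min, the instrument's sampling cadence) keeps
#'   the dense-output interpolation error at the level of the integration
#'   tolerance.
#' @param safety step-size safety factor (default 0.9).
#' @param max_steps hard cap on accepted+rejected steps per call.
#' @return A list of class `integrator_settings`.
#' @export
integrator_settings <- function(rtol = 1e-6, atol = 1e-9, h_init = 0.01,
                                h_min = 1e-8, h_max = 1 / 12, safety = 0.9,
                                max_steps = 500000L) {
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive")
  if (h_min <= 0 || h_min > h_max) stop("need 0 < h_min <= h_max")
  if (safety <= 0 || safety >= 1) stop("safety factor must lie in (0, 1)")
  structure(list(rtol = rtol, atol = atol, h_init = h_init, h_min = h_min,
                 h_max = h_max, safety = safety,
                 max_steps = as.integer(max_steps)),
            class = "integrator_settings")
}

#' Construct a system state vector
#'
#' @param y length-M vector of cancer subpopulation levels (CI units, >= 0).
#' @param x_A active T-cell level (CI-equivalent, >= 0).
#' @param x_E exhausted T-cell level (CI-equivalent, >= 0).
#' @return A named numeric vector `c(y_1..y_M, x_A, x_E)`.
#' @export
system_state <- function(y, x_A = 0, x_E = 0) {
  if (any(c(y, x_A, x_E) < 0)) stop("state components must be nonnegative")
  stats::setNames(c(y, x_A, x_E),
                  c(paste0("y_", seq_along(y)), "x_A", "x_E"))
}

#' Right-hand side of the tumor/T-cell ODE system
#'
#' Pure evaluation of the model's time derivatives at a given state; see
#' [model_parameters()] for the equations.
#'
#' @param state numeric vector `c(y_1..y_M, x_A, x_E)` (see [system_state()]).
#' @param params a [model_parameters()] object.
#' @return Named numeric vector of derivatives, same shape as `state`
#'   (units: per hour).
#' @examples
#' p <- model_parameters(r = 2, d = 1, a = 1, K = 2, h = 0.8, l = 1,
#'                       b_A = 0.5, b_E = 0.5, r_A = 2, d_E = 1, C = 10)
#' derivatives(system_state(1, 0.5, 0), p)
#' @export
derivatives <- function(state, params) {
  stopifnot(inherits(params, "model_parameters"))
  n <- params$M + 2L
  if (length(state) != n)
    stop(sprintf("state has length %d but the model with M = %d needs %d (y_1..y_M, x_A, x_E)",
                 length(state), params$M, n))
  if (any(state < 0)) stop("state components must be nonnegative")
  out <- cpp_derivs(as_theta(params), as.numeric(state))
  stats::setNames(out, c(paste0("y_", seq_len(params$M)), "x_A", "x_E"))
}

new_trajectory <- function(segments, params) {
  structure(list(segments = segments, params = params, M = params$M),
            class = "ci_trajectory")
}

#' Integrate the model over a time span
#'
#' Deterministically solves the ODE system from `t0` to `t1`, storing every
#' accepted step together with its derivative so the solution can be
#' evaluated at arbitrary times by cubic Hermite interpolation
#' ([trajectory_states()], [observable_ci()]).
#'
#' @param params a [model_parameters()] object.
#' @param state0 initial state `c(y_1..y_M, x_A, x_E)`, all components >= 0.
#' @param t0,t1 span in hours, `t1 > t0`.
#' @param settings an [integrator_settings()] object.
#' @return An object of class `ci_trajectory`.
#' @export
integrate_model <- function(params, state0, t0, t1,
                            settings = integrator_settings()) {
  stopifnot(inherits(params, "model_parameters"))
  if (t1 <= t0) stop("t1 must be greater than t0")
  if (any(state0 < 0)) stop("initial state must be nonnegative")
  res <- cpp_integrate(as_theta(params), as.numeric(state0), t0, t1,
                       settings$rtol, settings$atol, settings$h_init,
                       settings$h_min, settings$h_max, settings$safety,
                       settings$max_steps)
  if (!res$ok)
    stop(sprintf("integration failed at t = %.6g h: step size underflow or step budget exhausted",
                 res$t_fail))
  cols <- c(paste0("y_", seq_len(params$M)), "x_A", "x_E")
  colnames(res$states) <- cols
  colnames(res$derivs) <- cols
  seg <- list(times = res$times, states = res$states, derivs = res$derivs)
  new_trajectory(list(seg), params)
}

traj_span <- function(traj) {
  n <- length(traj$segments)
  c(traj$segments[[1]]$times[1],
    traj$segments[[n]]$times[length(traj$segments[[n]]$times)])
}

#' @export
print.ci_trajectory <- function(x, ...) {
  sp <- traj_span(x)
  ns <- sum(vapply(x$segments, function(s) length(s$times), 1L))
  cat(sprintf("Model trajectory: M = %d, t in [%g, %g] h, %d stored steps, %d segment(s)\n",
              x$M, sp[1], sp[2], ns, length(x$segments)))
  invisible(x)
}

# Cubic Hermite interpolation of all state columns of one segment.
interp_segment <- function(seg, times) {
  tt <- seg$times
  idx <- findInterval(times, tt, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx >= length(tt)] <- length(tt) - 1L
  if (length(tt) == 1L) {
    return(seg$states[rep(1L, length(times)), , drop = FALSE])
  }
  h <- tt[idx + 1L] - tt[idx]
  th <- (times - tt[idx]) / h
  t2 <- th * th; t3 <- t2 * th
  h00 <- 2 * t3 - 3 * t2 + 1
  h10 <- t3 - 2 * t2 + th
  h01 <- -2 * t3 + 3 * t2
  h11 <- t3 - t2
  ya <- seg$states[idx, , drop = FALSE]
  yb <- seg$states[idx + 1L, , drop = FALSE]
  fa <- seg$derivs[idx, , drop = FALSE]
  fb <- seg$derivs[idx + 1L, , drop = FALSE]
  h00 * ya + (h10 * h) * fa + h01 * yb + (h11 * h) * fb
}

#' Evaluate a trajectory at arbitrary times
#'
#' States between stored steps are obtained by cubic Hermite interpolation of
#' the stored states and derivatives (matching the integrator's order).  When
#' the trajectory contains a treatment-time discontinuity, query times at or
#' after the jump use the post-treatment segment.
#'
#' @param traj a `ci_trajectory` from [integrate_model()],
#'   [simulate_growth()] or [simulate_coculture()].
#' @param times numeric vector of query times (hours) within the span.
#' @return A matrix with one row per query time and columns
#'   `y_1..y_M, x_A, x_E`.
#' @export
trajectory_states <- function(traj, times) {
  stopifnot(inherits(traj, "ci_trajectory"))
  sp <- traj_span(traj)
  if (any(times < sp[1] - 1e-9) || any(times > sp[2] + 1e-9))
    stop(sprintf("query times outside trajectory span [%g, %g] h", sp[1], sp[2]))
  times <- pmin(pmax(times, sp[1]), sp[2])
  starts <- vapply(traj$segments, function(s) s$times[1], 1.0)
  segi <- findInterval(times, starts)  # times >= a later segment start use it
  segi[segi < 1L] <- 1L
  out <- matrix(NA_real_, length(times), traj$M + 2L)
  for (k in unique(segi)) {
    sel <- segi == k
    out[sel, ] <- interp_segment(traj$segments[[k]], times[sel])
  }
  colnames(out) <- c(paste0("y_", seq_len(traj$M)), "x_A", "x_E")
  out
}

#' Observable cell index along a trajectory
#'
#' The impedance instrument sees only attached cancer cells, so the modelled
#' cell index is the sum of the cancer subpopulations, `sum_i y_i(t)`; the
#' suspended T-cell compartments are excluded.
#'
#' @inheritParams trajectory_states
#' @return Numeric vector of CI values, one per query time.
#' @export
observable_ci <- function(traj, times) {
  st <- trajectory_states(traj, times)
  rowSums(st[, seq_len(traj$M), drop = FALSE])
}

#' @export
as.data.frame.ci_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                        times = NULL, ...) {
  if (is.null(times)) {
    times <- unlist(lapply(x$segments, function(s) s$times), use.names = FALSE)
    times <- times[!duplicated(times)]
  }
  st <- trajectory_states(x, times)
  df <- data.frame(time_h = times, st, check.names = FALSE)
  df$ci_total <- rowSums(st[, seq_len(x$M), drop = FALSE])
  df
}

#' Export a trajectory to CSV
#'
#' Columns: `time_h`, `y_1..y_M`, `x_A`, `x_E`, `ci_total`.
#'
#' @param traj a `ci_trajectory`.
#' @param path output file path.
#' @param times optional evaluation grid; defaults to the stored step times.
#' @return The path, invisibly.
#' @export
trajectory_to_csv <- function(traj, path, times = NULL) {
  df <- as.data.frame(traj, times = times)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Simulate cancer-only growth
#'
#' Solves the model with no T cells present (`x_A = x_E = 0` throughout),
#' the configuration of the effector-free wells used to estimate the
#' intrinsic growth parameters.  The measured initial cell index `ci0` is
#' divided across the M subpopulations by `fractions` (equal split by
#' default).
#'
#' @param params a [model_parameters()] object.
#' @param ci0 initial total cell index (> 0).
#' @param t1 end of the span (hours).
#' @param t0 start of the span (hours, default 0).
#' @param fractions optional length-M vector of nonnegative fractions summing
#'   to 1 giving the initial split of `ci0`.
#' @param settings an [integrator_settings()] object.
#' @return A `ci_trajectory` whose `x_A`, `x_E` components are identically 0.
#' @export
simulate_growth <- function(params, ci0, t1, t0 = 0, fractions = NULL,
                            settings = integrator_settings()) {
  if (ci0 <= 0) stop("ci0 must be positive")
  y0 <- split_ci0(ci0, params$M, fractions)
  integrate_model(params, c(y0, 0, 0), t0, t1, settings)
}

split_ci0 <- function(ci0, M, fractions = NULL) {
  if (is.null(fractions)) fractions <- rep(1 / M, M)
  if (length(fractions) != M) stop(sprintf("fractions must have length M = %d", M))
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be nonnegative and sum to 1")
  ci0 * fractions
}

#' Simulate a co-culture killing experiment
#'
#' Cancer-only growth on `[t0, t_treat]`; at the treatment time the active
#' T-cell level jumps to `xA0` (exhausted level to 0) and the full system is
#' integrated to `t_end`.  The cancer components are continuous across the
#' jump; the integrator is stopped and restarted exactly at `t_treat` so no
#' step crosses the discontinuity.
#'
#' If `xA0` is `NULL` it is computed from the effector-to-target ratio as
#' `et_ratio * CI(t_treat)`, which makes interaction rates comparable across
#' wells with different attachment levels.
#'
#' @inheritParams simulate_growth
#' @param t_treat treatment time (hours), strictly inside `(t0, t_end)`.
#' @param xA0 active T-cell level added at `t_treat` (CI-equivalent, >= 0).
#' @param et_ratio effector-to-target ratio used when `xA0` is `NULL`.
#' @param t_end end of the follow-up (hours).
#' @return A `ci_trajectory` with two segments split at `t_treat`.
#' @export
simulate_coculture <- function(params, ci0, t_treat, t_end, xA0 = NULL,
                               et_ratio = NULL, t0 = 0, fractions = NULL,
                               settings = integrator_settings()) {
  if (ci0 <= 0) stop("ci0 must be positive")
  if (!(t0 < t_treat && t_treat < t_end))
    stop("need t0 < t_treat < t_end")
  growth <- simulate_growth(params, ci0, t_treat, t0 = t0,
                            fractions = fractions, settings = settings)
  seg1 <- growth$segments[[1]]
  y_treat <- seg1$states[nrow(seg1$states), seq_len(params$M)]
  if (is.null(xA0)) {
    if (is.null(et_ratio)) stop("either xA0 or et_ratio must be given")
    xA0 <- et_ratio * sum(y_treat)
  }
  if (xA0 < 0) stop("xA0 must be nonnegative")
  post <- integrate_model(params, c(y_treat, xA0, 0), t_treat, t_end, settings)
  new_trajectory(list(seg1, post$segments[[1]]), params)
}
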