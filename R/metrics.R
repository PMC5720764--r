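#' Resolve sensor forces into streamwise and lateral components
#'
#' The force transducer rotates with the pitch actuator, so its axes must
#' be rotated back through the instantaneous pitch angle:
#' `Fx = Fx_meas cos(theta) + Fy_meas sin(theta)`,
#' `Fy = -Fx_meas sin(theta) + Fy_meas cos(theta)`. A constant `theta`
#' also corrects a static sensor misalignment.
#'
#' @param Fx_meas,Fy_meas Measured components (N), vectorized.
#' @param theta Pitch angle (rad), scalar or vector.
#' @return List with `Fx`, `Fy` (N).
#' @export
resolve_forces <- function(Fx_meas, Fy_meas, theta) {
  if (any(!is.finite(Fx_meas)) || any(!is.finite(Fy_meas)) || any(!is.finite(theta)))
    stop("inputs must be finite")
  list(Fx = Fx_meas * cos(theta) + Fy_meas * sin(theta),
       Fy = -Fx_meas * sin(theta) + Fy_meas * cos(theta))
}

#' Subtract rod-only loads from an assembly trial
#'
#' The sensor can only measure the rod+body assembly (or the rod alone);
#' the rod series is linearly interpolated onto the assembly timestamps and
#' subtracted element-wise, isolating the loads on the body. Provenance of
#' the result is `"foil-only"`.
#'
#' @param assembly,rod `load_series` objects with overlapping time ranges;
#'   assembly timestamps must lie within the rod's range.
#' @return A `load_series` with provenance `"foil-only"`. Nondimensional
#'   columns are dropped (re-derive after subtraction).
#' @export
subtract_rod <- function(assembly, rod) {
  stopifnot(inherits(assembly, "load_series"), inherits(rod, "load_series"))
  if (min(assembly$t) > max(rod$t) || max(assembly$t) < min(rod$t))
    stop("assembly and rod series have non-overlapping time ranges")
  if (min(assembly$t) < min(rod$t) - 1e-9 || max(assembly$t) > max(rod$t) + 1e-9)
    stop("rod series does not cover the assembly time range")
  out <- assembly[c("t", "Fx", "Fy", "Tz")]
  for (cc in c("Fx", "Fy", "Tz")) {
    rv <- if (nrow(rod) == 1) rep(rod[[cc]], nrow(out))
          else stats::approx(rod$t, rod[[cc]], xout = out$t)$y
    out[[cc]] <- out[[cc]] - rv
  }
  if ("theta" %in% names(assembly)) out$theta <- assembly$theta
  load_series_frame(out, provenance = "foil-only",
                    period = attr(assembly, "period"))
}

#' Phase-average replicate motion cycles
#'
#' Folds the series into `n_cycles` consecutive segments of one period
#' each and returns the pointwise mean and sample standard deviation - the
#' repeatability summary for replicate cycles.
#'
#' @param x Numeric series sampled at `fs`.
#' @param period Motion-cycle period (s).
#' @param n_cycles Number of cycles to fold, >= 2 for a nonzero sd.
#' @param fs Sampling rate (Hz).
#' @return List with `mean` and `sd`, each of length
#'   `round(period * fs)`.
#' @export
phase_average <- function(x, period, n_cycles, fs) {
  spc <- round(period * fs)
  if (spc < 2) stop("period is not resolvable at this sampling rate")
  if (length(x) < n_cycles * spc)
    stop(sprintf("series has %d samples; %d cycles of %d samples required",
                 length(x), n_cycles, spc))
  m <- matrix(x[seq_len(n_cycles * spc)], nrow = spc)
  list(mean = rowMeans(m), sd = apply(m, 1, stats::sd))
}

#' Pearson correlation with Fisher 95% confidence interval
#'
#' @param M,C Equal-length numeric series (measured, calculated), n >= 4,
#'   both non-constant.
#' @return List with `r` and `ci95 = c(low, high)` from the Fisher
#'   z-transform, `z +/- 1.96 / sqrt(n - 3)`.
#' @export
correlation_with_ci <- function(M, C) {
  n <- length(M)
  if (length(C) != n) stop("series lengths differ")
  if (n < 4) stop("need n >= 4")
  if (stats::sd(M) == 0 || stats::sd(C) == 0)
    stop("correlation undefined for a constant series")
  r <- stats::cor(M, C)
  z <- atanh(r)
  se <- 1.96 / sqrt(n - 3)
  list(r = r, ci95 = tanh(c(z - se, z + se)))
}

#' Root-mean-square error as a percentage of the reference range
#'
#' `RMSE% = 100 * sqrt(mean((M - C)^2)) / (max(C) - min(C))`, with `C` the
#' calculated (reference) trace.
#'
#' @param M,C Equal-length numeric series.
#' @return RMSE percentage (>= 0).
#' @export
rmse_percent <- function(M, C) {
  if (length(M) != length(C)) stop("series lengths differ")
  rng <- max(C) - min(C)
  if (rng == 0) stop("RMSE% undefined: reference trace is constant")
  100 * sqrt(mean((M - C)^2)) / rng
}

#' Phase lag between two traces as a percentage of the motion cycle
#'
#' Cross-correlation of the mean-removed signals, searched within plus or
#' minus one period to avoid cycle-aliased lags. Positive lag means the
#' calculated trace `C` lags the measured trace `M` (is shifted later in
#' time).
#'
#' @param M,C Equal-length numeric series spanning at least one period.
#' @param period Motion-cycle period (s).
#' @param fs Sampling rate (Hz).
#' @return Signed lag in percent of the period.
#' @export
phase_lag <- function(M, C, period, fs) {
  n <- length(M)
  if (length(C) != n) stop("series lengths differ")
  spc <- round(period * fs)
  if (n < spc) stop("series must span at least one period")
  if (stats::sd(M) == 0 || stats::sd(C) == 0) stop("phase lag undefined for flat inputs")
  lags <- -spc:spc
  # Pearson correlation of the overlapping windows: an exact-match lag
  # scores 1 regardless of overlap length, so window-composition effects
  # cannot favour a wrong lag
  score <- vapply(lags, function(k) {
    if (k >= 0) { a <- M[seq_len(n - k)]; b <- C[seq_len(n - k) + k] }
    else { a <- M[seq_len(n + k) - k]; b <- C[seq_len(n + k)] }
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, numeric(1))
  # a delay of tau on periodic data is indistinguishable from an advance of
  # period - tau; among (numerically) tied maxima take the smallest |lag|
  tied <- which(score >= max(score) - 1e-9)
  best <- lags[tied[which.min(abs(lags[tied]))]]
  100 * best / spc
}

#' Out-of-plane flow fraction
#'
#' `Vz* = |Vz| / sqrt(Vx^2 + Vy^2 + Vz^2)`: the fraction of the local total
#' velocity magnitude that is out of the imaging plane, a diagnostic for
#' how well the 2D assumption holds (0 = purely planar, 1 = purely
#' vertical).
#'
#' @param Vx,Vy In-plane velocity components (m/s), vectorized.
#' @param Vz Out-of-plane component (m/s).
#' @return Dimensionless value in `[0, 1]`.
#' @export
vz_star <- function(Vx, Vy, Vz) {
  tot <- sqrt(Vx^2 + Vy^2 + Vz^2)
  if (any(tot == 0)) stop("total velocity is zero")
  abs(Vz) / tot
}

#' Compare a measured and a calculated load trace
#'
#' Bundles the three agreement metrics: Pearson correlation with its 95%
#' Fisher confidence interval (shape), RMSE% of the reference range
#' (magnitude), and cross-correlation phase lag in percent of the motion
#' cycle (timing; positive = calculated trace lags the measured one).
#'
#' @param M,C Equal-length numeric traces (measured, calculated).
#' @param period Motion-cycle period (s).
#' @param fs Sampling rate (Hz).
#' @return An object of class `comparison_report`: list with `r`, `ci95`,
#'   `rmse_pct`, `lag_pct`, `n`, `fs`, and the sign convention string.
#' @export
compare_traces <- function(M, C, period, fs) {
  cr <- correlation_with_ci(M, C)
  structure(list(r = cr$r, ci95 = cr$ci95,
                 rmse_pct = rmse_percent(M, C),
                 lag_pct = phase_lag(M, C, period, fs),
                 n = length(M), fs = fs,
                 lag_sign = "positive = calculated trace lags measured"),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison (n=%d, fs=%g Hz):\n", x$n, x$fs))
  cat(sprintf("  r = %.4f  (95%% CI %.4f, %.4f)\n", x$r, x$ci95[1], x$ci95[2]))
  cat(sprintf("  RMSE%% = %.2f\n", x$rmse_pct))
  cat(sprintf("  phase lag = %+.2f%% of cycle (%s)\n", x$lag_pct, x$lag_sign))
  invisible(x)
}
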