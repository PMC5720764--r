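# Butterworth low-pass design as second-order sections, plus zero-phase
# forward-backward filtering. No DSP package ships with the target image, so
# the design is done from the analog prototype poles via the bilinear
# transform; the stopband/passband behaviour is checked against the analytic
# magnitude response in the tests.

# SOS matrix (k x 6: b0 b1 b2 a0 a1 a2, a0 = 1) for an order-n Butterworth
# low-pass with cutoff fc at sampling rate fs.
butter_lowpass_sos <- function(n, fc, fs) {
  if (fc <= 0 || fc >= fs / 2) stop("cutoff must lie in (0, Nyquist)")
  W <- tan(pi * fc / fs)                       # pre-warped analog cutoff
  sos <- NULL
  n <- as.integer(n)
  if (n < 1) stop("order must be >= 1")
  npairs <- n %/% 2
  for (k in seq_len(npairs)) {
    # b = -2 Re(pole) of the unit-cutoff analog prototype pair
    b <- -2 * cos(pi * (2 * k + n - 1) / (2 * n))
    a0 <- 1 + b * W + W^2
    sos <- rbind(sos, c(W^2 / a0, 2 * W^2 / a0, W^2 / a0,
                        1, 2 * (W^2 - 1) / a0, (1 - b * W + W^2) / a0))
  }
  if (n %% 2 == 1) {
    a0 <- 1 + W
    sos <- rbind(sos, c(W / a0, W / a0, 0, 1, (W - 1) / a0, 0))
  }
  sos
}

# single-direction IIR filtering of one biquad, using the vectorized
# moving-average + recursive kernels in stats::filter. Initial conditions
# are the steady state for a constant input x[1], so a constant series
# passes through unchanged (DC gain 1) with no start-up transient.
filter_biquad <- function(x, b, a) {
  n <- length(x)
  xp <- c(x[1], x[1], x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[3:(n + 2)]
  y_ss <- x[1] * sum(b) / (1 + a[2] + a[3])
  as.numeric(stats::filter(v, -a[2:3], method = "recursive",
                           init = c(y_ss, y_ss)))
}

apply_sos <- function(x, sos) {
  for (k in seq_len(nrow(sos)))
    x <- filter_biquad(x, sos[k, 1:3], c(1, sos[k, 5], sos[k, 6]))
  x
}

# analytic magnitude response of the digital SOS cascade at frequency f (Hz)
sos_gain <- function(sos, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  gain <- rep(1 + 0i, length(f))
  for (k in seq_len(nrow(sos))) {
    num <- sos[k, 1] + sos[k, 2] * z + sos[k, 3] * z^2
    den <- 1 + sos[k, 5] * z + sos[k, 6] * z^2
    gain <- gain * num / den
  }
  Mod(gain)
}

#' Cutoff correction for multi-pass Butterworth filtering
#'
#' Cascading an order-`n` Butterworth filter in `p` passes lowers the
#' overall -3 dB point; to keep the cascade's effective cutoff at the
#' desired value, each pass must be designed at
#' `fc / (2^(1/p) - 1)^(1/(2 n))`. For a second-order filter applied in
#' two passes (the zero-phase configuration), a desired 7 Hz cutoff maps
#' to 8.73 Hz per pass.
#'
#' @param desired_fc Desired effective cutoff (Hz), > 0.
#' @param order Filter order per pass, >= 1.
#' @param passes Number of passes, >= 1.
#' @return Per-pass design cutoff (Hz).
#' @examples
#' adjusted_cutoff(7, order = 2, passes = 2)  # 8.73 Hz
#' @export
adjusted_cutoff <- function(desired_fc, order = 2, passes = 2) {
  if (desired_fc <= 0) stop("desired_fc must be > 0")
  if (order < 1 || passes < 1) stop("order and passes must be >= 1")
  desired_fc / (2^(1 / passes) - 1)^(1 / (2 * order))
}

#' Zero-phase dual-pass Butterworth low-pass filter
#'
#' Applies the filter forward then backward (two passes), which cancels the
#' phase shift; the per-pass cutoff is raised with [adjusted_cutoff()] so
#' the cascade's effective -3 dB point sits at `desired_fc`. Edge
#' transients are suppressed by odd-reflection padding.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz); must exceed twice the adjusted cutoff.
#' @param desired_fc Desired effective cutoff (Hz).
#' @param order Filter order (default 2).
#' @return Filtered series, same length as `x`, zero net phase shift.
#' @export
lowpass_dual_pass <- function(x, fs, desired_fc, order = 2) {
  fc <- adjusted_cutoff(desired_fc, order = order, passes = 2)
  if (fs <= 2 * fc)
    stop(sprintf("sampling rate %g Hz too low for adjusted cutoff %.3g Hz", fs, fc))
  n <- length(x)
  sos <- butter_lowpass_sos(order, fc, fs)
  pad <- min(n - 1, max(12, ceiling(3 * fs / fc)))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- apply_sos(xp, sos)
  y <- rev(apply_sos(rev(y), sos))
  y[(pad + 1):(pad + n)]
}
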