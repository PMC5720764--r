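test_that("force resolution rotates sensor axes and preserves magnitude", {
  expect_equal(resolve_forces(1.2, -0.7, 0), list(Fx = 1.2, Fy = -0.7))
  r <- resolve_forces(0, 1, pi / 2)
  expect_equal(r$Fx, 1); expect_equal(r$Fy, 0, tolerance = 1e-15)
  r30 <- resolve_forces(1, 0, pi / 6)
  expect_equal(r30$Fx, 0.86603, tolerance = 1e-5)
  expect_equal(r30$Fy, -0.5, tolerance = 1e-12)
  set.seed(11)
  for (k in 1:20) {
    f <- rnorm(2); th <- runif(1, -pi, pi)
    rr <- resolve_forces(f[1], f[2], th)
    expect_equal(sqrt(rr$Fx^2 + rr$Fy^2), sqrt(sum(f^2)))
  }
})

test_that("multi-pass cutoff correction reproduces the printed adjustment", {
  expect_equal(adjusted_cutoff(5, 2, 1), 5)
  expect_equal(round(adjusted_cutoff(7, 2, 2), 2), 8.73)
  expect_equal(round(adjusted_cutoff(10, 2, 2), 2), 12.47)
})

test_that("dual-pass Butterworth is zero-phase with correct pass/stop bands", {
  fs <- 1000
  t <- seq(0, 3, 1 / fs)
  expect_equal(lowpass_dual_pass(rep(3.3, 500), fs, 7), rep(3.3, 500),
               tolerance = 1e-9)
  s1 <- sin(2 * pi * 1 * t)
  f1 <- lowpass_dual_pass(s1, fs, 7)
  expect_length(f1, length(s1))
  expect_equal(max(abs(f1)), 1, tolerance = 0.01)
  expect_equal(phase_lag(s1, f1, 1, fs), 0)
  s50 <- sin(2 * pi * 50 * t)
  f50 <- lowpass_dual_pass(s50, fs, 7)
  expect_lt(max(abs(f50[500:2500])), 0.1)
  # analytic transfer function of the designed cascade: two passes at the
  # adjusted cutoff give |H| = 1/sqrt(2) at the desired cutoff
  sos <- pivload:::butter_lowpass_sos(2, adjusted_cutoff(7, 2, 2), fs)
  expect_equal(pivload:::sos_gain(sos, 7, fs)^2, sqrt(0.5), tolerance = 1e-3)
  expect_lt(pivload:::sos_gain(sos, 50, fs)^2, 0.01)
  expect_error(lowpass_dual_pass(s1, 10, 7), "cutoff|sampling")
})

test_that("rod subtraction isolates the foil loads", {
  mk <- function(Fx, t = seq_along(Fx) - 1) load_series_frame(
    data.frame(t = t, Fx = Fx, Fy = 0, Tz = 0), "measured")
  asm <- mk(c(1, 2))
  expect_equal(subtract_rod(asm, mk(c(0, 0)))$Fx, c(1, 2))
  z <- subtract_rod(asm, asm)
  expect_true(all(z$Fx == 0))
  expect_identical(attr(z, "provenance"), "foil-only")
  expect_equal(subtract_rod(asm, mk(c(0.5, 0.5)))$Fx, c(0.5, 1.5))
  expect_error(subtract_rod(asm, mk(c(1, 1), t = c(10, 11))), "overlap")
})

test_that("phase averaging folds replicate cycles", {
  cyc <- sin(2 * pi * (0:99) / 100)
  pa <- phase_average(rep(cyc, 3), period = 1, n_cycles = 3, fs = 100)
  expect_equal(pa$mean, cyc)
  expect_true(all(pa$sd == 0))
  pa2 <- phase_average(c(1, 1, 3, 3), period = 2, n_cycles = 2, fs = 1)
  expect_equal(pa2$mean, c(2, 2))
  expect_equal(pa2$sd, c(sqrt(2), sqrt(2)))
  expect_error(phase_average(cyc, 1, 3, 100), "cycles")
})

test_that("correlation with Fisher confidence interval", {
  x <- sin(2 * pi * (0:199) / 50)
  expect_equal(correlation_with_ci(x, x)$r, 1)
  y <- cos(2 * pi * (0:199) / 50)
  expect_lt(abs(correlation_with_ci(x, y)$r), 1e-12)
  # construct two series with r = 0.9 at n = 200 exactly, check the CI
  # against the closed-form Fisher transform
  ci <- tanh(atanh(0.9) + c(-1, 1) * 1.96 / sqrt(200 - 3))
  expect_equal(ci, c(0.869877, 0.923435), tolerance = 1e-6)
  set.seed(3)
  a <- rnorm(200); a <- a - mean(a)
  b <- rnorm(200); b <- b - mean(b)
  b <- b - sum(b * a) / sum(a^2) * a          # orthogonalize
  m <- a / sd(a); cc <- 0.9 * m + sqrt(1 - 0.81) * b / sd(b)
  r <- correlation_with_ci(m, cc)
  expect_equal(r$r, 0.9, tolerance = 1e-12)
  expect_equal(r$ci95, ci, tolerance = 1e-12)
  expect_error(correlation_with_ci(rep(1, 10), rnorm(10)), "constant")
  # affine invariance
  expect_equal(correlation_with_ci(2 * m + 5, cc)$r, r$r)
})

test_that("RMSE% normalizes by the reference range", {
  expect_equal(rmse_percent(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse_percent(c(2, 2, 2), c(1, 2, 3)), 100 * sqrt(2 / 3) / 2)
  expect_equal(rmse_percent(c(2, 2, 2), c(1, 2, 3)), 40.82, tolerance = 1e-2)
  expect_equal(rmse_percent(c(2, 3, 4), c(1, 2, 3)), 50)
  # common positive rescaling leaves RMSE% unchanged
  expect_equal(rmse_percent(3 * c(2, 2, 2), 3 * c(1, 2, 3)),
               rmse_percent(c(2, 2, 2), c(1, 2, 3)))
  expect_error(rmse_percent(c(1, 2), c(5, 5)), "constant")
})

test_that("phase lag recovers constructed shifts with the stated sign", {
  fs <- 100; period <- 1
  t <- seq(0, 4 - 1 / fs, 1 / fs)
  M <- sin(2 * pi * t / period) + 0.3 * sin(4 * pi * t / period)
  expect_equal(phase_lag(M, M, period, fs), 0)
  # circular shifts: the signal is periodic, so rotating is a pure delay
  delay <- function(x, k) x[((seq_along(x) - 1 - k) %% length(x)) + 1]
  expect_equal(phase_lag(M, delay(M, 25), period, fs), 25)   # +25 % = C lags
  expect_equal(phase_lag(M, delay(M, -10), period, fs), -10)
  # tau recovery within one sample up to half a period
  set.seed(9)
  for (k in sample(1:49, 5)) {
    expect_equal(phase_lag(M, delay(M, k), period, fs) * fs * period / 100,
                 k, tolerance = 1)
  }
  expect_error(phase_lag(rep(1, 400), M, period, fs), "flat")
})

test_that("out-of-plane fraction is the |Vz| share of total speed", {
  expect_equal(vz_star(0.2, -0.1, 0), 0)
  expect_equal(vz_star(0, 0, -0.4), 1)
  expect_equal(vz_star(4, 0, 3), 0.6)
  set.seed(5)
  v <- matrix(rnorm(300), ncol = 3)
  out <- vz_star(v[, 1], v[, 2], v[, 3])
  expect_true(all(out >= 0 & out <= 1))
  expect_error(vz_star(0, 0, 0), "zero")
})

test_that("compare_traces bundles the three metrics", {
  fs <- 100
  t <- seq(0, 2 - 1 / fs, 1 / fs)
  M <- sin(2 * pi * t) + 0.1
  C <- 0.95 * sin(2 * pi * t)
  rep <- compare_traces(M, C, 1, fs)
  expect_s3_class(rep, "comparison_report")
  expect_equal(rep$r, 1, tolerance = 1e-9)
  expect_true(rep$ci95[1] <= rep$r && rep$r <= rep$ci95[2])
  expect_equal(rep$lag_pct, 0)
  expect_equal(rep$rmse_pct, 100 * sqrt(mean((M - C)^2)) / (max(C) - min(C)))
  expect_output(print(rep), "RMSE")
})
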