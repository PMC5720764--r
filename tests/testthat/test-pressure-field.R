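fl0 <- fluid_properties(1000, 0)

test_that("pressure gradient: steady uniform flow gives zero, errors on bad input", {
  g <- grid_spec(0, 0, 0.01, 0.01, 16, 16)
  f <- make_uniform_flow(g, c(0.3, 0.1))$velocity
  gr <- pressure_gradient(f, f, f, fl0, 0.01)
  expect_lt(max(abs(gr$dpdx)), 1e-12)
  expect_lt(max(abs(gr$dpdy)), 1e-12)
  expect_error(pressure_gradient(NULL, f, NULL, fl0, 0.01), "neighbour")
  expect_error(pressure_gradient(f, f, f, fl0, 0), "dt")
  g2 <- grid_spec(0, 0, 0.02, 0.02, 16, 16)
  f2 <- make_uniform_flow(g2, c(0.3, 0.1))$velocity
  expect_error(pressure_gradient(f2, f, f, fl0, 0.01), "grid")
})

test_that("pressure gradient matches closed forms (solid body, Taylor-Green)", {
  g <- grid_spec(-0.5, -0.5, 1 / 63, 1 / 63, 64, 64)
  sb <- make_solid_body_rotation(g, 2, fl0)$velocity
  gr <- pressure_gradient(sb, sb, sb, fl0, 0.01)
  nd <- grid_nodes(g)
  # e.g. node nearest (0.1, 0): grad p = rho omega^2 (x, y) ~ (400, 0) Pa/m
  k <- which.min((nd$x - 0.1)^2 + nd$y^2)
  expect_equal(gr$dpdx[k], 1000 * 4 * nd$x[k], tolerance = 1e-10)
  expect_equal(gr$dpdy[k], 1000 * 4 * nd$y[k], tolerance = 1e-8)

  gt <- tg_grid(128)
  flv <- fluid_properties(1000, 1e-3)
  t0 <- 0.05; dt <- 0.01
  gr2 <- pressure_gradient(make_taylor_green(gt, t0 - dt, flv)$velocity,
                           make_taylor_green(gt, t0, flv)$velocity,
                           make_taylor_green(gt, t0 + dt, flv)$velocity,
                           flv, dt)
  nd2 <- grid_nodes(gt)
  Ft2 <- exp(-2 * flv$nu * t0)^2
  tru_x <- 1000 * Ft2 / 2 * sin(2 * nd2$x)
  tru_y <- 1000 * Ft2 / 2 * sin(2 * nd2$y)
  rel <- sqrt(mean((gr2$dpdx - tru_x)^2 + (gr2$dpdy - tru_y)^2, na.rm = TRUE)) /
    sqrt(mean(tru_x^2 + tru_y^2))
  expect_lt(rel, 0.02)
})

test_that("median-polled integration recovers closed-form pressure", {
  g <- grid_spec(-0.5, -0.5, 1 / 63, 1 / 63, 64, 64)
  # zero gradient -> zero pressure everywhere
  f <- make_uniform_flow(g, c(0.3, 0))$velocity
  gr0 <- pressure_gradient(f, f, f, fl0, 0.01)
  p0 <- integrate_pressure(gr0)
  expect_lt(max(abs(p0$p)), 1e-12)
  # zero gradient with a central circular mask: zero outside, undefined inside
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  mk <- body_mask(cbind(0.15 * cos(th), 0.15 * sin(th)))
  pm <- integrate_pressure(gr0, mask = mk)
  expect_true(any(!pm$defined))
  expect_lt(max(abs(pm$p), na.rm = TRUE), 1e-12)
  nd <- grid_nodes(g)
  expect_true(all(!pm$defined[nd$x^2 + nd$y^2 < 0.14^2]))
  # solid-body rotation oracle, nrmse < 2 %
  sb <- make_solid_body_rotation(g, 2, fl0)
  gr <- pressure_gradient(sb$velocity, sb$velocity, sb$velocity, fl0, 0.01)
  pf <- integrate_pressure(gr)
  expect_lt(pressure_nrmse(pf, sb$pressure$p), 0.02)
  # and with 4 direction families
  expect_lt(pressure_nrmse(integrate_pressure(gr, n_directions = 4),
                           sb$pressure$p), 0.02)
})

test_that("gauge invariance: constant seed offsets cancel after gauge fixing", {
  g <- grid_spec(-0.5, -0.5, 1 / 31, 1 / 31, 32, 32)
  sb <- make_solid_body_rotation(g, 2, fl0)
  gr <- pressure_gradient(sb$velocity, sb$velocity, sb$velocity, fl0, 0.01)
  est <- pivload:::ray_family_estimates(gr, 8)
  p1 <- apply(est, c(1, 2), median)
  p2 <- apply(est + 37.5, c(1, 2), median)
  # before gauge fixing: shifted by exactly the seed constant
  expect_equal(p2, p1 + 37.5, tolerance = 1e-12)
  # after ring-median gauge fixing both give the same field
  fix <- function(p) {
    ring <- c(p[c(1, nrow(p)), ], p[, c(1, ncol(p))])
    p - median(ring, na.rm = TRUE)
  }
  expect_equal(fix(p2), fix(p1), tolerance = 1e-12)
})

test_that("median polling is robust to one corrupted direction family", {
  g <- grid_spec(-0.5, -0.5, 1 / 63, 1 / 63, 64, 64)
  sb <- make_solid_body_rotation(g, 2, fl0)
  gr <- pressure_gradient(sb$velocity, sb$velocity, sb$velocity, fl0, 0.01)
  est <- pivload:::ray_family_estimates(gr, 8)
  set.seed(42)
  scale <- max(sb$pressure$p)
  est[, , 3] <- est[, , 3] + matrix(rnorm(64 * 64, 0, 5 * scale), 64)
  p <- apply(est, c(1, 2), median)
  e <- p - sb$pressure$p
  e <- e - mean(e)
  expect_lt(sqrt(mean(e^2)) / (max(sb$pressure$p) - min(sb$pressure$p)), 0.05)
})

test_that("masked nodes are opaque to integration paths", {
  g <- grid_spec(-0.5, -0.5, 1 / 63, 1 / 63, 64, 64)
  f <- make_uniform_flow(g, c(0.3, 0))$velocity
  gr <- pressure_gradient(f, f, f, fl0, 0.01)
  # plant a violent gradient discontinuity inside the mask region
  nd <- grid_nodes(g)
  inside <- nd$x^2 + nd$y^2 < 0.12^2
  gr$dpdx[inside] <- 1e6
  gr$dpdy[inside] <- -1e6
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  pm <- integrate_pressure(gr, mask = body_mask(cbind(0.15 * cos(th),
                                                      0.15 * sin(th))))
  expect_lt(max(abs(pm$p), na.rm = TRUE), 1e-9)
  expect_error(integrate_pressure(
    structure(list(grid = g, dpdx = gr$dpdx, dpdy = gr$dpdy,
                   valid = matrix(FALSE, 64, 64), t = 0),
              class = "pressure_gradient_frame")), "empty")
})

test_that("pressure error shrinks monotonically under grid refinement", {
  flv <- fluid_properties(1000, 0)
  errs <- vapply(c(32, 63, 125), function(n) {
    tg <- make_taylor_green(tg_grid(n), 0, flv)
    gr <- pressure_gradient(tg$velocity, tg$velocity, tg$velocity, flv, 0.01)
    pressure_nrmse(integrate_pressure(gr), tg$pressure$p)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("pressure_sequence subsamples and recovers the Taylor-Green field", {
  flv <- fluid_properties(1000, 1e-3)
  g <- tg_grid(64)
  frames <- lapply(seq(0, by = 0.002, length.out = 100),
                   function(t) make_taylor_green(g, t, flv)$velocity)
  sq <- velocity_sequence(frames, 0.002)
  pf <- pressure_sequence(sq, fluid = flv, dt_calc = 0.01)
  expect_length(pf, 20)
  expect_equal(pf[[2]]$t, 0.01)
  for (k in c(1, 10, 20)) {
    truth <- make_taylor_green(g, pf[[k]]$t, flv)$pressure$p
    expect_lt(pressure_nrmse(pf[[k]], truth), 0.05)
  }
  expect_error(pressure_sequence(sq, fluid = flv, dt_calc = 0.005),
               "integer multiple")
  # identical uniform frames -> all-zero pressure
  gu <- grid_spec(0, 0, 0.01, 0.01, 16, 16)
  fu <- lapply(0:4 * 0.01, function(t) {
    fr <- make_uniform_flow(gu, c(0.2, 0))$velocity; fr$t <- t; fr })
  pu <- pressure_sequence(velocity_sequence(fu, 0.01), fluid = fl0, dt_calc = 0.01)
  expect_true(all(vapply(pu, function(p) max(abs(p$p)) < 1e-12, logical(1))))
})
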