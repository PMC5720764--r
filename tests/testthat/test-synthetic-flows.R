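test_that("uniform flow is constant, divergence-free and pressure-free", {
  g <- grid_spec(0, 0, 0.01, 0.01, 32, 32)
  for (U in list(c(0.3, 0), c(0, 0), c(-0.1, 0.25))) {
    uf <- make_uniform_flow(g, U)
    expect_true(all(uf$velocity$u == U[1]))
    expect_true(all(uf$velocity$v == U[2]))
    expect_true(all(uf$pressure$p == 0))
    expect_lt(max(abs(divergence(uf$velocity))), 1e-14)
  }
  expect_error(make_uniform_flow(g, c(NaN, 0)), "finite")
})

test_that("solid-body rotation matches the closed form", {
  g <- grid_spec(-0.5, -0.5, 1 / 63, 1 / 63, 64, 64)
  fl <- fluid_properties(1000, 0)
  sb <- make_solid_body_rotation(g, 2, fl)
  # node closest to (0.1, 0): |u| = omega r, p - p(center) = rho omega^2 r^2 / 2
  nd <- grid_nodes(g)
  k <- which.min((nd$x - 0.1)^2 + nd$y^2)
  r2 <- nd$x[k]^2 + nd$y[k]^2
  expect_equal(sqrt(sb$velocity$u[k]^2 + sb$velocity$v[k]^2), 2 * sqrt(r2))
  k0 <- which.min(nd$x^2 + nd$y^2)
  expect_equal(sb$pressure$p[k] - sb$pressure$p[k0],
               0.5 * 1000 * 4 * (r2 - nd$x[k0]^2 - nd$y[k0]^2))
  expect_equal(min(sb$pressure$p), 0)
  expect_lt(max(abs(divergence(sb$velocity))), 1e-12)
  # steady momentum balance: rho (u . grad) u = -grad p at interior nodes
  gr <- pressure_gradient(sb$velocity, sb$velocity, sb$velocity, fl, 0.01)
  expect_lt(max(abs(gr$dpdx - 1000 * 4 * nd$x)), 1e-9)
  expect_lt(max(abs(gr$dpdy - 1000 * 4 * nd$y)), 1e-9)
  # omega = 0: quiescent, uniform pressure
  q <- make_solid_body_rotation(g, 0, fl)
  expect_true(all(q$velocity$u == 0) && all(q$pressure$p == 0))
})

test_that("Taylor-Green fields satisfy the discrete momentum equations", {
  g <- tg_grid(128)
  fl <- fluid_properties(1000, 1e-3)
  tg <- make_taylor_green(g, 0, fl)
  div <- divergence(tg$velocity)
  # discrete divergence cancels exactly in the interior (matched sinc
  # factors); the domain edge uses one-sided stencils with O(h) error
  interior <- matrix(FALSE, g$nx, g$ny); interior[2:(g$nx - 1), 2:(g$ny - 1)] <- TRUE
  expect_lt(max(abs(div[interior])), 1e-3)

  # brute-force substitution oracle: evaluate every term of the x-momentum
  # equation rho (du/dt + u du/dx + v du/dy) = -dp/dx + mu lap(u) by
  # numerical differentiation of the closed-form fields themselves
  # (independent of the solver's finite-difference stencils)
  uf <- function(x, y, t) cos(x) * sin(y) * exp(-2 * fl$nu * t)
  vf <- function(x, y, t) -sin(x) * cos(y) * exp(-2 * fl$nu * t)
  pf <- function(x, y, t) -(fl$rho / 4) * (cos(2 * x) + cos(2 * y)) *
    exp(-2 * fl$nu * t)^2
  set.seed(31)
  x <- runif(500, 0.5, 2 * pi - 0.5); y <- runif(500, 0.5, 2 * pi - 0.5)
  eps <- 1e-5
  nd1 <- function(f, x, y, t, arg) switch(arg,
    x = (f(x + eps, y, t) - f(x - eps, y, t)) / (2 * eps),
    y = (f(x, y + eps, t) - f(x, y - eps, t)) / (2 * eps),
    t = (f(x, y, t + eps) - f(x, y, t - eps)) / (2 * eps))
  lap_u <- (uf(x + eps, y, 0) - 2 * uf(x, y, 0) + uf(x - eps, y, 0)) / eps^2 +
           (uf(x, y + eps, 0) - 2 * uf(x, y, 0) + uf(x, y - eps, 0)) / eps^2
  res <- fl$rho * (nd1(uf, x, y, 0, "t") +
                   uf(x, y, 0) * nd1(uf, x, y, 0, "x") +
                   vf(x, y, 0) * nd1(uf, x, y, 0, "y")) +
    nd1(pf, x, y, 0, "x") - fl$rho * fl$nu * lap_u
  conv_scale <- sqrt(mean((fl$rho * uf(x, y, 0) * nd1(uf, x, y, 0, "x"))^2))
  expect_lt(sqrt(mean(res^2)) / conv_scale, 1e-6)

  # inviscid limit: kinetic energy constant in t
  fl0 <- fluid_properties(1000, 0)
  ke <- function(t) { f <- make_taylor_green(g, t, fl0)$velocity
                      sum(f$u^2 + f$v^2) }
  expect_equal(ke(0.5), ke(0))
  expect_error(make_taylor_green(grid_spec(0, 0, 0.01, 0.01, 32, 32)), "2\\*pi")
})

test_that("flapping-midline kinematics follow the two motion programs", {
  kin_h <- kinematics_program("heave", h = 0.015, f = 1.5, U = 0.3, c = 0.18)
  m0 <- make_flapping_midline(kin_h, 0)
  expect_equal(m0$points[1, 2], 0, ignore_attr = TRUE)
  expect_equal(attr(m0, "theta"), 0)
  expect_equal(max(abs(m0$points[, 2])), 0)   # rigid straight chord
  expect_equal(m0$points[nrow(m0$points), 1] - m0$points[1, 1], 0.18,
               ignore_attr = TRUE)

  kin_a <- kinematics_program("zero_aoa", h = 0.015, f = 1.5, U = 0.3, c = 0.18)
  # heave extreme: zero heave velocity, zero pitch
  expect_equal(pitch_angle(kin_a, 1 / (4 * 1.5)), 0, tolerance = 1e-12)
  # t = 0: theta = -atan(2 pi f h / U)
  expect_equal(pitch_angle(kin_a, 0), -atan(2 * pi * 1.5 * 0.015 / 0.3),
               tolerance = 1e-12)
  expect_equal(pitch_angle(kin_a, 0), -0.4404, tolerance = 1e-4)
  # periodicity of heave; pitch extremes at heave zero-crossings
  ts <- seq(0, 2, by = 0.001)
  y <- heave_position(kin_a, ts)
  expect_equal(y, heave_position(kin_a, ts + 1 / 1.5), tolerance = 1e-10)
  th <- pitch_angle(kin_a, ts)
  expect_equal(ts[which.max(abs(th))] %% (1 / (2 * 1.5)), 0, tolerance = 2e-3)
})

test_that("plate scene provides analytic loads from the divergence-theorem oracle", {
  kin <- kinematics_program("zero_aoa", h = 0.015, f = 1.5, U = 0.3, c = 0.18)
  hw <- 1.64 * delta99(0.18, 54000)
  margin <- 3 * hw + 0.015 + 0.06
  g <- grid_spec(-margin, -(margin + 0.09), (0.18 + 2 * margin) / 47,
                 (0.18 + 2 * margin) / 47, 48, 48)
  # frame-count arithmetic: 3 cycles at 1.5 Hz, dt 0.01 -> 200 frames
  sc <- make_plate_scene(kin, g, pressure_law = "linear_x", n_cycles = 3, dt = 0.01)
  expect_length(sc$midlines, 200)
  expect_length(sc$pressures, 200)
  # uniform law: identically zero loads
  scu <- suppressWarnings(make_plate_scene(kin, g, pressure_law = "uniform",
                                           slope = 55, n_frames = 30, dt = 0.01))
  expect_true(all(scu$loads$Fx == 0 & scu$loads$Fy == 0 & scu$loads$Tz == 0))
  # linear-in-x: Fx = -a * A * s at every frame
  A <- abs(pivload:::polygon_area_centroid(
    offset_boundary(sc$midlines[[1]], sc$geometry$halfwidth)$points)$area)
  expect_equal(sc$loads$Fx[1], -10 * A * sc$geometry$span, tolerance = 1e-10)
  expect_lt(diff(range(sc$loads$Fx)) / abs(mean(sc$loads$Fx)), 1e-6)
  # less than one cycle -> warning; noise without seed -> error
  expect_warning(make_plate_scene(kin, g, n_frames = 5, dt = 0.01), "cycle")
  expect_error(make_plate_scene(kin, g, n_frames = 30, dt = 0.01,
                                noise_sd = 0.01), "seed")
})
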