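#' Analytic flow generators
#'
#' Closed-form velocity/pressure pairs used as ground truth for the pressure
#' solver and the load integrator. Each generator returns both the velocity
#' frame and the matching gauge-pressure frame so downstream stages can be
#' validated without external data.
#'
#' @name synthetic_flows
NULL

#' Uniform flow
#'
#' Steady uniform flow has zero pressure gradient, so the matching gauge
#' pressure is identically zero. The trivial limit of the solver.
#'
#' @param grid A `grid_spec`.
#' @param U Length-2 numeric velocity vector (m/s).
#' @param fluid A `fluid_properties`.
#' @param t Frame time (s).
#' @return List with `velocity` (`velocity_frame`) and `pressure`
#'   (`pressure_frame`).
#' @export
make_uniform_flow <- function(grid, U, fluid = fluid_properties(), t = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(U) != 2 || any(!is.finite(U)))
    stop("U must be a finite length-2 velocity vector")
  u <- matrix(U[1], grid$nx, grid$ny)
  v <- matrix(U[2], grid$nx, grid$ny)
  list(velocity = velocity_frame(grid, u, v, t = t),
       pressure = pressure_frame(grid, matrix(0, grid$nx, grid$ny), t = t))
}

#' Solid-body rotation
#'
#' `u = (-omega y, omega x)` about `center`, with the closed-form radial
#' pressure `p = rho omega^2 r^2 / 2` (centripetal balance). The gauge is
#' chosen so `min(p) = 0`. This is the steady oracle for the path-integration
#' solver: all spatial derivatives of the field are linear, so central
#' differences and trapezoidal path integration are exact up to rounding.
#'
#' @param grid A `grid_spec`.
#' @param omega Angular rate (1/s).
#' @param fluid A `fluid_properties`.
#' @param center Rotation axis, default `c(0, 0)`.
#' @param t Frame time (s).
#' @return List with `velocity` and `pressure` frames.
#' @export
make_solid_body_rotation <- function(grid, omega, fluid = fluid_properties(),
                                     center = c(0, 0), t = 0) {
  stopifnot(inherits(grid, "grid_spec"), is.finite(omega), length(center) == 2)
  nd <- grid_nodes(grid)
  xr <- nd$x - center[1]; yr <- nd$y - center[2]
  u <- -omega * yr
  v <- omega * xr
  p <- 0.5 * fluid$rho * omega^2 * (xr^2 + yr^2)
  p <- p - min(p)
  list(velocity = velocity_frame(grid, u, v, t = t),
       pressure = pressure_frame(grid, p, t = t))
}

#' Taylor-Green vortex
#'
#' Decaying viscous vortex array on the periodic box `[0, 2*pi]^2`:
#' `u =  cos(x) sin(y) exp(-2 nu t)`,
#' `v = -sin(x) cos(y) exp(-2 nu t)`,
#' `p = -(rho / 4) (cos 2x + cos 2y) exp(-4 nu t)`.
#' The pressure satisfies the incompressible momentum equations exactly
#' (verified numerically in the test suite); it exercises all three gradient
#' terms (unsteady, convective, viscous) at once. Gauge: zero spatial mean
#' of the analytic expression.
#'
#' @param grid A `grid_spec` spanning exactly `[0, 2*pi]` in each direction
#'   (inclusive endpoints); anything else is rejected.
#' @param t Time (s), >= 0.
#' @param fluid A `fluid_properties`; `nu` sets the decay rate.
#' @return List with `velocity` and `pressure` frames.
#' @export
make_taylor_green <- function(grid, t = 0, fluid = fluid_properties()) {
  stopifnot(inherits(grid, "grid_spec"))
  if (t < 0) stop("t must be >= 0")
  span_x <- (grid$nx - 1) * grid$dx
  span_y <- (grid$ny - 1) * grid$dy
  if (abs(grid$x0) > 1e-9 || abs(grid$y0) > 1e-9 ||
      abs(span_x - 2 * pi) > 1e-6 || abs(span_y - 2 * pi) > 1e-6)
    stop("Taylor-Green grid must span exactly [0, 2*pi]^2 from the origin")
  nd <- grid_nodes(grid)
  Ft <- exp(-2 * fluid$nu * t)
  u <- cos(nd$x) * sin(nd$y) * Ft
  v <- -sin(nd$x) * cos(nd$y) * Ft
  p <- -(fluid$rho / 4) * (cos(2 * nd$x) + cos(2 * nd$y)) * Ft^2
  list(velocity = velocity_frame(grid, u, v, t = t),
       pressure = pressure_frame(grid, p, t = t))
}
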