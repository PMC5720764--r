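#' Flapping-plate kinematics program
#'
#' Describes the motion of a rigid plate's leading edge. Two programs are
#' supported: pure sinusoidal heave (no pitch), and a 0-degree
#' angle-of-attack program in which the pitch angle continuously tracks the
#' instantaneous relative flow, `theta(t) = -atan(dy_LE/dt / U)`. Positive
#' pitch is a counter-clockwise rotation of the leading edge in the (x, y)
#' plane viewed from +z.
#'
#' @param program `"heave"` or `"zero_aoa"`.
#' @param h Heave amplitude (m), >= 0.
#' @param f Flapping frequency (Hz), > 0.
#' @param U Free-stream flow speed (m/s), > 0.
#' @param c Chord length (m), > 0.
#' @return An object of class `kinematics_program`.
#' @export
kinematics_program <- function(program = c("heave", "zero_aoa"),
                               h = 0.015, f = 1.5, U = 0.3, c = 0.18) {
  program <- match.arg(program)
  if (!is.finite(f) || f <= 0) stop("f must be > 0")
  if (!is.finite(U) || U <= 0) stop("U must be > 0")
  if (!is.finite(h) || h < 0) stop("h must be >= 0")
  if (!is.finite(c) || c <= 0) stop("chord must be > 0")
  structure(list(program = program, h = h, f = f, U = U, c = c),
            class = "kinematics_program")
}

#' Pitch angle of a kinematics program
#'
#' @param kin A `kinematics_program`.
#' @param t Time (s), vectorized.
#' @return Pitch angle theta (rad); identically 0 for the heave program,
#'   `-atan(2 pi f h cos(2 pi f t) / U)` for the 0-degree AoA program.
#' @export
pitch_angle <- function(kin, t) {
  stopifnot(inherits(kin, "kinematics_program"))
  if (kin$program == "heave") return(rep(0, length(t)))
  ydot <- 2 * pi * kin$f * kin$h * cos(2 * pi * kin$f * t)
  -atan(ydot / kin$U)
}

#' Leading-edge lateral position
#'
#' @param kin A `kinematics_program`.
#' @param t Time (s), vectorized.
#' @return `h * sin(2 pi f t)` (m).
#' @export
heave_position <- function(kin, t) {
  stopifnot(inherits(kin, "kinematics_program"))
  kin$h * sin(2 * pi * kin$f * t)
}

#' Rigid flapping-plate midline at one instant
#'
#' The midline is the rigid chord anchored at the leading edge
#' `(x_le, y_LE(t))` and rotated by the program's pitch angle about the
#' leading edge. An optional curvature envelope can superimpose a quadratic
#' lateral bend growing toward the trailing edge (amplitude at the trailing
#' edge, in m); the default is rigid.
#'
#' @param kin A `kinematics_program`.
#' @param t Time (s).
#' @param n_points Number of midline points, >= 2.
#' @param x_le Streamwise position of the leading edge (m).
#' @param bend Trailing-edge lateral bend amplitude (m); 0 = rigid.
#' @return A `midline` object; its `theta` attribute carries the pitch angle.
#' @export
make_flapping_midline <- function(kin, t, n_points = 25, x_le = 0, bend = 0) {
  stopifnot(inherits(kin, "kinematics_program"))
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be >= 2")
  theta <- pitch_angle(kin, t)
  s <- seq(0, kin$c, length.out = n_points)
  le <- c(x_le, heave_position(kin, t))
  px <- le[1] + s * cos(theta)
  py <- le[2] + s * sin(theta)
  if (bend != 0) {
    # lateral (chord-normal) quadratic envelope, zero at the leading edge
    off <- bend * (s / kin$c)^2
    px <- px - off * sin(theta)
    py <- py + off * cos(theta)
  }
  m <- midline(cbind(px, py), t = t)
  attr(m, "theta") <- theta
  m
}

# polygon area / centroid by the shoelace formula; loop given as n x 2 matrix,
# not repeated at the end. Area is positive for counter-clockwise loops.
polygon_area_centroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  list(area = A, centroid = c(cx, cy))
}

#' Flapping-plate scene with prescribed pressure and analytic loads
#'
#' Builds an end-to-end recovery fixture: a moving rigid plate, a prescribed
#' analytic pressure field around it, and the loads that pressure must
#' produce on the plate's control surface. The analytic loads are computed
#' by an independent divergence-theorem route,
#' `F = -(integral of grad p over the enclosed area) * span`, using the
#' shoelace area and centroid of the control-surface polygon - not by the
#' loop-sum integrator under test. The control surface is the
#' `surface_factor * delta99` offset of each frame's midline, so the same
#' geometry parameters must be used downstream.
#'
#' @param kin A `kinematics_program`.
#' @param grid A `grid_spec`; must contain the plate plus its control
#'   surface at all times.
#' @param fluid A `fluid_properties`.
#' @param pressure_law One of `"uniform"`, `"linear_x"`, `"linear_y"`,
#'   `"solid_body"`.
#' @param slope Pressure-gradient magnitude `a` (Pa/m) for the linear laws;
#'   `p = a x` or `p = a y`. For `"solid_body"`, the angular rate omega
#'   (1/s) of `p = rho omega^2 r^2 / 2` about the origin. For `"uniform"`,
#'   the constant pressure level (Pa).
#' @param n_frames Number of frames; when `NULL`, derived from `n_cycles`
#'   as `round(n_cycles / (f * dt))`.
#' @param n_cycles Number of motion cycles used when `n_frames` is `NULL`.
#' @param dt Frame spacing (s), > 0.
#' @param Re Reynolds number used for the delta99 offsets.
#' @param surface_factor Control-surface offset in delta99 units.
#' @param span Plate span (m).
#' @param noise_sd Optional Gaussian velocity noise (m/s); requires `seed`.
#' @param seed RNG seed, mandatory when `noise_sd > 0`.
#' @return List with `velocity` (a `velocity_sequence` of uniform flow at
#'   the program's U), `midlines`, `pressures` (list of `pressure_frame`),
#'   `loads` (the analytic `load_series`), and `geometry` (chord, Re,
#'   surface_factor, span, reference rule) needed to rebuild the same
#'   control surfaces downstream.
#' @export
make_plate_scene <- function(kin, grid, fluid = fluid_properties(),
                             pressure_law = c("linear_x", "linear_y",
                                              "uniform", "solid_body"),
                             slope = 10, n_frames = NULL, n_cycles = 3,
                             dt = 0.01, Re = 54000, surface_factor = 1.64,
                             span = 0.05, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(kin, "kinematics_program"), inherits(grid, "grid_spec"))
  pressure_law <- match.arg(pressure_law)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (is.null(n_frames))
    n_frames <- as.integer(round(n_cycles / (kin$f * dt)))
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("need at least 2 frames")
  if (noise_sd > 0 && is.null(seed))
    stop("seed is mandatory when velocity noise is requested")
  if ((n_frames - 1) * dt < 1 / kin$f)
    warning("scene spans less than one motion cycle")

  nd <- grid_nodes(grid)
  p_field <- switch(pressure_law,
    uniform    = matrix(slope, grid$nx, grid$ny),
    linear_x   = slope * nd$x,
    linear_y   = slope * nd$y,
    solid_body = 0.5 * fluid$rho * slope^2 * (nd$x^2 + nd$y^2))

  hw <- surface_factor * delta99(kin$c, Re)
  ts <- (seq_len(n_frames) - 1) * dt
  if (noise_sd > 0) set.seed(seed)

  frames <- vector("list", n_frames)
  midlines <- vector("list", n_frames)
  pressures <- vector("list", n_frames)
  rec <- data.frame(t = ts, Fx = 0, Fy = 0, Tz = 0, theta = 0)
  for (k in seq_len(n_frames)) {
    t <- ts[k]
    u <- matrix(kin$U, grid$nx, grid$ny)
    v <- matrix(0, grid$nx, grid$ny)
    if (noise_sd > 0) {
      u <- u + matrix(stats::rnorm(grid$nx * grid$ny, 0, noise_sd), grid$nx)
      v <- v + matrix(stats::rnorm(grid$nx * grid$ny, 0, noise_sd), grid$nx)
    }
    frames[[k]] <- velocity_frame(grid, u, v, t = t)
    m <- make_flapping_midline(kin, t)
    midlines[[k]] <- m
    pressures[[k]] <- pressure_frame(grid, p_field, t = t)

    surf <- offset_boundary(m, hw)
    geo <- polygon_area_centroid(surf$points)
    A <- abs(geo$area); ctr <- geo$centroid
    r0 <- m$points[1, ]                       # leading edge reference
    ld <- switch(pressure_law,
      uniform = list(F = c(0, 0), Tz = 0),
      linear_x = {
        Fv <- -c(slope, 0) * A * span
        list(F = Fv, Tz = cross2(ctr - r0, Fv))
      },
      linear_y = {
        Fv <- -c(0, slope) * A * span
        list(F = Fv, Tz = cross2(ctr - r0, Fv))
      },
      solid_body = {
        # grad p = rho omega^2 (x, y); area integrals via centroid moments
        g0 <- fluid$rho * slope^2
        Fv <- -g0 * A * ctr * span
        # Tz = -s g0 int (r - r0) x (x, y) dA = -s g0 (y0 Sx - x0 Sy)
        Tz <- -span * g0 * (r0[2] * A * ctr[1] - r0[1] * A * ctr[2])
        list(F = Fv, Tz = Tz)
      })
    rec$Fx[k] <- ld$F[1]; rec$Fy[k] <- ld$F[2]; rec$Tz[k] <- ld$Tz
    rec$theta[k] <- attr(m, "theta")
  }
  list(velocity = velocity_sequence(frames, dt),
       midlines = midlines,
       pressures = pressures,
       loads = load_series_frame(rec, provenance = "measured",
                                 period = 1 / kin$f),
       geometry = list(chord = kin$c, Re = Re,
                       surface_factor = surface_factor, span = span,
                       halfwidth = hw, reference = "leading-edge"))
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]
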