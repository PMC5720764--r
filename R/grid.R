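#' Regular grid specification
#'
#' Defines a rectangular, regular grid of velocity/pressure nodes. Node
#' coordinates are `x_i = x0 + (i-1) dx`, `y_j = y0 + (j-1) dy` (1-based).
#' All field arrays in the package are `nx x ny` matrices indexed `[i, j]`
#' with `i` along x and `j` along y.
#'
#' @param x0,y0 Coordinates of the first node (m).
#' @param dx,dy Node spacing (m), strictly positive.
#' @param nx,ny Node counts along x and y, each at least 8.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 0, 0.01, 0.01, 32, 32)
#' head(grid_x(g))
#' @export
grid_spec <- function(x0, y0, dx, dy, nx, ny) {
  stopifnot(is.numeric(x0), is.numeric(y0), is.finite(x0), is.finite(y0))
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0)
    stop("grid spacings dx, dy must be finite and > 0")
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 8L || ny < 8L)
    stop("grid must have at least 8 nodes per direction (got ", nx, " x ", ny, ")")
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0),
                 dx = as.numeric(dx), dy = as.numeric(dy),
                 nx = nx, ny = ny),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param g A `grid_spec`.
#' @export
grid_x <- function(g) g$x0 + (seq_len(g$nx) - 1) * g$dx

#' @rdname grid_spec
#' @export
grid_y <- function(g) g$y0 + (seq_len(g$ny) - 1) * g$dy

#' Node coordinate matrices
#'
#' @param g A `grid_spec`.
#' @return A list with `nx x ny` matrices `x` and `y`.
#' @export
grid_nodes <- function(g) {
  list(x = matrix(grid_x(g), g$nx, g$ny),
       y = matrix(grid_y(g), g$nx, g$ny, byrow = TRUE))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d nodes, dx=%g m dy=%g m, origin (%g, %g) m\n",
              x$nx, x$ny, x$dx, x$dy, x$x0, x$y0))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = tol))
}

#' Fluid properties
#'
#' @param rho Density (kg/m^3), > 0. Default is fresh water.
#' @param nu Kinematic viscosity (m^2/s), >= 0. Dynamic viscosity
#'   `mu = rho * nu` is derived on demand, never stored.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1000, nu = 1e-6) {
  if (!is.finite(rho) || rho <= 0) stop("rho must be finite and > 0")
  if (!is.finite(nu) || nu < 0) stop("nu must be finite and >= 0")
  structure(list(rho = as.numeric(rho), nu = as.numeric(nu)),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("fluid: rho=%g kg/m^3, nu=%g m^2/s (mu=%g Pa s)\n",
              x$rho, x$nu, x$rho * x$nu))
  invisible(x)
}

#' Planar velocity frame
#'
#' One time slice of a planar velocity field on a regular grid with per-node
#' validity. Invalid nodes carry no velocity information and are never read
#' by downstream differencing.
#'
#' @param grid A `grid_spec`.
#' @param u,v `nx x ny` velocity component matrices (m/s).
#' @param t Frame time (s).
#' @param valid Logical `nx x ny` matrix; defaults to all valid.
#' @return An object of class `velocity_frame`.
#' @export
velocity_frame <- function(grid, u, v, t = 0, valid = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  u <- as.matrix(u); v <- as.matrix(v)
  if (!all(dim(u) == c(grid$nx, grid$ny)) || !all(dim(v) == c(grid$nx, grid$ny)))
    stop("u, v must be nx x ny matrices matching the grid")
  if (is.null(valid)) valid <- matrix(TRUE, grid$nx, grid$ny)
  valid <- matrix(as.logical(valid), grid$nx, grid$ny)
  if (any(!is.finite(u[valid])) || any(!is.finite(v[valid])))
    stop("velocity must be finite at valid nodes")
  structure(list(grid = grid, u = u, v = v, valid = valid, t = as.numeric(t)),
            class = "velocity_frame")
}

#' Time-resolved velocity sequence
#'
#' @param frames List of `velocity_frame`s sharing one grid.
#' @param dt Uniform time step (s), > 0. Frame timestamps must equal
#'   `t0 + k dt`.
#' @return An object of class `velocity_sequence`.
#' @export
velocity_sequence <- function(frames, dt) {
  if (!length(frames)) stop("velocity_sequence needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "velocity_frame")))
    stop("all frames must be velocity_frame objects")
  if (!is.finite(dt) || dt <= 0) stop("dt must be finite and > 0")
  g <- frames[[1]]$grid
  for (f in frames) if (!same_grid(f$grid, g)) stop("all frames must share one grid")
  ts <- vapply(frames, `[[`, numeric(1), "t")
  expect <- ts[1] + (seq_along(ts) - 1) * dt
  if (max(abs(ts - expect)) > 1e-6 * max(dt, 1))
    stop("frame timestamps must be uniform at spacing dt")
  structure(list(frames = frames, dt = as.numeric(dt)),
            class = "velocity_sequence")
}

#' @export
print.velocity_sequence <- function(x, ...) {
  cat(sprintf("velocity_sequence: %d frames, dt=%g s, t in [%g, %g] s\n",
              length(x$frames), x$dt, x$frames[[1]]$t,
              x$frames[[length(x$frames)]]$t))
  invisible(x)
}

#' Gauge pressure frame
#'
#' @param grid A `grid_spec`.
#' @param p `nx x ny` gauge pressure matrix (Pa); `NA` where undefined.
#' @param t Frame time (s).
#' @param defined Logical matrix; defaults to `is.finite(p)`.
#' @return An object of class `pressure_frame`.
#' @export
pressure_frame <- function(grid, p, t = 0, defined = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  p <- as.matrix(p)
  if (!all(dim(p) == c(grid$nx, grid$ny))) stop("p must match the grid")
  if (is.null(defined)) defined <- is.finite(p)
  defined <- matrix(as.logical(defined), grid$nx, grid$ny)
  if (any(!is.finite(p[defined]))) stop("pressure must be finite where defined")
  p[!defined] <- NA_real_
  structure(list(grid = grid, p = p, defined = defined, t = as.numeric(t)),
            class = "pressure_frame")
}

# -- finite differences -------------------------------------------------------

# Central differences in the interior, one-sided at domain edges and next to
# invalid nodes (so values stay defined up to the control surface); a node is
# dropped only when no one-sided stencil is available.
# Returns list(d, ok): derivative matrix and usable-node mask.
fd_deriv <- function(f, valid, h, along = c("x", "y")) {
  along <- match.arg(along)
  if (along == "y") {
    r <- fd_deriv(t(f), t(valid), h, "x")
    return(list(d = t(r$d), ok = t(r$ok)))
  }
  nx <- nrow(f); ny <- ncol(f)
  fm <- rbind(NA_real_, f[-nx, , drop = FALSE])     # f[i-1, j]
  fp <- rbind(f[-1, , drop = FALSE], NA_real_)      # f[i+1, j]
  vm <- rbind(FALSE, valid[-nx, , drop = FALSE])
  vp <- rbind(valid[-1, , drop = FALSE], FALSE)
  d <- matrix(NA_real_, nx, ny)
  both <- valid & vm & vp
  d[both] <- (fp[both] - fm[both]) / (2 * h)
  fwd <- valid & vp & !both
  d[fwd] <- (fp[fwd] - f[fwd]) / h
  bwd <- valid & vm & !both
  d[bwd] <- (f[bwd] - fm[bwd]) / h
  list(d = d, ok = both | fwd | bwd)
}

# Second derivative; central where possible, one-sided second difference with
# two same-side neighbours otherwise, NA when neither stencil fits.
fd_second <- function(f, valid, h, along = c("x", "y")) {
  along <- match.arg(along)
  if (along == "y") {
    r <- fd_second(t(f), t(valid), h, "x")
    return(list(d = t(r$d), ok = t(r$ok)))
  }
  nx <- nrow(f); ny <- ncol(f)
  shift <- function(m, k) {  # m shifted so result[i,] = m[i+k,]
    if (k > 0) rbind(m[-seq_len(k), , drop = FALSE],
                     matrix(NA, k, ncol(m)))
    else if (k < 0) rbind(matrix(NA, -k, ncol(m)),
                          m[seq_len(nx + k), , drop = FALSE])
    else m
  }
  vshift <- function(k) { s <- shift(valid, k); s[is.na(s)] <- FALSE; s }
  d <- matrix(NA_real_, nx, ny)
  fm1 <- shift(f, -1); fp1 <- shift(f, 1)
  ctr <- valid & vshift(-1) & vshift(1)
  d[ctr] <- (fp1[ctr] - 2 * f[ctr] + fm1[ctr]) / h^2
  fp2 <- shift(f, 2)
  fwd <- valid & vshift(1) & vshift(2) & !ctr
  d[fwd] <- (f[fwd] - 2 * fp1[fwd] + fp2[fwd]) / h^2
  fm2 <- shift(f, -2)
  bwd <- valid & vshift(-1) & vshift(-2) & !ctr & !fwd
  d[bwd] <- (f[bwd] - 2 * fm1[bwd] + fm2[bwd]) / h^2
  list(d = d, ok = ctr | fwd | bwd)
}

#' Discrete divergence of a velocity frame
#'
#' Central differences in the interior, one-sided at edges. Used by the
#' generator invariants (analytic fields must be divergence-free to
#' truncation error).
#'
#' @param frame A `velocity_frame`.
#' @return Matrix of `du/dx + dv/dy` (1/s), `NA` where stencils are unusable.
#' @export
divergence <- function(frame) {
  gx <- fd_deriv(frame$u, frame$valid, frame$grid$dx, "x")
  gy <- fd_deriv(frame$v, frame$valid, frame$grid$dy, "y")
  d <- gx$d + gy$d
  d[!(gx$ok & gy$ok)] <- NA_real_
  d
}
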