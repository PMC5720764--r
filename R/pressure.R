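#' Navier-Stokes pressure gradient from velocity frames
#'
#' Evaluates `grad p = -rho (du/dt + (u . grad) u) + rho nu laplacian(u)`
#' per node. Spatial derivatives use central differences in the interior
#' and one-sided differences next to the domain edge or masked/invalid
#' nodes (so the gradient stays defined up to the control surface, which
#' sits close to the mask). The time derivative is central when both
#' temporal neighbours exist and one-sided otherwise. The viscous term is
#' retained by default; neglecting shear in the load integration does not
#' imply neglecting viscosity here.
#'
#' @param prev,nxt Temporal neighbour `velocity_frame`s (either may be
#'   `NULL`, not both).
#' @param cur Current `velocity_frame`.
#' @param fluid A `fluid_properties`.
#' @param dt Time spacing between the supplied frames (s), > 0.
#' @param viscous Include the viscous term (default `TRUE`).
#' @return An object of class `pressure_gradient_frame` with matrices
#'   `dpdx`, `dpdy` (Pa/m) and logical `valid`.
#' @export
pressure_gradient <- function(prev, cur, nxt, fluid, dt, viscous = TRUE) {
  stopifnot(inherits(cur, "velocity_frame"), inherits(fluid, "fluid_properties"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (is.null(prev) && is.null(nxt))
    stop("at least one temporal neighbour is required")
  for (f in list(prev, nxt)) if (!is.null(f)) {
    if (!inherits(f, "velocity_frame")) stop("neighbours must be velocity_frames")
    if (!same_grid(f$grid, cur$grid)) stop("mismatched grids between frames")
  }
  g <- cur$grid
  V <- cur$valid

  dudt <- dvdt <- matrix(0, g$nx, g$ny)
  tvalid <- V
  if (!is.null(prev) && !is.null(nxt)) {
    dudt <- (nxt$u - prev$u) / (2 * dt)
    dvdt <- (nxt$v - prev$v) / (2 * dt)
    tvalid <- V & prev$valid & nxt$valid
  } else if (is.null(prev)) {
    dudt <- (nxt$u - cur$u) / dt
    dvdt <- (nxt$v - cur$v) / dt
    tvalid <- V & nxt$valid
  } else {
    dudt <- (cur$u - prev$u) / dt
    dvdt <- (cur$v - prev$v) / dt
    tvalid <- V & prev$valid
  }

  dudx <- fd_deriv(cur$u, V, g$dx, "x"); dudy <- fd_deriv(cur$u, V, g$dy, "y")
  dvdx <- fd_deriv(cur$v, V, g$dx, "x"); dvdy <- fd_deriv(cur$v, V, g$dy, "y")
  conv_u <- cur$u * dudx$d + cur$v * dudy$d
  conv_v <- cur$u * dvdx$d + cur$v * dvdy$d
  ok <- tvalid & dudx$ok & dudy$ok & dvdx$ok & dvdy$ok

  visc_u <- visc_v <- 0
  if (viscous && fluid$nu > 0) {
    lux <- fd_second(cur$u, V, g$dx, "x"); luy <- fd_second(cur$u, V, g$dy, "y")
    lvx <- fd_second(cur$v, V, g$dx, "x"); lvy <- fd_second(cur$v, V, g$dy, "y")
    # where a second-difference stencil cannot be formed the (small) viscous
    # contribution is dropped rather than invalidating the node
    z <- function(r) { d <- r$d; d[!r$ok] <- 0; d }
    visc_u <- fluid$nu * (z(lux) + z(luy))
    visc_v <- fluid$nu * (z(lvx) + z(lvy))
  }

  dpdx <- fluid$rho * (-(dudt + conv_u) + visc_u)
  dpdy <- fluid$rho * (-(dvdt + conv_v) + visc_v)
  dpdx[!ok] <- NA_real_
  dpdy[!ok] <- NA_real_
  structure(list(grid = g, dpdx = dpdx, dpdy = dpdy, valid = ok, t = cur$t),
            class = "pressure_gradient_frame")
}

# Pressure along the outer ring of the domain by trapezoidal integration of
# the tangential gradient, both orientations averaged and the closure drift
# distributed linearly. Gives every ray family a common gauge seed.
# Returns a list with west/east/south/north edge vectors (NA where unknown).
edge_ring_pressure <- function(grad) {
  g <- grad$grid
  nx <- g$nx; ny <- g$ny
  # ring nodes counter-clockwise from (1,1): south, east, north(rev), west(rev)
  ij <- rbind(cbind(seq_len(nx), 1L),
              cbind(nx, seq(2L, ny)),
              cbind(seq(nx - 1L, 1L), ny),
              cbind(1L, seq(ny - 1L, 2L)))
  n <- nrow(ij)
  px <- grad$dpdx[ij]; py <- grad$dpdy[ij]
  vv <- grad$valid[ij]
  nxt <- c(2:n, 1L)
  dxy <- cbind((ij[nxt, 1] - ij[, 1]) * g$dx, (ij[nxt, 2] - ij[, 2]) * g$dy)
  inc <- 0.5 * ((px + px[nxt]) * dxy[, 1] + (py + py[nxt]) * dxy[, 2])
  inc[!(vv & vv[nxt])] <- NA_real_
  p <- rep(NA_real_, n)
  if (all(is.finite(inc))) {
    cumf <- c(0, cumsum(inc))
    drift <- cumf[n + 1]
    p <- cumf[seq_len(n)] - drift * (seq_len(n) - 1) / n
  } else {
    # broken ring (mask touches the edge): integrate outwards from the first
    # valid run without closure correction
    p[1] <- 0
    for (k in seq_len(n - 1)) if (is.finite(p[k]) && is.finite(inc[k]))
      p[k + 1] <- p[k] + inc[k]
    for (k in rev(seq_len(n - 1))) if (is.finite(p[k + 1]) && is.finite(inc[k]) &&
                                       !is.finite(p[k]))
      p[k] <- p[k + 1] - inc[k]
  }
  ring <- matrix(NA_real_, nx, ny)
  ring[ij] <- p
  ring[!grad$valid] <- NA_real_
  ring
}

# One pressure-estimate matrix per straight-ray family. Families 1-4 are the
# axis directions (+x, -x, +y, -y), 5-8 the diagonals. Rays start at the
# domain edge (seeded with the shared ring pressure) and accumulate
# trapezoidal increments of the projected gradient; they terminate at
# invalid nodes and never bridge them (cumsum propagates NA past a block).
ray_family_estimates <- function(grad, n_directions = 8) {
  g <- grad$grid
  nx <- g$nx; ny <- g$ny
  n_directions <- as.integer(n_directions)
  if (!n_directions %in% c(4L, 8L))
    stop("n_directions must be 4 (axes) or 8 (axes + diagonals)")
  ring <- edge_ring_pressure(grad)
  gx <- grad$dpdx; gy <- grad$dpdy
  V <- grad$valid
  gxn <- gx; gxn[!V] <- NA_real_
  gyn <- gy; gyn[!V] <- NA_real_

  est <- vector("list", n_directions)
  est[[1]] <- ray_along_rows(gxn, g$dx, ring[1, ], FALSE)
  est[[2]] <- ray_along_rows(gxn, g$dx, ring[nx, ], TRUE)
  est[[3]] <- t(ray_along_rows(t(gyn), g$dy, ring[, 1], FALSE))
  est[[4]] <- t(ray_along_rows(t(gyn), g$dy, ring[, ny], TRUE))

  if (n_directions == 8L) {
    step <- sqrt(g$dx^2 + g$dy^2)
    for (kk in 1:4) {
      sx <- c(1, -1, 1, -1)[kk]; sy <- c(1, 1, -1, -1)[kk]
      proj <- sx * g$dx * gxn + sy * g$dy * gyn   # g . step vector
      e <- matrix(NA_real_, nx, ny)
      # rays of direction (sx, sy): enumerate by starting node on the edge
      starts <- rbind(
        cbind(if (sx > 0) 1L else nx, seq_len(ny)),
        cbind(seq_len(nx), if (sy > 0) 1L else ny))
      starts <- unique(starts)
      for (s in seq_len(nrow(starts))) {
        i0 <- starts[s, 1]; j0 <- starts[s, 2]
        len <- min(if (sx > 0) nx - i0 else i0 - 1,
                   if (sy > 0) ny - j0 else j0 - 1) + 1
        ii <- i0 + sx * (seq_len(len) - 1)
        jj <- j0 + sy * (seq_len(len) - 1)
        idx <- cbind(ii, jj)
        pr <- proj[idx]
        inc <- c(ring[i0, j0], 0.5 * (pr[-len] + pr[-1]))
        e[idx] <- cumsum(inc)
      }
      est[[4 + kk]] <- e
    }
  }
  array(unlist(est), dim = c(nx, ny, n_directions))
}

# Cumulative trapezoid of the row-direction gradient component down each
# column, seeded at the first row. flip = TRUE integrates from the last row
# toward the first (the step is then -h).
ray_along_rows <- function(f, h, seed, flip) {
  n <- nrow(f)
  step <- h
  if (flip) { f <- f[n:1, , drop = FALSE]; step <- -h }
  inc <- rbind(seed, 0.5 * (f[-n, , drop = FALSE] + f[-1, , drop = FALSE]) * step)
  est <- apply(inc, 2, cumsum)
  if (flip) est[n:1, , drop = FALSE] else est
}

#' Integrate a pressure-gradient field with median polling
#'
#' One pressure estimate per straight-ray direction family is produced by
#' trapezoidal line integration of the projected gradient from the domain
#' edge inward; the node value is the median of the available estimates
#' (for an even count, the mean of the two central values). Paths terminate
#' at masked or invalid nodes and never integrate across them. The gauge is
#' fixed afterwards so the median pressure over the outermost valid ring
#' is zero; nodes inside the mask are undefined.
#'
#' @param grad A `pressure_gradient_frame`.
#' @param mask Optional `body_mask`; nodes inside are treated as opaque.
#' @param n_directions 4 or 8 ray families (default 8: axes + diagonals).
#' @return A `pressure_frame`.
#' @export
integrate_pressure <- function(grad, mask = NULL, n_directions = 8) {
  stopifnot(inherits(grad, "pressure_gradient_frame"))
  g <- grad$grid
  if (!is.null(mask)) {
    nd <- grid_nodes(g)
    inside <- matrix(mask_contains(mask, cbind(as.vector(nd$x), as.vector(nd$y))),
                     g$nx, g$ny)
    grad$valid <- grad$valid & !inside
    grad$dpdx[!grad$valid] <- NA_real_
    grad$dpdy[!grad$valid] <- NA_real_
  } else inside <- matrix(FALSE, g$nx, g$ny)
  if (!any(grad$valid)) stop("empty field: no valid gradient nodes")

  est <- ray_family_estimates(grad, n_directions)
  p <- apply(est, c(1, 2), stats::median, na.rm = TRUE)
  p[inside] <- NA_real_
  p[!grad$valid] <- NA_real_

  defined <- is.finite(p)
  ring_sel <- matrix(FALSE, g$nx, g$ny)
  ring_sel[c(1, g$nx), ] <- TRUE
  ring_sel[, c(1, g$ny)] <- TRUE
  ring_vals <- p[ring_sel & defined]
  if (length(ring_vals)) p <- p - stats::median(ring_vals)
  pressure_frame(g, p, t = grad$t, defined = defined)
}

#' Pressure fields for a velocity sequence
#'
#' Subsamples the sequence to the calculation interval `dt_calc` (an
#' integer multiple of the acquisition step; 0.01 s by default, the value
#' that preserves the load trends while keeping computation cheap), then
#' evaluates the pressure gradient with temporal neighbours at `dt_calc`
#' spacing and integrates each frame with median polling.
#'
#' @param seq A `velocity_sequence`.
#' @param masks Optional list of `body_mask` per retained frame (or a
#'   single mask recycled, or `NULL`).
#' @param fluid A `fluid_properties`.
#' @param dt_calc Calculation interval (s), integer multiple of `seq$dt`.
#' @param n_directions Passed to [integrate_pressure()].
#' @param viscous Passed to [pressure_gradient()].
#' @return List of `pressure_frame`s with the original timestamps.
#' @export
pressure_sequence <- function(seq, masks = NULL, fluid = fluid_properties(),
                              dt_calc = 0.01, n_directions = 8,
                              viscous = TRUE) {
  stopifnot(inherits(seq, "velocity_sequence"))
  stride <- dt_calc / seq$dt
  if (abs(stride - round(stride)) > 1e-6)
    stop(sprintf("dt_calc (%g s) must be an integer multiple of the sequence dt (%g s)",
                 dt_calc, seq$dt))
  stride <- as.integer(round(stride))
  keep <- seq(1L, length(seq$frames), by = stride)
  frames <- seq$frames[keep]
  n <- length(frames)
  if (!is.null(masks) && inherits(masks, "body_mask")) masks <- rep(list(masks), n)
  if (!is.null(masks) && length(masks) != n)
    stop("need one mask per retained frame")
  out <- vector("list", n)
  for (k in seq_len(n)) {
    prev <- if (k > 1) frames[[k - 1]] else NULL
    nxt <- if (k < n) frames[[k + 1]] else NULL
    grad <- pressure_gradient(prev, frames[[k]], nxt, fluid, dt_calc,
                              viscous = viscous)
    out[[k]] <- integrate_pressure(grad, mask = if (is.null(masks)) NULL else masks[[k]],
                                   n_directions = n_directions)
  }
  out
}
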