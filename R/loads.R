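#' Sample a pressure field at control-surface points
#'
#' Bilinear interpolation from the four surrounding grid nodes, using only
#' defined nodes with renormalized weights; when all four are undefined the
#' nearest defined node within two cells is used instead (the fallback
#' count is reported in the `fallbacks` attribute - a data-quality signal
#' normally managed by mask sizing).
#'
#' @param p A `pressure_frame`.
#' @param surface A `control_surface` lying inside the grid extent.
#' @return Numeric vector of pressures (Pa), one per surface point, with
#'   attribute `fallbacks` (count of nearest-node fallbacks).
#' @export
sample_pressure <- function(p, surface) {
  stopifnot(inherits(p, "pressure_frame"), inherits(surface, "control_surface"))
  g <- p$grid
  pts <- surface$points
  fx <- (pts[, 1] - g$x0) / g$dx
  fy <- (pts[, 2] - g$y0) / g$dy
  if (any(fx < 0 | fx > g$nx - 1 | fy < 0 | fy > g$ny - 1))
    stop("control surface extends outside the pressure grid")
  i0 <- pmin(pmax(floor(fx), 0), g$nx - 2) + 1
  j0 <- pmin(pmax(floor(fy), 0), g$ny - 2) + 1
  tx <- fx - (i0 - 1); ty <- fy - (j0 - 1)
  out <- numeric(nrow(pts))
  fallbacks <- 0L
  for (k in seq_len(nrow(pts))) {
    ii <- c(i0[k], i0[k] + 1, i0[k], i0[k] + 1)
    jj <- c(j0[k], j0[k], j0[k] + 1, j0[k] + 1)
    w <- c((1 - tx[k]) * (1 - ty[k]), tx[k] * (1 - ty[k]),
           (1 - tx[k]) * ty[k], tx[k] * ty[k])
    vals <- p$p[cbind(ii, jj)]
    def <- p$defined[cbind(ii, jj)]
    if (any(def & w > 0) || any(def)) {
      w[!def] <- 0
      if (sum(w) > 0) {
        out[k] <- sum(w * vals, na.rm = TRUE) / sum(w)
        next
      }
    }
    # all four corners undefined (or zero usable weight): nearest defined
    # node within 2 cells
    ir <- max(1, i0[k] - 2):min(g$nx, i0[k] + 3)
    jr <- max(1, j0[k] - 2):min(g$ny, j0[k] + 3)
    sub <- expand.grid(i = ir, j = jr)
    def2 <- p$defined[cbind(sub$i, sub$j)]
    if (!any(def2))
      stop(sprintf("undefined pressure around surface point %d: no defined node within 2 cells", k))
    dx2 <- (g$x0 + (sub$i - 1) * g$dx - pts[k, 1])^2 +
           (g$y0 + (sub$j - 1) * g$dy - pts[k, 2])^2
    dx2[!def2] <- Inf
    b <- which.min(dx2)
    out[k] <- p$p[sub$i[b], sub$j[b]]
    fallbacks <- fallbacks + 1L
  }
  attr(out, "fallbacks") <- fallbacks
  out
}

#' Integrate pressure loads over a control surface
#'
#' Pressure-only surface integral of the load exerted by the fluid on the
#' body: `F = -sum p_i n_i dl_i s_i` and
#' `Tz = -sum p_i [(r_i - reference) x n_i]_z dl_i s_i`, with `n` the unit
#' outward normal, `dl` the forward distance between loop points and `s`
#' the local span. The viscous (shear) contribution is intentionally
#' omitted - the method's central approximation - and reported as an
#' identically-zero `shear` component so reports can state "pressure-only".
#' With +x pointing downstream, thrust appears as negative `Fx`.
#'
#' @param surface A `control_surface` with spans attached
#'   (see [attach_span()]).
#' @param pressures Numeric vector from [sample_pressure()] (or analytic),
#'   one value per surface point, no `NA`s.
#' @param reference Torque reference point (m); defaults to the surface's
#'   stored leading edge `r0`.
#' @return List with `F` (length-2, N), `Tz` (N m) and `shear`
#'   (zero placeholder).
#' @export
integrate_loads <- function(surface, pressures, reference = surface$r0) {
  stopifnot(inherits(surface, "control_surface"))
  n <- nrow(surface$points)
  if (length(pressures) != n) stop("pressure count must match surface points")
  if (any(!is.finite(pressures)))
    stop("NaN/undefined pressure on the surface; resolve upstream (mask sizing)")
  if (any(!is.finite(reference)) || length(reference) != 2)
    stop("reference must be a finite (x, y) point")
  if (any(!is.finite(surface$span)))
    stop("surface has no span attached; call attach_span()")
  w <- pressures * surface$dl * surface$span
  Fx <- -sum(w * surface$normals[, 1])
  Fy <- -sum(w * surface$normals[, 2])
  rx <- surface$points[, 1] - reference[1]
  ry <- surface$points[, 2] - reference[2]
  crossz <- rx * surface$normals[, 2] - ry * surface$normals[, 1]
  Tz <- -sum(w * crossz)
  list(F = c(Fx, Fy), Tz = Tz, shear = list(F = c(0, 0), Tz = 0))
}

#' Nondimensionalize forces and torques
#'
#' `F* = F / (rho s c v^2)` and `T* = T / (rho s c^2 v^2)`, with `s` the
#' span, `c` the chord and `v` the flow speed.
#'
#' @param record A one-row data frame (or list) with `Fx`, `Fy`, `Tz`.
#' @param rho Fluid density (kg/m^3), > 0.
#' @param span,chord Body span and chord (m), > 0.
#' @param speed Flow speed (m/s), > 0.
#' @return The record with `Fx_star`, `Fy_star`, `Tz_star` added.
#' @export
nondimensionalize <- function(record, rho, span, chord, speed) {
  if (any(c(rho, span, chord, speed) <= 0) || !all(is.finite(c(rho, span, chord, speed))))
    stop("rho, span, chord, speed must all be finite and > 0")
  fs <- rho * span * chord * speed^2
  record$Fx_star <- record$Fx / fs
  record$Fy_star <- record$Fy / fs
  record$Tz_star <- record$Tz / (fs * chord)
  record
}

#' Load time series container
#'
#' A data frame of per-frame loads (columns `t`, `Fx`, `Fy`, `Tz`,
#' optionally `theta` and starred nondimensional columns) with provenance
#' and optional motion-cycle period attached as attributes.
#'
#' @param df Data frame with at least `t`, `Fx`, `Fy`, `Tz`; `t` strictly
#'   increasing with uniform step.
#' @param provenance One of `"measured"`, `"estimated"`, `"rod"`,
#'   `"foil-only"`.
#' @param period Motion-cycle period (s) or `NULL`.
#' @return A `load_series` (data frame subclass).
#' @export
load_series_frame <- function(df, provenance = c("estimated", "measured",
                                                 "rod", "foil-only"),
                              period = NULL) {
  provenance <- match.arg(provenance)
  need <- c("t", "Fx", "Fy", "Tz")
  if (!all(need %in% names(df))) stop("load series needs columns t, Fx, Fy, Tz")
  if (nrow(df) > 1) {
    dts <- diff(df$t)
    if (any(dts <= 0)) stop("timestamps must be strictly increasing")
    if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
      stop("timestamps must have a uniform step")
  }
  structure(as.data.frame(df), provenance = provenance, period = period,
            class = c("load_series", "data.frame"))
}

#' Assemble a load series from pressure frames and surfaces
#'
#' Per frame: sample the pressure on the control surface, integrate, and
#' nondimensionalize.
#'
#' @param pressures List of `pressure_frame`s.
#' @param surfaces List of `control_surface`s (spans attached), one per
#'   frame.
#' @param reference `"leading-edge"` (each surface's own `r0`) or a fixed
#'   (x, y) point.
#' @param rho,span,chord,speed Nondimensionalization parameters; when any
#'   is `NULL` the starred columns are skipped.
#' @param theta Optional pitch-angle vector (rad), one per frame.
#' @param period Motion-cycle period (s), carried on the result.
#' @return A `load_series` with provenance `"estimated"` and attribute
#'   `fallbacks` (total nearest-node sampling fallbacks).
#' @export
load_series <- function(pressures, surfaces, reference = "leading-edge",
                        rho = NULL, span = NULL, chord = NULL, speed = NULL,
                        theta = NULL, period = NULL) {
  n <- length(pressures)
  if (length(surfaces) != n) stop("need one surface per pressure frame")
  if (!is.null(theta) && length(theta) != n) stop("theta length mismatch")
  rec <- data.frame(t = numeric(n), Fx = numeric(n), Fy = numeric(n),
                    Tz = numeric(n))
  fallbacks <- 0L
  for (k in seq_len(n)) {
    ps <- sample_pressure(pressures[[k]], surfaces[[k]])
    fallbacks <- fallbacks + attr(ps, "fallbacks")
    ref <- if (identical(reference, "leading-edge")) surfaces[[k]]$r0 else reference
    ld <- integrate_loads(surfaces[[k]], ps, reference = ref)
    rec$t[k] <- pressures[[k]]$t
    rec$Fx[k] <- ld$F[1]; rec$Fy[k] <- ld$F[2]; rec$Tz[k] <- ld$Tz
  }
  if (!is.null(theta)) rec$theta <- theta
  if (!is.null(rho) && !is.null(span) && !is.null(chord) && !is.null(speed))
    rec <- nondimensionalize(rec, rho, span, chord, speed)
  out <- load_series_frame(rec, provenance = "estimated", period = period)
  attr(out, "fallbacks") <- fallbacks
  out
}
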