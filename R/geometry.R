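#' Body midline
#'
#' Ordered centerline polyline of a (possibly deforming) body, leading edge
#' first, in physical meters.
#'
#' @param points `n x 2` matrix of (x, y) coordinates (m), n >= 2, no
#'   duplicate consecutive points.
#' @param t Frame time (s).
#' @return An object of class `midline`.
#' @export
midline <- function(points, t = 0) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 2) stop("midline needs >= 2 (x, y) points")
  if (any(!is.finite(points))) stop("midline coordinates must be finite")
  seg <- diff(points)
  if (any(sqrt(rowSums(seg^2)) == 0)) stop("duplicate consecutive midline points")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, t = as.numeric(t)), class = "midline")
}

#' Flat-plate 99% boundary-layer thickness
#'
#' Laminar flat-plate estimate `delta99 = 5 x / sqrt(Re)`, with `x` the
#' chord length and `Re` the chord-based Reynolds number. This length scale
#' sets the mask and control-surface offsets.
#'
#' @param x Chord length (m), >= 0.
#' @param Re Reynolds number, > 0.
#' @return Thickness (m).
#' @examples
#' delta99(0.18, 54000)  # ~3.87 mm
#' @export
delta99 <- function(x, Re) {
  if (any(x < 0)) stop("x must be >= 0")
  if (any(!is.finite(Re)) || any(Re <= 0)) stop("Re must be > 0")
  5 * x / sqrt(Re)
}

#' Extend a midline upstream of its leading edge
#'
#' Prepends a point at the given distance upstream along the reversed
#' tangent of the first segment (models an actuation rod clamped at the
#' leading edge that the camera cannot see).
#'
#' @param m A `midline`.
#' @param length Extension length (m), >= 0; 0 returns the midline unchanged.
#' @return A `midline` with one extra leading point (when `length > 0`).
#' @export
extend_leading_edge <- function(m, length) {
  stopifnot(inherits(m, "midline"))
  if (!is.finite(length) || length < 0) stop("length must be >= 0")
  if (length == 0) return(m)
  tangent <- m$points[2, ] - m$points[1, ]
  nrm <- sqrt(sum(tangent^2))
  if (nrm == 0) stop("degenerate first midline segment")
  new_pt <- m$points[1, ] - length * tangent / nrm
  midline(rbind(new_pt, m$points), t = m$t)
}

# densify a polyline to roughly n points at equal arc spacing
densify_polyline <- function(pts, n = 400) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  si <- seq(0, s[length(s)], length.out = max(n, nrow(pts)))
  cbind(stats::approx(s, pts[, 1], xout = si)$y,
        stats::approx(s, pts[, 2], xout = si)$y)
}

# distance from each query point to a polyline, plus the arc position of the
# nearest point. pts: m x 2 polyline; q: n x 2 queries. Vectorized over
# segments (polylines here are short).
polyline_distance <- function(q, pts) {
  m <- nrow(pts)
  seg_d2 <- matrix(Inf, nrow(q), m - 1)
  seg_s <- matrix(0, nrow(q), m - 1)
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  for (k in seq_len(m - 1)) {
    a <- pts[k, ]; b <- pts[k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tq <- ((q[, 1] - a[1]) * ab[1] + (q[, 2] - a[2]) * ab[2]) / len2
    tq <- pmin(pmax(tq, 0), 1)
    dx <- q[, 1] - (a[1] + tq * ab[1])
    dy <- q[, 2] - (a[2] + tq * ab[2])
    seg_d2[, k] <- dx * dx + dy * dy
    seg_s[, k] <- cum[k] + tq * sqrt(len2)
  }
  best <- max.col(-seg_d2, ties.method = "first")
  idx <- cbind(seq_len(nrow(q)), best)
  list(dist = sqrt(seg_d2[idx]), arc = seg_s[idx])
}

# resample a closed loop (n x 2, not repeated) to n_points equal arc spacing
resample_loop <- function(pts, n_points) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  keep <- c(TRUE, seg > 0)
  closed <- closed[keep, , drop = FALSE]
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  dup <- duplicated(s)
  s <- s[!dup]; closed <- closed[!dup, , drop = FALSE]
  total <- s[length(s)]
  si <- seq(0, total, length.out = n_points + 1)[-(n_points + 1)]
  cbind(stats::approx(s, closed[, 1], xout = si)$y,
        stats::approx(s, closed[, 2], xout = si)$y)
}

# centered circular moving average of span k applied to each column
smooth_loop <- function(pts, k) {
  if (k <= 1) return(pts)
  if (k %% 2 == 0) stop("smoothing span must be odd")
  n <- nrow(pts)
  half <- (k - 1) / 2
  idx <- outer(seq_len(n), -half:half, function(i, o) ((i + o - 1) %% n) + 1)
  cbind(rowMeans(matrix(pts[idx, 1], n)), rowMeans(matrix(pts[idx, 2], n)))
}

#' Offset boundary of a midline
#'
#' Builds the closed loop at constant normal distance `halfwidth` from the
#' midline (the geometric equivalent of rasterize / binary-dilate /
#' boundary-trace), resampled to `n_points` of equal arc spacing and
#' smoothed with a centered circular moving average. Two pathways are
#' provided: exact geometric buffering (default; side offsets plus
#' semicircular end caps) and a raster pathway (distance-field contour)
#' kept as a cross-check of the image-processing route; they agree to
#' within the raster cell size.
#'
#' @param m A `midline`.
#' @param halfwidth Offset distance (m), > 0.
#' @param n_points Loop points after resampling, >= 16 (default 200).
#' @param smooth_span Moving-average span (odd), default 5.
#' @param method `"buffer"` (geometric) or `"raster"`.
#' @param raster_cells Cells across `halfwidth` for the raster pathway.
#' @return List of class `control_surface`: `points` (closed loop, not
#'   repeated), unit outward `normals`, forward segment lengths `dl` (m),
#'   per-point `span` (m, filled by [attach_span()]; default `NA`),
#'   midline `arc` positions (m), and torque reference `r0` (the leading
#'   edge).
#' @export
offset_boundary <- function(m, halfwidth, n_points = 200, smooth_span = 5,
                            method = c("buffer", "raster"),
                            raster_cells = 8) {
  stopifnot(inherits(m, "midline"))
  method <- match.arg(method)
  if (!is.finite(halfwidth) || halfwidth <= 0) stop("halfwidth must be > 0")
  n_points <- as.integer(n_points)
  if (n_points < 16L) stop("n_points must be >= 16")
  dense <- densify_polyline(m$points, 400)

  if (method == "buffer") {
    nseg <- nrow(dense)
    tang <- rbind(dense[2, ] - dense[1, ],
                  (dense[-(1:2), , drop = FALSE] -
                     dense[seq_len(nseg - 2), , drop = FALSE]) / 2,
                  dense[nseg, ] - dense[nseg - 1, ])
    tang <- tang / sqrt(rowSums(tang^2))
    nl <- cbind(-tang[, 2], tang[, 1])          # left normal
    left <- dense + halfwidth * nl
    right <- dense - halfwidth * nl
    cap <- function(center, from_ang, to_ang, k = 32) {
      ang <- seq(from_ang, to_ang, length.out = k)
      cbind(center[1] + halfwidth * cos(ang), center[2] + halfwidth * sin(ang))
    }
    # trailing cap: from left normal around through forward tangent to right
    a_end <- atan2(nl[nseg, 2], nl[nseg, 1])
    cap_end <- cap(dense[nseg, ], a_end, a_end - pi)
    a_start <- atan2(-nl[1, 2], -nl[1, 1])
    cap_start <- cap(dense[1, ], a_start, a_start - pi)
    loop <- rbind(left, cap_end, right[rev(seq_len(nseg)), ], cap_start)
  } else {
    cell <- halfwidth / raster_cells
    if (cell <= 0) stop("halfwidth smaller than raster resolution; use a finer raster")
    pad <- 2.5 * halfwidth
    xs <- seq(min(dense[, 1]) - pad, max(dense[, 1]) + pad, by = cell)
    ys <- seq(min(dense[, 2]) - pad, max(dense[, 2]) + pad, by = cell)
    q <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
    dist <- polyline_distance(q, dense)$dist
    img <- matrix(as.numeric(dist <= halfwidth), length(xs), length(ys))
    cl <- grDevices::contourLines(xs, ys, img, levels = 0.5)
    if (!length(cl)) stop("raster boundary trace found no contour")
    lens <- vapply(cl, function(cc) length(cc$x), numeric(1))
    best <- cl[[which.max(lens)]]
    loop <- cbind(best$x, best$y)
  }

  pts <- resample_loop(loop, n_points)
  pts <- smooth_loop(pts, smooth_span)
  # smoothing contracts segments near high curvature; re-resampling restores
  # equal arc spacing without reintroducing the jagged edges
  pts <- resample_loop(pts, n_points)

  # normals recomputed after smoothing: perpendicular of the central-difference
  # tangent, oriented away from the nearest midline point
  nxt <- pts[c(2:n_points, 1), ]
  prv <- pts[c(n_points, 1:(n_points - 1)), ]
  tang <- nxt - prv
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- cbind(-tang[, 2], tang[, 1])
  near <- polyline_distance(pts, dense)
  # direction from nearest midline point (recomputed through projection)
  cum <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  out_dir <- pts - cbind(stats::approx(cum, dense[, 1], xout = near$arc, rule = 2)$y,
                         stats::approx(cum, dense[, 2], xout = near$arc, rule = 2)$y)
  flip <- rowSums(nrm * out_dir) < 0
  nrm[flip, ] <- -nrm[flip, ]
  # centered segment length |p(i+1) - p(i-1)| / 2: paired with the
  # central-difference normal, the loop sum p_i n_i dl_i reproduces the
  # polygon surface integral exactly for linear pressure fields (the
  # forward distance would overweight high-curvature end caps by ~1%)
  dl <- sqrt(rowSums((nxt - prv)^2)) / 2

  structure(list(points = pts, normals = nrm, dl = dl,
                 span = rep(NA_real_, n_points), arc = near$arc,
                 r0 = m$points[1, ], t = m$t),
            class = "control_surface")
}

#' Attach a span profile to a control surface
#'
#' Each surface point is projected to its nearest midline arc position and
#' the span profile is evaluated there; a scalar gives the constant span of
#' a rectangular body.
#'
#' @param surface A `control_surface`.
#' @param span Scalar span (m) or a function `span(arc)` of the chordwise
#'   arc position (m).
#' @return The surface with its `span` field filled.
#' @export
attach_span <- function(surface, span) {
  stopifnot(inherits(surface, "control_surface"))
  s <- if (is.function(span)) vapply(surface$arc, span, numeric(1))
       else rep(as.numeric(span), length(surface$dl))
  if (any(!is.finite(s)) || any(s <= 0)) stop("span must be > 0 over the body")
  surface$span <- s
  surface
}

#' @export
print.control_surface <- function(x, ...) {
  cat(sprintf("control_surface: %d points, perimeter %.4g m, reference (%.4g, %.4g)\n",
              nrow(x$points), sum(x$dl), x$r0[1], x$r0[2]))
  invisible(x)
}

#' Body mask and control surface for a midline
#'
#' The mask loop sits at `mask_factor * delta99` from the midline (it marks
#' where velocity vectors are contaminated by the body) and the force
#' calculation loop at `surface_factor * delta99`, so the surface always
#' encloses the mask and pressure is defined at every sampling point.
#'
#' @param m A `midline`.
#' @param chord Chord length (m).
#' @param Re Chord Reynolds number.
#' @param mask_factor Mask offset in delta99 units (default 1.1).
#' @param surface_factor Surface offset in delta99 units (default 1.64);
#'   must exceed `mask_factor`.
#' @param n_points Points per loop (default 200).
#' @return List with `mask` (a `body_mask`) and `surface`
#'   (a `control_surface`).
#' @export
boundary_pair <- function(m, chord, Re, mask_factor = 1.1,
                          surface_factor = 1.64, n_points = 200) {
  if (mask_factor <= 0 || surface_factor <= mask_factor)
    stop("need surface_factor > mask_factor > 0")
  d <- delta99(chord, Re)
  mask_loop <- offset_boundary(m, mask_factor * d, n_points = n_points)
  surface <- offset_boundary(m, surface_factor * d, n_points = n_points)
  list(mask = body_mask(mask_loop$points), surface = surface)
}

#' Body mask
#'
#' Closed loop delimiting the region where pressure is undefined (body plus
#' contaminated velocity vectors).
#'
#' @param boundary `n x 2` closed loop (not repeated).
#' @return An object of class `body_mask`.
#' @export
body_mask <- function(boundary) {
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2 || nrow(boundary) < 3) stop("mask boundary needs >= 3 points")
  structure(list(boundary = boundary), class = "body_mask")
}

#' Points inside a body mask
#'
#' @param mask A `body_mask` (or `NULL`, in which case all points are out).
#' @param pts `n x 2` matrix of query points.
#' @return Logical vector, `TRUE` inside the mask loop.
#' @export
mask_contains <- function(mask, pts) {
  pts <- as.matrix(pts)
  if (is.null(mask)) return(rep(FALSE, nrow(pts)))
  stopifnot(inherits(mask, "body_mask"))
  bnd <- rbind(mask$boundary, mask$boundary[1, ])
  mgcv::in.out(bnd, pts)
}

#' Control-surface sweep over offset factors
#'
#' Builds one control surface per offset factor (in delta99 units); the
#' loops are nested with strictly increasing enclosed area, the geometry of
#' the placement-sensitivity sweep.
#'
#' @param m A `midline`.
#' @param chord,Re Chord (m) and Reynolds number.
#' @param factors Ascending offset factors, e.g.
#'   `c(1.5, 2.0, 2.5, 3.0, 3.5, 4.0)`.
#' @param n_points Points per loop.
#' @return List of `control_surface` objects, one per factor.
#' @export
surface_sweep <- function(m, chord, Re,
                          factors = c(1.5, 2.0, 2.5, 3.0, 3.5, 4.0),
                          n_points = 200) {
  if (is.unsorted(factors, strictly = TRUE)) stop("factors must be sorted ascending")
  d <- delta99(chord, Re)
  lapply(factors, function(f) offset_boundary(m, f * d, n_points = n_points))
}

#' Midline detection from a grayscale image (utility)
#'
#' For each image column intersecting the body, returns the
#' intensity-weighted centroid row of above-threshold pixels; columns with
#' no such pixel are filled by linear interpolation. Coordinates are in
#' pixels; callers apply their own pixel-to-meter scale.
#'
#' @param image Numeric matrix (rows x cols) of intensities.
#' @param threshold Intensity threshold.
#' @return A `midline` in (col, row) pixel coordinates.
#' @export
detect_midline <- function(image, threshold) {
  image <- as.matrix(image)
  if (!length(image)) stop("empty image")
  hit <- image > threshold
  if (!any(hit)) stop("midline detection failed: no pixel above threshold")
  cols <- which(colSums(hit) > 0)
  rows <- vapply(cols, function(jj) {
    w <- image[, jj] * hit[, jj]
    sum(w * seq_len(nrow(image))) / sum(w)
  }, numeric(1))
  all_cols <- seq(min(cols), max(cols))
  rows_full <- stats::approx(cols, rows, xout = all_cols)$y
  midline(cbind(all_cols, rows_full))
}
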