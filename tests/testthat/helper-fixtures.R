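# shared fixtures, built in code at test time

# analytic circle control surface (exact normals/segments), radius R about
# `center`, constant span
circle_surface <- function(R = 0.1, n = 200, span = 0.05, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pts <- cbind(center[1] + R * cos(th), center[2] + R * sin(th))
  nxt <- pts[c(2:n, 1), ]; prv <- pts[c(n, 1:(n - 1)), ]
  structure(list(points = pts, normals = cbind(cos(th), sin(th)),
                 dl = sqrt(rowSums((nxt - prv)^2)) / 2,
                 span = rep(span, n), arc = rep(0, n),
                 r0 = center, t = 0),
            class = "control_surface")
}

# random star-shaped closed surface for property tests
random_surface <- function(n = 64, span = 0.05) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 0.08 + 0.03 * runif(1) + 0.02 * sin(sample(2:5, 1) * th + runif(1) * 2 * pi)
  pts <- cbind(r * cos(th), r * sin(th))
  nxt <- pts[c(2:n, 1), ]; prv <- pts[c(n, 1:(n - 1)), ]
  tang <- nxt - prv
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = pts, normals = cbind(tang[, 2], -tang[, 1]) *
                   sign(pivload:::polygon_area_centroid(pts)$area),
                 dl = sqrt(rowSums((nxt - prv)^2)) / 2,
                 span = rep(span, n), arc = rep(0, n),
                 r0 = c(0, 0), t = 0),
            class = "control_surface")
}

# gauge-aligned RMS error of a pressure frame against a truth matrix,
# normalized by the truth's peak-to-peak range
pressure_nrmse <- function(pf, truth) {
  e <- pf$p - truth
  e <- e - mean(e, na.rm = TRUE)
  sqrt(mean(e^2, na.rm = TRUE)) / (max(truth, na.rm = TRUE) - min(truth, na.rm = TRUE))
}

tg_grid <- function(n) grid_spec(0, 0, 2 * pi / (n - 1), 2 * pi / (n - 1), n, n)
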