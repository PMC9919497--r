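# Independent oracles used to check the analytic implementations.

# Brute-force aspect ratio: rasterise the polygon at `supersample` pixels
# per unit and take the eigenvalue ratio of the pixel-cloud covariance.
raster_ar <- function(v, supersample = 10) {
  step <- 1 / supersample
  xr <- range(v[, 1]); yr <- range(v[, 2])
  xs <- seq(xr[1] + step / 2, xr[2], by = step)
  ys <- seq(yr[1] + step / 2, yr[2], by = step)
  g <- expand.grid(x = xs, y = ys)
  inside <- psmet:::points_in_polygon(g$x, g$y, v)
  pts <- g[inside, ]
  ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
  sqrt(ev[1] / ev[2])
}

# Random star polygon: sorted angles, radii drawn in a band, anisotropic
# x-scaling so AR varies. If the angles happen to cluster in a half-plane
# the construction can self-intersect, so redraw until the polygon is
# simple (the AR engine's documented precondition).
random_polygon <- function(n_vertices = 7, scale = 20, concavity = 0.5) {
  repeat {
    ang <- sort(runif(n_vertices, 0, 2 * pi))
    rad <- scale * runif(n_vertices, 1 - concavity / 2, 1 + concavity / 2)
    sx <- runif(1, 0.5, 2)
    v <- cbind(x = sx * rad * cos(ang), y = rad * sin(ang))
    if (psmet:::is_simple_polygon(v)) return(v)
  }
}

# Random rigid motion (+ optional uniform scaling) of a polygon.
rigid_transform <- function(v, scale = 1) {
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  t(scale * R %*% t(v)) + matrix(runif(2, -100, 100), nrow(v), 2, byrow = TRUE)
}

# Dense-projection position oracle: resample the midline at n_dense points
# by arc length and return, per input point, the normalized position of the
# nearest resampled point.
dense_position <- function(px, py, midline, n_dense = 10000) {
  seg <- sqrt(rowSums(diff(midline)^2))
  cum <- c(0, cumsum(seg))
  s <- seq(0, cum[length(cum)], length.out = n_dense)
  mx <- stats::approx(cum, midline[, 1], s)$y
  my <- stats::approx(cum, midline[, 2], s)$y
  vapply(seq_along(px), function(i) {
    s[which.min((mx - px[i])^2 + (my - py[i])^2)]
  }, 1) / cum[length(cum)] * 100
}

# A small noiseless-truth object shared by several tests.
quiet_truth <- function(...) {
  synthetic_truth(ar_sigma = 0, intensity_sigma = 0, ...)
}
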