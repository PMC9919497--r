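# Planar polygon primitives used by the shape and axis modules.
# Vertices are n x 2 matrices in pixel coordinates (x right, y down),
# implicitly closed (last vertex joins the first).

# Drop a duplicated closing vertex if present.
close_polygon <- function(v) {
  v <- as.matrix(v)
  if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  storage.mode(v) <- "double"
  unname(v)
}

# Signed area, centroid and area-covariance matrix of a simple polygon,
# by Green's theorem on the vertex list (exact for polygons; no rasterisation).
polygon_moments <- function(v) {
  v <- close_polygon(v)
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  area <- sum(cr) / 2
  if (abs(area) < .Machine$double.eps * max(1, sum(abs(v)))) {
    return(list(area = 0, centroid = c(NA_real_, NA_real_), cov = NULL))
  }
  cx <- sum((x + x2) * cr) / (6 * area)
  cy <- sum((y + y2) * cr) / (6 * area)
  sxx <- sum((x^2 + x * x2 + x2^2) * cr) / 12
  syy <- sum((y^2 + y * y2 + y2^2) * cr) / 12
  sxy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  cov <- matrix(c(sxx / area - cx^2, sxy / area - cx * cy,
                  sxy / area - cx * cy, syy / area - cy^2), 2, 2)
  list(area = area, centroid = c(cx, cy), cov = cov)
}

polygon_area <- function(v) abs(polygon_moments(v)$area)

# Proper + improper segment intersection test (excluding shared endpoints),
# used to reject self-intersecting outlines. O(n^2); outlines are small.
is_simple_polygon <- function(v) {
  v <- close_polygon(v)
  n <- nrow(v)
  if (n < 3) return(FALSE)
  if (anyDuplicated(v) > 0) return(FALSE)
  orient <- function(p, q, r) {
    val <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    sign(val)
  }
  on_seg <- function(p, q, r) {
    min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
      min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  }
  idx <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    a1 <- v[i, ]; a2 <- v[idx(i + 1), ]
    for (j in seq_len(n)) {
      if (j <= i) next
      # adjacent edges share a vertex; skip
      if (j == i + 1 || (i == 1 && j == n)) next
      b1 <- v[j, ]; b2 <- v[idx(j + 1), ]
      o1 <- orient(a1, a2, b1); o2 <- orient(a1, a2, b2)
      o3 <- orient(b1, b2, a1); o4 <- orient(b1, b2, a2)
      if (o1 != o2 && o3 != o4) return(FALSE)
      if (o1 == 0 && on_seg(a1, a2, b1)) return(FALSE)
      if (o2 == 0 && on_seg(a1, a2, b2)) return(FALSE)
      if (o3 == 0 && on_seg(b1, b2, a1)) return(FALSE)
      if (o4 == 0 && on_seg(b1, b2, a2)) return(FALSE)
    }
  }
  TRUE
}

# Even-odd ray-casting point-in-polygon test, vectorised over points.
points_in_polygon <- function(px, py, poly) {
  poly <- close_polygon(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from points to a polyline (open chain of segments);
# also returns, per point, the arc length of the closest projection and the
# signed perpendicular offset (positive = left of the direction of travel).
project_on_polyline <- function(px, py, line) {
  line <- as.matrix(line)
  nseg <- nrow(line) - 1
  stopifnot(nseg >= 1)
  seg_dx <- diff(line[, 1]); seg_dy <- diff(line[, 2])
  seg_len <- sqrt(seg_dx^2 + seg_dy^2)
  cum <- c(0, cumsum(seg_len))
  np <- length(px)
  best_d2 <- rep(Inf, np)
  best_arc <- numeric(np)
  best_off <- numeric(np)
  best_seg <- integer(np)
  tie <- rep(FALSE, np)
  for (s in seq_len(nseg)) {
    wx <- px - line[s, 1]; wy <- py - line[s, 2]
    tt <- (wx * seg_dx[s] + wy * seg_dy[s]) / (seg_len[s]^2)
    tt <- pmin(1, pmax(0, tt))
    qx <- line[s, 1] + tt * seg_dx[s]
    qy <- line[s, 2] + tt * seg_dy[s]
    d2 <- (px - qx)^2 + (py - qy)^2
    cross <- seg_dx[s] * (py - line[s, 2]) - seg_dy[s] * (px - line[s, 1])
    off <- cross / seg_len[s]
    arc <- cum[s] + tt * seg_len[s]
    tol2 <- (1e-9 * max(1, max(seg_len)))^2
    better <- d2 < best_d2 - tol2
    # equidistant to two non-adjacent segments: keep the smaller arc length
    near <- abs(d2 - best_d2) <= tol2 & best_seg != 0L & abs(best_seg - s) > 1L
    tie <- tie | near
    upd <- better | (near & arc < best_arc)
    best_arc[upd] <- arc[upd]
    best_off[upd] <- off[upd]
    best_seg[upd] <- s
    best_d2[upd] <- d2[upd]
  }
  list(arc = best_arc, offset = best_off, dist = sqrt(best_d2),
       total_length = cum[length(cum)], tie = tie)
}

# Distance from points to a closed polygon boundary.
dist_to_boundary <- function(px, py, poly) {
  poly <- close_polygon(poly)
  ring <- rbind(poly, poly[1, , drop = FALSE])
  project_on_polyline(px, py, ring)$dist
}

# Vectorised Green's-theorem moments for a list of polygons: stacks all
# vertices and accumulates the per-polygon sums with rowsum(), avoiding a
# per-cell interpreter round trip. Returns area, centroid and the
# eigenvalues of the area-covariance matrix (closed form for 2x2).
polygon_moments_list <- function(vl) {
  vl <- lapply(vl, close_polygon)
  nv <- vapply(vl, nrow, 1L)
  v <- do.call(rbind, vl)
  grp <- rep.int(seq_along(vl), nv)
  ends <- cumsum(nv)
  starts <- c(1L, head(ends, -1) + 1L)
  nxt <- seq_len(nrow(v)) + 1L
  nxt[ends] <- starts
  x <- v[, 1]; y <- v[, 2]
  x2 <- x[nxt]; y2 <- y[nxt]
  cr <- x * y2 - x2 * y
  gsum <- function(v) unname(rowsum(v, grp, reorder = FALSE)[, 1])
  area <- gsum(cr) / 2
  cx <- gsum((x + x2) * cr) / (6 * area)
  cy <- gsum((y + y2) * cr) / (6 * area)
  sxx <- gsum((x^2 + x * x2 + x2^2) * cr) / 12
  syy <- gsum((y^2 + y * y2 + y2^2) * cr) / 12
  sxy <- gsum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  cxx <- sxx / area - cx^2
  cyy <- syy / area - cy^2
  cxy <- sxy / area - cx * cy
  half_tr <- (cxx + cyy) / 2
  disc <- sqrt(pmax(((cxx - cyy) / 2)^2 + cxy^2, 0))
  list(area = area, cx = cx, cy = cy,
       l1 = half_tr + disc, l2 = half_tr - disc)
}

# Area centroids for a list of polygons (vectorised).
polygon_centroids_list <- function(vl) {
  m <- polygon_moments_list(vl)
  cbind(m$cx, m$cy)
}

# Regular-polygon approximation of an ellipse, rotated by theta (radians,
# measured in image coordinates) and centred at (cx, cy).
ellipse_polygon <- function(cx, cy, major, minor, theta, n_vertices = 24) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  ex <- (major / 2) * cos(ang)
  ey <- (minor / 2) * sin(ang)
  cbind(x = cx + ex * cos(theta) - ey * sin(theta),
        y = cy + ex * sin(theta) + ey * cos(theta))
}
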