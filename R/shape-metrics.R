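#' Per-cell aspect ratio
#'
#' Computes the aspect ratio (AR) of each cell outline: the ratio of the
#' longest to the shortest dimension of the cell, the classical 2D proxy for
#' epithelial elongation. The default `"ellipse"` method takes the axis
#' ratio of the second-moment (area-covariance) ellipse of the polygon,
#' computed analytically from the vertices by Green's theorem — the same
#' quantity as FIJI's fitted-ellipse AR shape descriptor, deterministic and
#' rasterisation-free. The alternative `"feret"` method returns the
#' max/min caliper (Feret) diameter ratio; the two disagree on concave
#' outlines, so both are exposed.
#'
#' AR is invariant under rigid motion and uniform scaling and is
#' always at least 1. Major/minor axis lengths are those of the ellipse
#' with the same area moments (4 * sqrt(eigenvalue)).
#'
#' @param outlines Outline tibble with a `vertices` list-column (see
#'   [read_outlines()]), or a single two-column vertex matrix.
#' @param method `"ellipse"` (second-moment axis ratio, default) or
#'   `"feret"` (max/min caliper ratio).
#' @return A tibble with one row per cell: `cell_id`, `aspect_ratio`,
#'   `major_axis_px`, `minor_axis_px`, `centroid_x`, `centroid_y`, joined to
#'   the context columns of the input.
#' @examples
#' rect <- cbind(x = c(0, 40, 40, 0), y = c(0, 0, 20, 20))
#' aspect_ratio(rect)$aspect_ratio  # 2
#' @export
aspect_ratio <- function(outlines, method = c("ellipse", "feret")) {
  method <- match.arg(method)
  if (is.matrix(outlines)) {
    outlines <- tibble(cell_id = "cell", embryo_id = NA_character_,
                       plane = NA_character_, structure = NA_character_,
                       domain = NA_character_, somite_index = NA_integer_,
                       vertices = list(close_polygon(outlines)))
  }
  m <- polygon_moments_list(outlines$vertices)
  bad <- !is.finite(m$area) | abs(m$area) <= 0
  if (any(bad)) {
    abort(sprintf("Degenerate (zero-area) polygon for cell '%s'.",
                  outlines$cell_id[which(bad)[1]]))
  }
  coll <- m$l2 <= .Machine$double.eps * pmax(m$l1, 1)
  if (any(coll)) {
    abort(sprintf("Degenerate (collinear) polygon for cell '%s'.",
                  outlines$cell_id[which(coll)[1]]))
  }
  if (method == "ellipse") {
    ar <- tibble(cell_id = outlines$cell_id,
                 aspect_ratio = sqrt(m$l1 / m$l2),
                 major_axis_px = 4 * sqrt(m$l1),
                 minor_axis_px = 4 * sqrt(m$l2),
                 centroid_x = m$cx, centroid_y = m$cy)
  } else {
    fer <- unname(vapply(outlines$vertices, feret_diameters, numeric(2)))
    ar <- tibble(cell_id = outlines$cell_id,
                 aspect_ratio = fer[1, ] / fer[2, ],
                 major_axis_px = fer[1, ],
                 minor_axis_px = fer[2, ],
                 centroid_x = m$cx, centroid_y = m$cy)
  }
  ctx <- setdiff(names(outlines), c("vertices", names(ar)))
  dplyr::bind_cols(ar["cell_id"], outlines[ctx],
                   ar[setdiff(names(ar), "cell_id")])
}

# Max and min caliper (Feret) diameters via the convex hull: the maximum is
# the largest pairwise hull-vertex distance; the minimum is the smallest
# width over hull edges (rotating-calipers width).
feret_diameters <- function(v) {
  v <- close_polygon(v)
  h <- v[grDevices::chull(v), , drop = FALSE]
  n <- nrow(h)
  dmax <- max(stats::dist(h))
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    e <- h[j, ] - h[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    max(abs((v[, 1] - h[i, 1]) * e[2] - (v[, 2] - h[i, 2]) * e[1]) / len)
  }, 1)
  c(max = dmax, min = min(widths))
}

#' Pseudo-colour bin for an aspect ratio
#'
#' Maps AR values onto the bins of a pseudo-colour lookup table, as used to
#' colour-encode cell elongation on section images. Bins are half-open
#' `[b_i, b_{i+1})`; values at or above the last break saturate into the top
#' bin. Bin indices are counted from zero (lookup-table slots).
#'
#' @param ar Numeric vector of aspect ratios (all >= 1).
#' @param breaks Strictly increasing numeric break points, first >= 1.
#' @return Integer vector of 0-based bin indices.
#' @examples
#' ar_colormap(c(1, 3.5, 9), breaks = 1:7)  # 0, 2, 5
#' @export
ar_colormap <- function(ar, breaks = 1:7) {
  if (any(is.na(ar)) || any(ar < 1)) {
    abort("Aspect ratios must be >= 1.")
  }
  if (length(breaks) < 2 || any(diff(breaks) <= 0) || breaks[1] < 1) {
    abort("breaks must be strictly increasing with first break >= 1.")
  }
  idx <- findInterval(ar, breaks)
  idx <- pmin(pmax(idx, 1L), length(breaks) - 1L)
  as.integer(idx - 1L)
}
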