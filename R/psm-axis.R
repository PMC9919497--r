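#' PSM axis model
#'
#' Builds the rostro-caudal axis model used to straighten a sagittal PSM
#' section: an ordered midline polyline running from the posterior tip of
#' the PSM (0%) to the PSM-somite border (100%), with its cumulative
#' arc-length table. Cell positions are later expressed as the arc length of
#' their orthogonal projection onto this midline, rescaled to 0-100% per
#' embryo, which removes between-embryo variation in absolute PSM length.
#'
#' @param midline Two-column matrix or data frame of (x, y) points ordered
#'   posterior tip -> border, in pixel coordinates.
#' @param dorsal_up If `TRUE` (default), the dorsal side is the side with
#'   smaller image y ("up"); transverse offsets are signed positive dorsal.
#' @return An object of class `psm_axis`.
#' @seealso [straighten()]
#' @export
psm_axis <- function(midline, dorsal_up = TRUE) {
  m <- as.matrix(midline)
  storage.mode(m) <- "double"
  if (ncol(m) != 2 || nrow(m) < 2) abort("midline needs >= 2 (x, y) points.")
  seg <- sqrt(rowSums(diff(m)^2))
  if (any(seg == 0)) abort("midline contains repeated consecutive points.")
  structure(list(midline = m, arc = c(0, cumsum(seg)),
                 total_psm_length_px = sum(seg), dorsal_up = dorsal_up),
            class = "psm_axis")
}

#' @export
print.psm_axis <- function(x, ...) {
  cat(sprintf("<psm_axis> %d midline points, PSM length %.1f px\n",
              nrow(x$midline), x$total_psm_length_px))
  invisible(x)
}

#' Straighten cells onto the normalized PSM axis
#'
#' Projects each cell centroid orthogonally onto the midline and expresses
#' its position as a percentage of total PSM arc length: 0% at the posterior
#' tip, 100% at the PSM-somite border. The transverse offset is the signed
#' perpendicular distance from the midline (positive = dorsal side). Somite
#' cells lie rostral of the border; for plotting continuity they are placed
#' at `100 + 10 * somite_index` percent and keep their somite tag.
#'
#' A centroid equidistant from two non-adjacent midline segments (possible
#' on strongly bent midlines) is assigned to the smaller arc length, with a
#' warning.
#'
#' @param cells Outline tibble (sagittal plane) with a `vertices`
#'   list-column, or any tibble with `centroid_x`/`centroid_y` columns.
#' @param axis A [psm_axis()] model.
#' @return The input tibble with `position_percent` and
#'   `transverse_offset_px` columns added.
#' @export
straighten <- function(cells, axis) {
  stopifnot(inherits(axis, "psm_axis"))
  if (!all(c("centroid_x", "centroid_y") %in% names(cells))) {
    cent <- polygon_centroids_list(cells$vertices)
    cells$centroid_x <- cent[, 1]
    cells$centroid_y <- cent[, 2]
  }
  pr <- project_on_polyline(cells$centroid_x, cells$centroid_y, axis$midline)
  if (any(pr$tie)) {
    warn(sprintf(
      "%d centroid(s) equidistant from non-adjacent midline segments; assigned to the smaller arc length.",
      sum(pr$tie)))
  }
  pos <- 100 * pr$arc / pr$total_length
  # image y grows downward: 'left of travel' is the ventral side when the
  # dorsal side is up, so flip the sign to make positive = dorsal
  off <- if (axis$dorsal_up) -pr$offset else pr$offset
  if (all(c("structure", "somite_index") %in% names(cells))) {
    is_som <- cells$structure == "somite" & !is.na(cells$somite_index)
    pos[is_som] <- 100 + 10 * cells$somite_index[is_som]
  }
  cells$position_percent <- pos
  cells$transverse_offset_px <- off
  cells
}

#' Domain geometry of a section
#'
#' Describes how a section is carved into tissue domains: the outer boundary
#' of the section, the depth of the one-cell surface band, and the sector
#' rules. A cell is a *surface* cell iff its outline intersects the band of
#' `band_depth_px` inset from the outer boundary (operationalising "a single
#' layer of cells" without tracking adjacency); all other cells are core.
#' Surface cells are then partitioned: sagittal sections into dorsal/ventral
#' by side; transverse sections into the four 90-degree sectors about the
#' section centroid (dorsal up, ventral down, medial/lateral by
#' `medial_side`), rotatable via `angle_offset_deg`; sagittal somite
#' sections analogously into dorsal/ventral/anterior/posterior. Ties at
#' exact sector corners break deterministically in the order
#' dorsal > medial > ventral > lateral.
#'
#' @param outer_boundary Closed polygon (two-column matrix) enclosing every
#'   cell centroid of the section.
#' @param band_depth_px Surface band depth in pixels; `NULL` (default) uses
#'   the median minor-axis length of the cells at assignment time.
#' @param medial_side `"left"` or `"right"`: which image side faces the
#'   neural tube (anatomy cannot be inferred from pixels).
#' @param anterior_side `"left"` or `"right"` for sagittal somite sections.
#' @param angle_offset_deg Rotation of the transverse sector boundaries.
#' @param dorsal_up Orientation flag shared with [psm_axis()].
#' @return An object of class `domain_geometry`.
#' @export
domain_geometry <- function(outer_boundary, band_depth_px = NULL,
                            medial_side = c("left", "right"),
                            anterior_side = c("right", "left"),
                            angle_offset_deg = 0, dorsal_up = TRUE) {
  b <- close_polygon(outer_boundary)
  if (nrow(b) < 3) abort("outer_boundary must be a polygon.")
  structure(list(outer_boundary = b, band_depth_px = band_depth_px,
                 medial_side = match.arg(medial_side),
                 anterior_side = match.arg(anterior_side),
                 angle_offset_deg = angle_offset_deg, dorsal_up = dorsal_up,
                 center = polygon_moments(b)$centroid),
            class = "domain_geometry")
}

# Sector label for angles measured with 'up' = +90 degrees. Half-open
# 90-degree sectors; the half-open convention plus the fixed listing order
# implements the dorsal > medial > ventral > lateral corner tie-break.
transverse_sector <- function(theta_deg, medial_side) {
  th <- (theta_deg + 360) %% 360
  lab <- character(length(th))
  lab[th >= 45 & th < 135] <- "dorsal"
  lab[th >= 135 & th < 225] <- if (medial_side == "left") "medial" else "lateral"
  lab[th >= 225 & th < 315] <- "ventral"
  lab[th >= 315 | th < 45] <- if (medial_side == "left") "lateral" else "medial"
  lab
}

somite_sector <- function(theta_deg, anterior_side) {
  th <- (theta_deg + 360) %% 360
  lab <- character(length(th))
  lab[th >= 45 & th < 135] <- "dorsal"
  lab[th >= 135 & th < 225] <- if (anterior_side == "left") "anterior" else "posterior"
  lab[th >= 225 & th < 315] <- "ventral"
  lab[th >= 315 | th < 45] <- if (anterior_side == "left") "posterior" else "anterior"
  lab
}

#' Assign cells to tissue domains
#'
#' Fills the `domain` column of an outline tibble according to the section's
#' [domain_geometry()]: surface cells (outline touching the surface band)
#' are split by sector rules, everything else is core. See
#' [domain_geometry()] for the rules. Every cell receives exactly one
#' domain, so per-domain counts always partition the section.
#'
#' @param cells Outline tibble with a `vertices` list-column.
#' @param geom A [domain_geometry()].
#' @param plane `"sagittal"` or `"transverse"`. Somite cells in sagittal
#'   sections (rows with `structure == "somite"`) are sectored into
#'   dorsal/ventral/anterior/posterior/core.
#' @return The input tibble with `domain` filled.
#' @export
assign_domains <- function(cells, geom, plane = c("sagittal", "transverse")) {
  plane <- match.arg(plane)
  stopifnot(inherits(geom, "domain_geometry"))
  mom <- polygon_moments_list(cells$vertices)
  cent <- cbind(mom$cx, mom$cy)
  inside <- points_in_polygon(cent[, 1], cent[, 2], geom$outer_boundary)
  if (!all(inside)) {
    abort(sprintf("Cell centroid outside the section boundary: %s",
                  paste(cells$cell_id[!inside], collapse = ", ")))
  }
  depth <- geom$band_depth_px
  if (is.null(depth)) {
    depth <- stats::median(4 * sqrt(pmax(mom$l2, 0)))
  }
  # stack all outline vertices and test band contact in one pass
  nv <- vapply(cells$vertices, nrow, 1L)
  allv <- do.call(rbind, cells$vertices)
  vdist <- dist_to_boundary(allv[, 1], allv[, 2], geom$outer_boundary)
  min_dist <- vapply(split(vdist, rep.int(seq_len(nrow(cells)), nv)), min, 1)
  surface <- min_dist <= depth
  dx <- cent[, 1] - geom$center[1]
  dy <- cent[, 2] - geom$center[2]
  up <- if (geom$dorsal_up) -dy else dy
  theta <- atan2(up, dx) * 180 / pi - geom$angle_offset_deg
  domain <- rep("core", nrow(cells))
  if (plane == "sagittal") {
    is_som <- if ("structure" %in% names(cells)) cells$structure == "somite" else
      rep(FALSE, nrow(cells))
    sag <- surface & !is_som
    domain[sag] <- ifelse(up[sag] > 0, "dorsal", "ventral")
    som <- surface & is_som
    domain[som] <- somite_sector(theta[som], geom$anterior_side)
  } else {
    domain[surface] <- transverse_sector(theta[surface], geom$medial_side)
  }
  cells$domain <- domain
  cells
}
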