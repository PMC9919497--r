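#' Intensity slice
#'
#' Constructs a transverse optical re-slice of a polarity-marker stain: a
#' 2D intensity grid with a binary PSM cross-section mask, the slice's
#' normalized axis position, and the apical reference point (the tissue
#' centre — the side epithelializing cells face with their apical pole).
#'
#' @param grid Numeric matrix of non-negative pixel intensities (rows = y,
#'   columns = x, image convention).
#' @param psm_mask Logical matrix of the same dimension, `TRUE` inside the
#'   PSM cross-section; must be non-empty.
#' @param axis_position_percent Position of the slice along the PSM axis
#'   (0-100% PSM; above 100% = somite levels).
#' @param apical_reference `(x, y)` point marking the apical side; must lie
#'   within the mask's bounding region.
#' @param embryo_id,marker Identifiers; `marker` is one of `"GM130"`,
#'   `"PAR3"`, `"PKCzeta"`, `"ZO1"`, `"Ncad"`, `"synthetic"`.
#' @param pixel_size_um Physical pixel size.
#' @return An object of class `intensity_slice`.
#' @export
intensity_slice <- function(grid, psm_mask, axis_position_percent,
                            apical_reference, embryo_id = "unknown",
                            marker = "synthetic", pixel_size_um = 1) {
  grid <- as.matrix(grid)
  psm_mask <- as.matrix(psm_mask)
  if (!all(dim(grid) == dim(psm_mask))) {
    abort("grid and psm_mask must have identical dimensions.")
  }
  if (!any(psm_mask)) abort("psm_mask is empty.")
  if (any(grid < 0)) abort("Intensities must be non-negative.")
  if (axis_position_percent < 0 || axis_position_percent > 130) {
    abort("axis_position_percent must be in [0, 130].")
  }
  marker <- match.arg(marker,
                      c("GM130", "PAR3", "PKCzeta", "ZO1", "Ncad", "synthetic"))
  structure(list(grid = grid, psm_mask = psm_mask == TRUE,
                 axis_position_percent = axis_position_percent,
                 apical_reference = as.double(apical_reference),
                 embryo_id = embryo_id, marker = marker,
                 pixel_size_um = pixel_size_um),
            class = "intensity_slice")
}

#' @export
print.intensity_slice <- function(x, ...) {
  cat(sprintf("<intensity_slice> %s %s @ %.1f%%, %dx%d px, %d mask px\n",
              x$embryo_id, x$marker, x$axis_position_percent,
              nrow(x$grid), ncol(x$grid), sum(x$psm_mask)))
  invisible(x)
}

#' Read / write single-channel TIFF stacks
#'
#' Thin wrappers around the `tiff` package for the intensity stacks the
#' polarity module consumes. `read_intensity_stack` pairs a TIFF (one slice
#' per page) with a mask TIFF and per-slice positions.
#'
#' @param path,mask_path TIFF files (single-channel, 8/16-bit or float).
#' @param positions Numeric vector of axis positions (% PSM), one per page.
#' @param apical_reference `(x, y)` apical reference shared by all slices.
#' @param embryo_id,marker,pixel_size_um See [intensity_slice()].
#' @return A list of `intensity_slice` objects.
#' @export
read_intensity_stack <- function(path, mask_path, positions, apical_reference,
                                 embryo_id = "unknown", marker = "synthetic",
                                 pixel_size_um = 1) {
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  masks <- tiff::readTIFF(mask_path, all = TRUE, as.is = FALSE)
  if (length(imgs) != length(positions) || length(masks) != length(imgs)) {
    abort("Stack, mask stack and positions must have the same length.")
  }
  purrr::pmap(list(imgs, masks, positions), function(g, m, p) {
    intensity_slice(g, m > 0.5, p, apical_reference, embryo_id, marker,
                    pixel_size_um)
  })
}

#' @rdname read_intensity_stack
#' @param slices List of `intensity_slice` objects to write.
#' @export
write_intensity_stack <- function(slices, path, mask_path = NULL) {
  mx <- max(vapply(slices, function(s) max(s$grid), 1), 1)
  tiff::writeTIFF(lapply(slices, function(s) s$grid / mx), path,
                  bits.per.sample = 16)
  if (!is.null(mask_path)) {
    tiff::writeTIFF(lapply(slices, function(s) s$psm_mask * 1), mask_path,
                    bits.per.sample = 8)
  }
  invisible(path)
}

# Label every mask pixel of a slice with its sector and apical/basal half.
# Sectors follow the transverse rules about the apical reference; the
# apical/basal split is at the midpoint of the local band thickness,
# estimated per angular bin as (min radius + max radius) / 2 of the mask
# pixels in that bin.
split_pixels <- function(slice, geom, n_angle_bins = 72) {
  idx <- which(slice$psm_mask, arr.ind = TRUE)
  px <- idx[, 2]; py <- idx[, 1]  # columns = x, rows = y
  ax <- slice$apical_reference[1]; ay <- slice$apical_reference[2]
  dx <- px - ax
  dy <- if (geom$dorsal_up) -(py - ay) else py - ay
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) * 180 / pi - geom$angle_offset_deg
  sector <- transverse_sector(theta, geom$medial_side)
  abin <- floor(((theta + 360) %% 360) / (360 / n_angle_bins))
  mid <- tapply(r, abin, function(v) (min(v) + max(v)) / 2)
  half <- ifelse(r <= mid[as.character(abin)], "apical", "basal")
  tibble(x = px, y = py, r = r, sector = sector, half = half,
         intensity = slice$grid[idx])
}

#' Apical-minus-basal polarity quantification of one slice
#'
#' Partitions the PSM cross-section's annular surface region into the four
#' sectors (dorsal/medial/ventral/lateral, same rules as domain
#' assignment), splits each sector into an apical (inner, toward the apical
#' reference) and a basal (outer) half at the midpoint of the local band
#' thickness, and summarises pixel intensity in each half. The polarity
#' index is `delta = apical - basal`; an unpolarized marker gives delta
#' near 0, an apically concentrated marker gives delta > 0. Mean intensity
#' is used by default so delta does not scale with sector area; `stat =
#' "sum"` is available. The mesenchymal core has no apical/basal sides and
#' is never analysed.
#'
#' @param slice An [intensity_slice()].
#' @param geom A [domain_geometry()] providing sector orientation; the
#'   boundary polygon itself is not used (the mask defines the section).
#' @param stat `"mean"` (default) or `"sum"`.
#' @param apical `"inner"` (default) or `"outer"`; `"outer"` swaps the
#'   apical/basal labels, exactly negating delta (mean stat).
#' @param min_pixels Minimum pixels per half; sectors below this are
#'   dropped with a message.
#' @return Tibble with one row per retained domain: `embryo_id`, `marker`,
#'   `domain`, `axis_position_percent`, `apical_mean`, `basal_mean`,
#'   `delta`, `n_apical_px`, `n_basal_px`. Pixel-level assignments are
#'   attached as the `"pixel_assignment"` attribute.
#' @export
split_domains_apical_basal <- function(slice, geom, stat = c("mean", "sum"),
                                       apical = c("inner", "outer"),
                                       min_pixels = 10) {
  stat <- match.arg(stat)
  apical <- match.arg(apical)
  stopifnot(inherits(slice, "intensity_slice"))
  px <- split_pixels(slice, geom)
  if (apical == "outer") {
    px$half <- ifelse(px$half == "apical", "basal", "apical")
  }
  agg <- function(v) if (stat == "mean") mean(v) else sum(v)
  rows <- lapply(c("dorsal", "medial", "ventral", "lateral"), function(dom) {
    ap <- px$intensity[px$sector == dom & px$half == "apical"]
    ba <- px$intensity[px$sector == dom & px$half == "basal"]
    if (length(ap) < min_pixels || length(ba) < min_pixels) {
      inform(sprintf("Dropping domain '%s' at %.1f%%: < %d pixels per half.",
                     dom, slice$axis_position_percent, min_pixels))
      return(NULL)
    }
    tibble(embryo_id = slice$embryo_id, marker = slice$marker, domain = dom,
           axis_position_percent = slice$axis_position_percent,
           apical_mean = agg(ap), basal_mean = agg(ba),
           delta = agg(ap) - agg(ba),
           n_apical_px = length(ap), n_basal_px = length(ba))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pixel_assignment") <- px
  out
}

#' Per-domain polarity profiles
#'
#' Fits the per-domain sigmoid profile of the polarity index delta against
#' axis position — the same 4PL machinery as cell-shape profiles — and
#' extracts onset landmarks per (marker, domain).
#'
#' @param records Tibble of polarity records from
#'   [split_domains_apical_basal()] (>= 8 slices per domain).
#' @return See [fit_domain_profiles()].
#' @export
polarity_profile <- function(records) {
  fit_domain_profiles(records, response = "delta",
                      position = "axis_position_percent",
                      by = c("marker", "domain"))
}
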