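#' Ground-truth parameters for synthetic data
#'
#' Assembles the parameter set that fully determines the synthetic inputs:
#' per-domain 4PL parameters for the aspect-ratio profile, a per-marker
#' per-domain truth table for polarity onsets, the core AR distribution,
#' noise levels, sample sizes and the time-lapse model. Defaults encode the
#' study conditions the pipeline is meant to recover: elongation onsets at
#' 40% (dorsal), 55% (medial) and 70% (ventral = lateral) of PSM length
#' with a mesenchymal core of constant mean AR; marker-specific
#' polarization orderings (e.g. PKC-zeta dorsal at 40% but lateral only at
#' the forming somite; ZO1 ventral only after budding); and a biphasic
#' advection profile breaking at 10 h with a 68 min somite interval.
#' Lognormal multiplicative AR noise (sigma 0.15) keeps AR >= a and
#' right-skewed, matching real per-cell scatter.
#'
#' @param ar_profiles Tibble (`domain`, `a`, `b`, `x0`, `k`) of AR truth
#'   per surface domain.
#' @param core_ar_mean Mean AR of core (never-epithelializing) cells.
#' @param ar_sigma Lognormal sigma of the multiplicative AR noise.
#' @param marker_profiles Tibble (`marker`, `domain`, `a`, `b`, `x0`, `k`)
#'   of polarity-delta truth.
#' @param intensity_baseline,intensity_sigma Baseline intensity and
#'   additive Gaussian pixel noise of synthetic slices.
#' @param cells_per_domain,slices Sample sizes.
#' @param timelapse List: `breakpoint_h`, `slow_rate`, `fast_rate` (% PSM
#'   per hour), `interval_min`, `duration_min`, `dt_min`, `psm_len0_um`,
#'   `psm_shrink_um_per_min`, `somite_len_um`, `noise_sigma_frac` (front
#'   noise as a fraction of PSM length).
#' @param cell_minor_px,n_vertices Synthetic cell size and polygon
#'   resolution.
#' @param seed Default RNG seed for the generators.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(
    ar_profiles = tibble(
      domain = c("dorsal", "medial", "ventral", "lateral"),
      a = 1.5, b = 6, x0 = c(40, 55, 70, 70), k = 0.3),
    core_ar_mean = 2.2,
    ar_sigma = 0.15,
    marker_profiles = default_marker_truth(),
    intensity_baseline = 20,
    intensity_sigma = 3,
    cells_per_domain = 600,
    slices = 40,
    timelapse = list(breakpoint_h = 10, slow_rate = 1, fast_rate = 6,
                     interval_min = 68, duration_min = 1440, dt_min = 20,
                     psm_len0_um = 2000, psm_shrink_um_per_min = 0.2,
                     somite_len_um = 100, noise_sigma_frac = 0.03),
    cell_minor_px = 10,
    n_vertices = 24,
    seed = 1) {
  stopifnot(ar_sigma >= 0, intensity_sigma >= 0,
            timelapse$noise_sigma_frac >= 0, cells_per_domain >= 1)
  structure(list(ar_profiles = ar_profiles, core_ar_mean = core_ar_mean,
                 ar_sigma = ar_sigma, marker_profiles = marker_profiles,
                 intensity_baseline = intensity_baseline,
                 intensity_sigma = intensity_sigma,
                 cells_per_domain = cells_per_domain, slices = slices,
                 timelapse = timelapse, cell_minor_px = cell_minor_px,
                 n_vertices = n_vertices, seed = seed),
            class = "synthetic_truth")
}

#' Default per-marker polarization truth table
#'
#' Onset positions (% PSM) per marker and domain for the synthetic
#' intensity stacks, encoding the characteristic orderings of the five
#' polarity markers: each marker polarizes each PSM surface at its own
#' axial level and rate, and the order differs from the elongation order.
#' Values above 100% place the onset at somite levels (after budding).
#'
#' @return Tibble with columns `marker`, `domain`, `a`, `b`, `x0`, `k`.
#' @export
default_marker_truth <- function() {
  tab <- rbind(
    data.frame(marker = "PKCzeta",
               domain = c("dorsal", "ventral", "medial", "lateral"),
               x0 = c(40, 50, 65, 100), k = c(0.3, 0.3, 0.3, 0.8)),
    data.frame(marker = "PAR3",
               domain = c("lateral", "ventral", "medial", "dorsal"),
               x0 = c(50, 60, 70, 80), k = c(0.15, 0.15, 0.15, 0.3)),
    data.frame(marker = "ZO1",
               domain = c("dorsal", "medial", "lateral", "ventral"),
               x0 = c(70, 90, 100, 110), k = c(0.3, 0.3, 0.3, 0.3)),
    data.frame(marker = "GM130",
               domain = c("ventral", "medial", "dorsal", "lateral"),
               x0 = c(60, 60, 80, 95), k = c(0.3, 0.3, 0.3, 0.3)),
    data.frame(marker = "Ncad",
               domain = c("dorsal", "medial", "ventral", "lateral"),
               x0 = c(60, 90, 90, 90), k = c(0.3, 0.5, 0.5, 0.5)))
  as_tibble(cbind(tab[, c("marker", "domain")], a = 0, b = 30,
                  tab[, c("x0", "k")]))
}

# Sagittal synthetic section geometry (pixels).
sag_geom <- function(truth) {
  list(length_px = 1000, height_px = 300, margin = truth$cell_minor_px)
}

#' Generate a synthetic cell-outline field
#'
#' Draws a field of synthetic cells with known per-domain elongation truth:
#' positions uniform on 0-100% of the PSM, aspect ratios drawn as
#' `sigmoid(position; domain truth) * lognormal(ar_sigma)` for surface
#' domains and constant-mean lognormal for the core, and 24-vertex ellipse
#' polygons placed so that surface cells touch the section's surface band
#' (oriented tangentially) and core cells lie in the interior. Sagittal
#' fields use the dorsal/ventral/core domains on a straight rectangular
#' strip (so straightening is the identity on normalized x); transverse
#' fields use dorsal/medial/ventral/lateral/core on a ring section, with
#' each cell's axis position carried as a label.
#'
#' The matching [psm_axis()] (sagittal) and [domain_geometry()] are
#' attached as attributes, and the generating truth as `"truth"`. Output is
#' deterministic given `seed`.
#'
#' @param truth A [synthetic_truth()].
#' @param plane `"sagittal"` or `"transverse"`.
#' @param seed RNG seed (default `truth$seed`).
#' @param cells_per_domain Override of `truth$cells_per_domain`.
#' @return An outline tibble (see [read_outlines()]) with extra truth
#'   columns `domain_true`, `position_true`, `ar_true`.
#' @export
generate_outline_field <- function(truth = synthetic_truth(),
                                   plane = c("sagittal", "transverse"),
                                   seed = truth$seed,
                                   cells_per_domain = truth$cells_per_domain) {
  plane <- match.arg(plane)
  with_seed(seed, {
    domains <- if (plane == "sagittal") c("dorsal", "ventral", "core") else
      c("dorsal", "medial", "ventral", "lateral", "core")
    rows <- lapply(domains, function(dom) {
      n <- cells_per_domain
      pos <- runif(n, 0, 100)
      ar_true <- if (dom == "core") {
        rep(truth$core_ar_mean, n)
      } else {
        p <- truth$ar_profiles[truth$ar_profiles$domain == dom, ]
        sigmoid4(pos, p$a, p$b, p$x0, p$k)
      }
      ar <- ar_true * exp(rnorm(n, 0, truth$ar_sigma))
      tibble(domain_true = dom, position_true = pos, ar_true = ar)
    })
    cells <- dplyr::bind_rows(rows)
    n <- nrow(cells)
    minor <- truth$cell_minor_px
    if (plane == "sagittal") {
      g <- sag_geom(truth)
      x <- cells$position_true / 100 * (g$length_px - 2 * g$margin) + g$margin
      half_major <- cells$ar_true * minor / 2
      y <- numeric(n); theta <- numeric(n)
      d <- cells$domain_true == "dorsal"
      v <- cells$domain_true == "ventral"
      co <- cells$domain_true == "core"
      y[d] <- minor / 2 + runif(sum(d), 0, minor / 4)
      y[v] <- g$height_px - minor / 2 - runif(sum(v), 0, minor / 4)
      # keep core outlines clear of the surface band whatever their tilt
      y[co] <- runif(sum(co), 4 * minor, g$height_px - 4 * minor)
      theta[d | v] <- 0                      # tangent to the surface
      theta[co] <- runif(sum(co), 0, pi)
    } else {
      R <- 150; cx0 <- 160; cy0 <- 160
      ang <- numeric(n); rad <- numeric(n)
      sector_range <- list(dorsal = c(50, 130), medial = c(140, 220),
                           ventral = c(230, 310), lateral = c(-40, 40))
      for (dom in names(sector_range)) {
        i <- cells$domain_true == dom
        ang[i] <- runif(sum(i), sector_range[[dom]][1], sector_range[[dom]][2])
      }
      co <- cells$domain_true == "core"
      ang[co] <- runif(sum(co), 0, 360)
      rad[!co] <- R - minor / 2
      rad[co] <- sqrt(runif(sum(co))) * (R - 4 * minor)
      x <- cx0 + rad * cos(ang * pi / 180)
      y <- cy0 - rad * sin(ang * pi / 180)   # image y grows downward
      theta <- numeric(n)
      theta[!co] <- (-ang[!co] + 90) * pi / 180  # tangent to the ring
      theta[co] <- runif(sum(co), 0, pi)
    }
    verts <- lapply(seq_len(n), function(i) {
      ellipse_polygon(x[i], y[i], cells$ar_true[i] * minor, minor, theta[i],
                      truth$n_vertices)
    })
    out <- tibble(
      cell_id = sprintf("cell%04d", seq_len(n)),
      embryo_id = "synthetic1", plane = plane, structure = "psm",
      domain = "unassigned", somite_index = NA_integer_,
      vertices = verts,
      domain_true = cells$domain_true,
      position_true = cells$position_true,
      ar_true = cells$ar_true,
      centroid_x = x, centroid_y = y)
    attr(out, "truth") <- truth
    if (plane == "sagittal") {
      g <- sag_geom(truth)
      attr(out, "axis") <- psm_axis(cbind(c(g$margin, g$length_px - g$margin),
                                          c(g$height_px / 2, g$height_px / 2)))
      # the boundary extends past the strip ends in x so that end cells
      # are classified by their dorso-ventral side, not by the cut edge
      attr(out, "geometry") <- domain_geometry(
        cbind(c(-50, g$length_px + 50, g$length_px + 50, -50),
              c(0, 0, g$height_px, g$height_px)),
        band_depth_px = 1.5 * truth$cell_minor_px)
    } else {
      th <- seq(0, 2 * pi, length.out = 73)[-73]
      attr(out, "geometry") <- domain_geometry(
        cbind(160 + 155 * cos(th), 160 - 155 * sin(th)),
        band_depth_px = 1.5 * truth$cell_minor_px)
    }
    out
  })
}

#' Generate a synthetic polarity-marker stack
#'
#' Builds a stack of transverse intensity slices with known polarization
#' truth: each slice is a ring-shaped PSM mask on a square grid, pixel
#' intensities are a constant baseline plus Gaussian noise, and the
#' marker's per-domain delta (from the truth table, evaluated at the
#' slice's axis position) is added to the apical (inner) half of each
#' sector's band. Slice positions are evenly spaced over 0-120% so onsets
#' at somite levels are covered. Deterministic given `seed`.
#'
#' @param truth A [synthetic_truth()].
#' @param marker Marker name present in `truth$marker_profiles`.
#' @param seed RNG seed (default `truth$seed`).
#' @param grid_px,r_outer,r_inner Slice raster geometry (pixels).
#' @return A list of [intensity_slice()] objects; the generating truth and
#'   the matching [domain_geometry()] are attached as attributes.
#' @export
generate_intensity_stack <- function(truth = synthetic_truth(),
                                     marker = "PKCzeta",
                                     seed = truth$seed,
                                     grid_px = 96, r_outer = 40,
                                     r_inner = 26) {
  prof <- truth$marker_profiles[truth$marker_profiles$marker == marker, ]
  if (!nrow(prof)) abort(sprintf("No truth profile for marker '%s'.", marker))
  ctr <- (grid_px + 1) / 2
  xs <- matrix(rep(seq_len(grid_px), each = grid_px), grid_px)   # column = x
  ys <- matrix(rep(seq_len(grid_px), times = grid_px), grid_px)  # row = y
  dx <- xs - ctr; dy <- -(ys - ctr)
  r <- sqrt(dx^2 + dy^2)
  mask <- r >= r_inner & r <= r_outer
  sector <- matrix(transverse_sector(atan2(dy, dx) * 180 / pi, "left"),
                   grid_px)
  apical_half <- mask & r <= (r_inner + r_outer) / 2
  positions <- seq(0, 120, length.out = truth$slices)
  with_seed(seed, {
    slices <- lapply(positions, function(pp) {
      g <- matrix(truth$intensity_baseline +
                    rnorm(grid_px^2, 0, truth$intensity_sigma), grid_px)
      for (i in seq_len(nrow(prof))) {
        dlt <- sigmoid4(pp, prof$a[i], prof$b[i], prof$x0[i], prof$k[i])
        sel <- apical_half & sector == prof$domain[i]
        g[sel] <- g[sel] + dlt
      }
      g[g < 0] <- 0
      intensity_slice(g, mask, pp, c(ctr, ctr), embryo_id = "synthetic1",
                      marker = marker)
    })
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    attr(slices, "geometry") <- domain_geometry(
      cbind(ctr + (r_outer + 2) * cos(th), ctr - (r_outer + 2) * sin(th)))
    attr(slices, "truth") <- truth
    slices
  })
}

#' Generate a synthetic DiI time-lapse track
#'
#' Emulates a time-lapse distance table: the somite count increments every
#' `interval_min`; the PSM length shrinks slowly and linearly; the DiI
#' front advances along the PSM with the biphasic profile (slow rate until
#' `breakpoint_h`, then the fast constant rate), and the front-to-border
#' distance is the remaining fraction of the concurrent PSM length plus
#' Gaussian noise (`noise_sigma_frac` of PSM length). Deterministic given
#' `seed`.
#'
#' @param truth A [synthetic_truth()].
#' @param seed RNG seed (default `truth$seed`).
#' @param duration_min,noise_sigma_frac Overrides of the truth's time-lapse
#'   settings.
#' @return A timepoint tibble (see [read_timelapse()]).
#' @export
generate_timelapse <- function(truth = synthetic_truth(),
                               seed = truth$seed,
                               duration_min = truth$timelapse$duration_min,
                               noise_sigma_frac = truth$timelapse$noise_sigma_frac) {
  tl <- truth$timelapse
  t_min <- seq(0, duration_min, by = tl$dt_min)
  th <- t_min / 60
  pos <- ifelse(th <= tl$breakpoint_h,
                tl$slow_rate * th,
                tl$slow_rate * tl$breakpoint_h +
                  tl$fast_rate * (th - tl$breakpoint_h))
  pos <- pmin(pos, 100)
  L <- tl$psm_len0_um - tl$psm_shrink_um_per_min * t_min
  stopifnot(all(L > 0))
  with_seed(seed, {
    noise <- rnorm(length(t_min), 0, noise_sigma_frac * L)
    dii <- pmin(pmax(L * (1 - pos / 100) + noise, 0), L)  # front stays in the PSM
    count <- floor(t_min / tl$interval_min)
    tibble(t_minutes = t_min,
           segmented_length_um = L + count * tl$somite_len_um,
           dii_front_to_border_um = dii,
           psm_length_um = L,
           somite_count = as.integer(count))
  })
}

#' Write a complete synthetic fixture directory
#'
#' Emits every synthetic input family to disk with its ground truth:
#' outline CSVs (both planes), an ImageJ ROI-zip of the sagittal field, a
#' TIFF stack plus mask per marker, the time-lapse CSV and a YAML truth
#' summary — a self-contained fixture set for exercising the full pipeline
#' from files.
#'
#' @param dir Output directory (created if needed).
#' @param truth A [synthetic_truth()].
#' @param markers Markers to emit stacks for.
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixtures <- function(dir, truth = synthetic_truth(),
                                     markers = "PKCzeta") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sag <- generate_outline_field(truth, "sagittal")
  tra <- generate_outline_field(truth, "transverse")
  write_outlines(sag, file.path(dir, "outlines_sagittal.csv"), "csv")
  write_outlines(tra, file.path(dir, "outlines_transverse.csv"), "csv")
  sag_int <- sag
  sag_int$vertices <- lapply(sag$vertices, round)
  write_outlines(sag_int, file.path(dir, "outlines_sagittal_roi.zip"), "roi_zip")
  for (m in markers) {
    st <- generate_intensity_stack(truth, m)
    write_intensity_stack(
      st, file.path(dir, sprintf("stack_%s.tif", m)),
      file.path(dir, sprintf("stack_%s_mask.tif", m)))
  }
  write_timelapse(generate_timelapse(truth), file.path(dir, "timelapse.csv"))
  yaml::write_yaml(list(
    ar_profiles = as.data.frame(truth$ar_profiles),
    core_ar_mean = truth$core_ar_mean, ar_sigma = truth$ar_sigma,
    timelapse = truth$timelapse, seed = truth$seed),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}
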