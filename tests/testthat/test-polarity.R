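# A disc/ring slice with controllable intensity, reused across tests.
ring_slice <- function(value = 10, grid_px = 64, r_in = 0, r_out = 26,
                       pos = 50) {
  ctr <- (grid_px + 1) / 2
  xs <- matrix(rep(seq_len(grid_px), each = grid_px), grid_px)
  ys <- matrix(rep(seq_len(grid_px), times = grid_px), grid_px)
  r <- sqrt((xs - ctr)^2 + (ys - ctr)^2)
  mask <- r >= r_in & r <= r_out
  intensity_slice(matrix(value, grid_px, grid_px), mask, pos, c(ctr, ctr))
}

ring_geom <- function() {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  domain_geometry(cbind(32.5 + 30 * cos(th), 32.5 - 30 * sin(th)))
}

test_that("a uniform disc has zero delta in all four domains", {
  rec <- split_domains_apical_basal(ring_slice(value = 7), ring_geom())
  expect_equal(nrow(rec), 4L)
  expect_setequal(rec$domain, c("dorsal", "medial", "ventral", "lateral"))
  expect_equal(rec$delta, rep(0, 4))
  expect_equal(rec$apical_mean, rep(7, 4))
})

test_that("doubling the apical half raises delta by exactly the base intensity", {
  base <- 10
  sl <- ring_slice(value = base, r_in = 14, r_out = 26)
  geom <- ring_geom()
  px <- attr(split_domains_apical_basal(sl, geom), "pixel_assignment")
  g2 <- sl$grid
  ap <- px[px$half == "apical", ]
  g2[cbind(ap$y, ap$x)] <- 2 * base
  sl2 <- intensity_slice(g2, sl$psm_mask, sl$axis_position_percent,
                         sl$apical_reference)
  rec <- split_domains_apical_basal(sl2, geom)
  expect_equal(rec$delta, rep(base, 4))
})

test_that("delta is invariant under constant background addition", {
  sl <- ring_slice(value = 5, r_in = 14, r_out = 26)
  geom <- ring_geom()
  set.seed(4)
  g <- sl$grid + matrix(runif(64 * 64, 0, 3), 64)  # arbitrary texture
  s1 <- intensity_slice(g, sl$psm_mask, 50, sl$apical_reference)
  s2 <- intensity_slice(g + 100, sl$psm_mask, 50, sl$apical_reference)
  r1 <- split_domains_apical_basal(s1, geom)
  r2 <- split_domains_apical_basal(s2, geom)
  expect_equal(r2$delta, r1$delta)
  expect_equal(r2$apical_mean, r1$apical_mean + 100)
})

test_that("swapping the apical and basal labels negates delta exactly", {
  sl <- ring_slice(value = 5, r_in = 14, r_out = 26)
  geom <- ring_geom()
  set.seed(9)
  g <- sl$grid + matrix(runif(64 * 64, 0, 4), 64)
  s <- intensity_slice(g, sl$psm_mask, 50, sl$apical_reference)
  inner <- split_domains_apical_basal(s, geom, apical = "inner")
  outer <- split_domains_apical_basal(s, geom, apical = "outer")
  expect_equal(outer$delta, -inner$delta)
})

test_that("apical and basal pixels together partition the sector band", {
  sl <- ring_slice(value = 5, r_in = 14, r_out = 26)
  rec <- split_domains_apical_basal(sl, ring_geom())
  px <- attr(rec, "pixel_assignment")
  expect_equal(sum(rec$n_apical_px) + sum(rec$n_basal_px), sum(sl$psm_mask))
  expect_equal(nrow(px), sum(sl$psm_mask))
})

test_that("undersized sector halves are dropped with a message", {
  # a sliver mask: only a few pixels on the dorsal side
  g <- matrix(1, 64, 64)
  m <- matrix(FALSE, 64, 64)
  m[6:8, 31:34] <- TRUE
  sl <- intensity_slice(g, m, 50, c(32.5, 32.5))
  expect_message(rec <- split_domains_apical_basal(sl, ring_geom()), "pixels")
  expect_lt(nrow(rec), 4)
})

test_that("noiseless polarity stacks recover the programmed onset", {
  tr <- quiet_truth(slices = 30)
  tr$marker_profiles <- tibble::tibble(marker = "synthetic", domain = "dorsal",
                                       a = 0, b = 30, x0 = 70, k = 0.3)
  st <- generate_intensity_stack(tr, "synthetic")
  geom <- attr(st, "geometry")
  recs <- dplyr::bind_rows(lapply(st, split_domains_apical_basal, geom = geom))
  prof <- polarity_profile(recs)
  dors <- prof[prof$domain == "dorsal", ]
  expect_equal(dors$x0, 70, tolerance = 0.5)
  # untouched sectors stay flat: fitted or flagged, their p is large
  rest <- prof[prof$domain != "dorsal", ]
  expect_true(all(rest$p_value > 0.5 | rest$flag == "no_sigmoid"))
})

test_that("zero-delta domains come out flat", {
  tr <- quiet_truth(slices = 20)
  tr$marker_profiles <- tibble::tibble(marker = "synthetic", domain = "dorsal",
                                       a = 0, b = 0, x0 = 50, k = 0.3)
  st <- generate_intensity_stack(tr, "synthetic")
  geom <- attr(st, "geometry")
  recs <- dplyr::bind_rows(lapply(st, split_domains_apical_basal, geom = geom))
  prof <- polarity_profile(recs)
  expect_true(all(prof$flag == "no_sigmoid" | prof$p_value > 0.9))
})

test_that("the five-marker default panel recovers each marker's onset ordering", {
  tr <- quiet_truth(slices = 25)
  geom <- NULL
  for (mk in unique(tr$marker_profiles$marker)) {
    st <- generate_intensity_stack(tr, mk)
    geom <- attr(st, "geometry")
    recs <- dplyr::bind_rows(lapply(st, split_domains_apical_basal, geom = geom))
    prof <- polarity_profile(recs)
    truth <- tr$marker_profiles[tr$marker_profiles$marker == mk, ]
    m <- merge(as.data.frame(prof[, c("domain", "x0")]),
               as.data.frame(truth[, c("domain", "x0")]),
               by = "domain", suffixes = c("_hat", "_true"))
    expect_equal(rank(m$x0_hat), rank(m$x0_true),
                 label = sprintf("onset ranks for %s", mk))
  }
})

test_that("intensity stacks survive a TIFF round trip", {
  tr <- quiet_truth(slices = 8)
  tr$marker_profiles <- tibble::tibble(marker = "synthetic", domain = "dorsal",
                                       a = 0, b = 30, x0 = 60, k = 0.3)
  st <- generate_intensity_stack(tr, "synthetic", grid_px = 48,
                                 r_outer = 20, r_inner = 13)
  tf <- withr::local_tempfile(fileext = ".tif")
  mf <- withr::local_tempfile(fileext = ".tif")
  write_intensity_stack(st, tf, mf)
  back <- read_intensity_stack(tf, mf,
                               positions = vapply(st, `[[`, 1, "axis_position_percent"),
                               apical_reference = st[[1]]$apical_reference)
  expect_equal(length(back), length(st))
  expect_equal(back[[3]]$psm_mask, st[[3]]$psm_mask)
  # 16-bit quantisation: intensities preserved up to scale within 2^-15
  sc <- max(vapply(st, function(s) max(s$grid), 1))  # the writer's scale
  expect_equal(back[[3]]$grid * sc, st[[3]]$grid, tolerance = 1e-4)
})
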