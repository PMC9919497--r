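cell_tbl <- function(cx, cy) {
  tibble::tibble(cell_id = paste0("c", seq_along(cx)),
                 centroid_x = cx, centroid_y = cy)
}

test_that("straightening a straight horizontal midline is linear in x", {
  ax <- psm_axis(cbind(c(0, 1000), c(100, 100)))
  s <- straighten(cell_tbl(440, 80), ax)
  expect_equal(s$position_percent, 44)
  expect_gt(s$transverse_offset_px, 0)   # above the midline = dorsal
  s2 <- straighten(cell_tbl(440, 120), ax)
  expect_lt(s2$transverse_offset_px, 0)
})

test_that("the posterior tip maps to 0% even on a bent midline", {
  bent <- psm_axis(cbind(c(0, 500, 500), c(0, 0, 500)))
  s <- straighten(cell_tbl(0, 0), bent)
  expect_equal(s$position_percent, 0)
})

test_that("positions on a curved midline match the dense-projection oracle", {
  phi <- seq(0, pi / 3, length.out = 60)
  mid <- cbind(800 * sin(phi), 800 * (1 - cos(phi)))
  ax <- psm_axis(mid)
  set.seed(7)
  t0 <- runif(200, 0.02, 0.98) * pi / 3
  off <- runif(200, -40, 40)
  # radial offset from the arc's centre keeps the true foot at angle t0
  px <- (800 + off) * sin(t0)
  py <- 800 - (800 + off) * cos(t0)
  got <- straighten(cell_tbl(px, py), ax)$position_percent
  want <- dense_position(px, py, mid)
  expect_lt(max(abs(got - want)), 0.2)
})

test_that("normalized position is invariant under rigid motion of the section", {
  phi <- seq(0, pi / 3, length.out = 40)
  mid <- cbind(800 * sin(phi), 800 * (1 - cos(phi)))
  set.seed(8)
  px <- 800 * sin(runif(50, 0.05, 0.95) * pi / 3) + runif(50, -30, 30)
  py <- 800 * (1 - cos(runif(50, 0.05, 0.95) * pi / 3)) + runif(50, -30, 30)
  base <- straighten(cell_tbl(px, py), psm_axis(mid))$position_percent
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(310, -77)
  midr <- sweep(t(R %*% t(mid)), 2, -shift)
  ptsr <- sweep(t(R %*% t(cbind(px, py))), 2, -shift)
  rot <- straighten(cell_tbl(ptsr[, 1], ptsr[, 2]), psm_axis(midr))$position_percent
  expect_equal(rot, base, tolerance = 1e-9)
})

test_that("somite cells are placed rostral of the border by somite index", {
  ax <- psm_axis(cbind(c(0, 1000), c(100, 100)))
  cells <- tibble::tibble(
    cell_id = c("p1", "s1"), structure = c("psm", "somite"),
    somite_index = c(NA_integer_, 2L),
    centroid_x = c(500, 990), centroid_y = c(90, 90))
  s <- straighten(cells, ax)
  expect_equal(s$position_percent, c(50, 120))
})

test_that("domain assignment partitions the section and recovers generator truth", {
  field <- generate_outline_field(synthetic_truth(), "transverse", seed = 21,
                                  cells_per_domain = 15)  # 60 surface + 15 core
  geom <- attr(field, "geometry")
  got <- assign_domains(field, geom, "transverse")
  expect_setequal(unique(got$domain),
                  c("dorsal", "medial", "ventral", "lateral", "core"))
  expect_equal(sum(table(got$domain)), nrow(field))   # partition
  expect_gte(mean(got$domain == got$domain_true), 0.95)
})

test_that("a lone central cell is core; a strip-edge cell is dorsal", {
  geom <- domain_geometry(cbind(c(0, 400, 400, 0), c(0, 0, 300, 300)),
                          band_depth_px = 15)
  mk <- function(id, cx, cy) tibble::tibble(
    cell_id = id, embryo_id = "e", plane = "sagittal", structure = "psm",
    domain = "unassigned", somite_index = NA_integer_,
    vertices = list(psmet:::ellipse_polygon(cx, cy, 20, 10, 0)))
  expect_equal(assign_domains(mk("mid", 200, 150), geom, "sagittal")$domain,
               "core")
  expect_equal(assign_domains(mk("top", 200, 8), geom, "sagittal")$domain,
               "dorsal")
  expect_equal(assign_domains(mk("bot", 200, 292), geom, "sagittal")$domain,
               "ventral")
})

test_that("cells outside the section boundary are an error", {
  geom <- domain_geometry(cbind(c(0, 400, 400, 0), c(0, 0, 300, 300)))
  bad <- tibble::tibble(
    cell_id = "out", embryo_id = "e", plane = "sagittal", structure = "psm",
    domain = "unassigned", somite_index = NA_integer_,
    vertices = list(psmet:::ellipse_polygon(600, 150, 20, 10, 0)))
  expect_error(assign_domains(bad, geom, "sagittal"), "out")
})

test_that("sagittal somite cells get the four somite sectors about the centroid", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  geom <- domain_geometry(cbind(200 + 120 * cos(th), 150 - 120 * sin(th)),
                          band_depth_px = 20, anterior_side = "right")
  mk <- function(id, cx, cy) tibble::tibble(
    cell_id = id, embryo_id = "e", plane = "sagittal", structure = "somite",
    domain = "unassigned", somite_index = 1L,
    vertices = list(psmet:::ellipse_polygon(cx, cy, 16, 8, 0)))
  expect_equal(assign_domains(mk("d", 200, 45), geom, "sagittal")$domain,
               "dorsal")
  expect_equal(assign_domains(mk("v", 200, 255), geom, "sagittal")$domain,
               "ventral")
  expect_equal(assign_domains(mk("a", 310, 150), geom, "sagittal")$domain,
               "anterior")
  expect_equal(assign_domains(mk("p", 90, 150), geom, "sagittal")$domain,
               "posterior")
})
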