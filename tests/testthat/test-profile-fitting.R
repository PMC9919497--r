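test_that("noiseless 4PL data is recovered to machine-level accuracy", {
  x <- seq(0, 100, length.out = 50)
  y <- psmet:::sigmoid4(x, 1, 7, 50, 0.3)
  f <- fit_sigmoid(tibble::tibble(position_percent = x, response = y))
  expect_equal(f$a, 1, tolerance = 1e-6)
  expect_equal(f$b, 7, tolerance = 1e-6)
  expect_equal(f$x0, 50, tolerance = 1e-6)
  expect_equal(f$k, 0.3, tolerance = 1e-6)
  expect_equal(f$flag, "ok")
})

test_that("a constant response falls back to the flat model", {
  x <- seq(0, 100, length.out = 50)
  f <- fit_sigmoid(tibble::tibble(position_percent = x, response = rep(2, 50)))
  expect_equal(f$flag, "no_sigmoid")
  expect_equal(f$b - f$a, 0)
  expect_error(landmarks(f), "no_sigmoid")
})

test_that("preconditions on sample size and span are enforced", {
  expect_error(fit_sigmoid(position = 1:7, response = rnorm(7)), "8")
  expect_error(fit_sigmoid(position = seq(40, 60, length.out = 20),
                           response = rnorm(20)), "span")
})

test_that("the 10%-height landmark has the stated closed form", {
  f <- structure(list(a = 1, b = 7, x0 = 50, k = 0.2, rss = 1, rss_flat = 10,
                      n = 50, flag = "ok"), class = "sigmoid_fit")
  lmk <- landmarks(f)
  expect_equal(lmk$x_inflection, 50)
  expect_equal(lmk$x_height10, 50 - log(9) / 0.2)
  expect_equal(round(lmk$x_height10, 3), 39.014)
  # near-step limit: the 10% point collapses onto the inflection
  fs <- structure(list(a = 0, b = 1, x0 = 50, k = 100, rss = 1,
                       rss_flat = 10, n = 50, flag = "ok"),
                  class = "sigmoid_fit")
  expect_equal(landmarks(fs)$x_height10, 50, tolerance = 0.05)
})

test_that("closed-form landmark agrees with numeric root finding", {
  grid <- expand.grid(a = c(0, 1.5), b = c(5, 30), x0 = c(30, 55, 70),
                      k = c(0.1, 0.3, 0.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    target <- g$a + 0.1 * (g$b - g$a)
    root <- uniroot(function(x) psmet:::sigmoid4(x, g$a, g$b, g$x0, g$k) - target,
                    c(g$x0 - 2000 / (100 * g$k), g$x0), tol = 1e-12)$root
    expect_equal(g$x0 - log(9) / g$k, root, tolerance = 1e-8)
  }
})

test_that("decreasing profiles are flagged and keep b >= a", {
  x <- seq(0, 100, length.out = 60)
  set.seed(5)
  # k < 0 with b > a: high caudally, dropping to the lower asymptote
  y <- psmet:::sigmoid4(x, 1.5, 6, 50, -0.3) + rnorm(60, 0, 0.05)
  f <- fit_sigmoid(tibble::tibble(position_percent = x, response = y))
  expect_equal(f$flag, "decreasing")
  expect_gte(f$b, f$a)
  expect_lt(f$k, 0)
  lmk <- landmarks(f)
  expect_equal(lmk$flag, "decreasing")
  expect_gt(lmk$x_height10, lmk$x_inflection)  # on the decreasing branch
})

test_that("group comparisons report both tests with Holm never below raw p", {
  set.seed(11)
  null_tbl <- tibble::tibble(
    domain = rep(c("dorsal", "ventral", "core"), each = 30),
    bin = rep(c(40, 70), times = 45),
    aspect_ratio = rnorm(90, 3, 0.5))
  cmp <- compare_groups(null_tbl, "between_domains_within_bin")
  expect_true(all(cmp$p_t_holm >= cmp$p_t))
  expect_true(all(cmp$p_wilcoxon_holm >= cmp$p_wilcoxon))
  expect_true(all(cmp$n1 >= 3 & cmp$n2 >= 3))
})

test_that("well-separated groups are detected with overwhelming evidence", {
  set.seed(12)
  tbl <- tibble::tibble(
    domain = rep(c("dorsal", "core"), each = 30),
    bin = 50,
    aspect_ratio = c(rnorm(30, 6, 0.5), rnorm(30, 2, 0.5)))
  cmp <- compare_groups(tbl, "between_domains_within_bin")
  expect_lt(cmp$p_t, 1e-10)
  expect_lt(cmp$p_wilcoxon, 1e-10)
})

test_that("identical groups give a Wilcoxon p of 1", {
  vals <- rep(c(1.8, 2.2, 3.1, 4.4, 5.0), 4)
  tbl <- tibble::tibble(
    side = rep(c("left", "right"), each = 20),
    aspect_ratio = c(vals, vals))  # right is a copy of left
  cmp <- compare_groups(tbl, "left_vs_right")
  expect_equal(cmp$p_wilcoxon, 1)
})

test_that("undersized groups are skipped with a message, not an error", {
  tbl <- tibble::tibble(
    domain = c(rep("dorsal", 10), rep("lateral", 2)),
    bin = 50,
    aspect_ratio = rnorm(12, 3))
  expect_message(cmp <- compare_groups(tbl, "between_domains_within_bin"),
                 "too small")
  expect_equal(nrow(cmp), 0L)
})

test_that("binned summaries follow the box-plot conventions", {
  tbl <- tibble::tibble(domain = "dorsal", position_percent = rep(50, 5),
                        aspect_ratio = 1:5)
  s <- binned_boxplot_summary(tbl, bin_centers = 50, bin_halfwidth = 10)
  expect_equal(s$median, 3)
  expect_equal(s$q3 - s$q1, 2)
  expect_equal(s$n, 5L)

  # a value exactly on the shared edge of two touching bins -> lower bin
  tbl2 <- tibble::tibble(domain = "dorsal",
                         position_percent = c(10, 15, 20),
                         aspect_ratio = c(1, 2, 3))
  s2 <- binned_boxplot_summary(tbl2, bin_centers = c(10, 20), bin_halfwidth = 5)
  expect_equal(s2$n[s2$bin == 10], 2L)
  expect_equal(s2$n[s2$bin == 20], 1L)
  expect_error(binned_boxplot_summary(tbl2, c(10, 15), 5), "overlap")
})

test_that("binned medians rise along the axis for surface domains only", {
  field <- generate_outline_field(synthetic_truth(), "transverse", seed = 31,
                                  cells_per_domain = 300)
  ar <- aspect_ratio(field)
  ar$position_percent <- field$position_true
  ar$domain <- field$domain_true
  s <- binned_boxplot_summary(ar, bin_centers = c(20, 85), bin_halfwidth = 15)
  for (dom in c("dorsal", "medial", "ventral", "lateral")) {
    lo <- s$median[s$domain == dom & s$bin == 20]
    hi <- s$median[s$domain == dom & s$bin == 85]
    expect_gt(hi, lo)
  }
  core <- s[s$domain == "core", ]
  expect_lt(abs(core$median[core$bin == 85] - core$median[core$bin == 20]), 0.3)
})

test_that("axial and somite comparison designs produce the right contrasts", {
  set.seed(21)
  axial <- tibble::tibble(
    domain = rep(c("dorsal", "core"), each = 40),
    bin = rep(rep(c(30, 80), each = 20), times = 2),
    aspect_ratio = c(rnorm(20, 2, 0.3), rnorm(20, 5.5, 0.5),   # dorsal rises
                     rnorm(40, 2.2, 0.3)))                     # core flat
  cmp <- compare_groups(axial, "same_domain_across_bins")
  expect_setequal(cmp$strata, c("dorsal", "core"))
  expect_lt(cmp$p_t[cmp$strata == "dorsal"], 1e-10)
  expect_gt(cmp$p_t[cmp$strata == "core"], 0.01)

  som <- tibble::tibble(
    domain = rep(c("anterior", "posterior"), each = 30),
    somite_index = rep(rep(1:2, each = 15), times = 2),
    aspect_ratio = c(rnorm(30, 2.5, 0.4), rnorm(15, 2.6, 0.4),
                     rnorm(15, 5.5, 0.4)))  # s2 posterior has elongated cells
  cmp2 <- compare_groups(som, "anterior_vs_posterior")
  expect_equal(sort(cmp2$strata), c("1", "2"))
  expect_gt(cmp2$p_wilcoxon[cmp2$strata == "1"], 0.05)
  expect_lt(cmp2$p_wilcoxon[cmp2$strata == "2"], 1e-4)
})
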