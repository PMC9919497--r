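#' Tidy a sigmoid fit
#'
#' broom-style methods for `sigmoid_fit` objects: `tidy()` returns the 4PL
#' parameter estimates, `glance()` a one-row model summary including the
#' onset landmarks and the sigmoid-vs-flat F test, and `augment()` the data
#' with fitted values and residuals.
#'
#' @param x,object A `sigmoid_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = c("a", "b", "x0", "k"),
         estimate = c(x$a, x$b, x$x0, x$k))
}

#' @rdname tidy.sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  lmk <- if (x$flag == "no_sigmoid") {
    tibble(x_inflection = NA_real_, x_height10 = NA_real_,
           f_statistic = 0, p_value = 1, flag = "no_sigmoid")
  } else {
    landmarks(x)
  }
  dplyr::bind_cols(
    tibble(a = x$a, b = x$b, x0 = x$x0, k = x$k,
           rss = x$rss, rss_flat = x$rss_flat, n = x$n),
    lmk)
}

#' @rdname tidy.sigmoid_fit
#' @export
augment.sigmoid_fit <- function(x, ...) {
  d <- x$data
  d$.fitted <- predict.sigmoid_fit(x)
  d$.resid <- d$response - d$.fitted
  d
}

#' Tidy a position-to-time map
#'
#' `tidy()` returns the fitted advection parameters as term/estimate rows;
#' `glance()` a one-row summary of the two-phase fit.
#'
#' @param x A `position_time_map`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.position_time_map <- function(x, ...) {
  tibble(term = c("breakpoint_h", "slow_phase_rate", "fast_phase_rate",
                  "t100_h"),
         estimate = c(x$breakpoint_h, x$slow_phase_rate, x$fast_phase_rate,
                      x$t100_h))
}

#' @rdname tidy.position_time_map
#' @export
glance.position_time_map <- function(x, ...) {
  tibble(breakpoint_h = x$breakpoint_h, slow_phase_rate = x$slow_phase_rate,
         fast_phase_rate = x$fast_phase_rate, t100_h = x$t100_h,
         single_phase = x$single_phase, f_statistic = x$f_statistic,
         p_value = x$p_value, n = nrow(x$data))
}

#' Tidy a somite formation rate
#'
#' `tidy()` returns the per-embryo intervals; `glance()` the cohort
#' summary.
#'
#' @param x A `somite_rate`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.somite_rate <- function(x, ...) x$per_embryo

#' @rdname tidy.somite_rate
#' @export
glance.somite_rate <- function(x, ...) {
  tibble(n_embryos = nrow(x$per_embryo),
         mean_interval_min = x$mean_interval_min,
         interval_min = x$interval_min)
}
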