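#' Somite formation interval
#'
#' Computes the per-embryo somite formation interval (duration divided by
#' somites formed) and the cohort mean interval, reported to the nearest
#' minute at cohort level. Embryos with zero somites are excluded with a
#' warning.
#'
#' @param tracks Data frame with columns `somites_formed` and
#'   `duration_min` (one row per embryo; an `embryo_id` column is used if
#'   present).
#' @return An object of class `somite_rate`: `$per_embryo` (tibble with
#'   `interval_min` per embryo), `$mean_interval_min` (full precision) and
#'   `$interval_min` (cohort mean rounded to the nearest minute).
#' @examples
#' somite_interval(data.frame(somites_formed = c(28, 27),
#'                            duration_min = c(2050, 1690)))$interval_min  # 68
#' @export
somite_interval <- function(tracks) {
  tracks <- as_tibble(tracks)
  if (!all(c("somites_formed", "duration_min") %in% names(tracks))) {
    abort("tracks needs columns somites_formed and duration_min.")
  }
  if (!"embryo_id" %in% names(tracks)) {
    tracks$embryo_id <- paste0("embryo", seq_len(nrow(tracks)))
  }
  if (any(tracks$duration_min <= 0)) abort("duration_min must be positive.")
  zero <- tracks$somites_formed < 1
  if (any(zero)) {
    warn(sprintf("Excluding %d embryo(s) with zero somites formed.", sum(zero)))
    tracks <- tracks[!zero, ]
  }
  if (!nrow(tracks)) abort("No embryos with somites formed.")
  per <- tracks |>
    dplyr::mutate(interval_min = .data$duration_min / .data$somites_formed) |>
    dplyr::select(dplyr::all_of(c("embryo_id", "somites_formed",
                                  "duration_min", "interval_min")))
  m <- mean(per$interval_min)
  structure(list(per_embryo = per, mean_interval_min = m,
                 interval_min = round(m)),
            class = "somite_rate")
}

#' @export
print.somite_rate <- function(x, ...) {
  cat(sprintf("<somite_rate> %d embryo(s), mean interval %d min/somite\n",
              nrow(x$per_embryo), x$interval_min))
  invisible(x)
}

#' Fit the position-to-time map from a DiI time-lapse track
#'
#' Converts a time-lapse track into a map from normalized PSM position to
#' developmental time. The DiI-front-to-border distance is normalized by
#' the concurrent PSM length into a position percentage
#' (`100 * (1 - d / L)`), then fitted with a continuous two-segment
#' piecewise-linear model of position against time — cells first advance
#' slowly along the PSM, then speed up at a constant rate. The breakpoint
#' is chosen by exhaustive grid search over the observed timepoints
#' (minimum RSS), and the two-segment model is accepted only if it beats
#' the single line in a nested F test (2 extra parameters, alpha = 0.05);
#' otherwise a single-phase map is returned, flagged.
#'
#' @param track Timepoint tibble (see [read_timelapse()]), >= 10 points
#'   spanning both phases.
#' @param alpha Significance level for the two-segment vs one-segment test.
#' @param normalize If `FALSE`, fit raw micrometre distances (converted to
#'   percent of the final PSM length) instead of per-timepoint
#'   normalization.
#' @return An object of class `position_time_map`: phase rates (% PSM per
#'   hour), `breakpoint_h`, the fitted trajectory, and the time at which
#'   the front reaches the border (`t100_h`), from which remaining time is
#'   measured.
#' @seealso [position_to_time()]
#' @export
fit_position_time <- function(track, alpha = 0.05, normalize = TRUE) {
  track <- validate_timelapse(as_tibble(track))
  if (nrow(track) < 10) abort("Need >= 10 timepoints to fit both phases.")
  th <- track$t_minutes / 60
  pos <- if (normalize) {
    100 * (1 - track$dii_front_to_border_um / track$psm_length_um)
  } else {
    100 * (1 - track$dii_front_to_border_um /
             track$psm_length_um[nrow(track)])
  }
  keep <- pos <= 100 + 1e-9
  th <- th[keep]; pos <- pos[keep]
  n <- length(th)
  fit1 <- lm(pos ~ th)
  rss1 <- sum(residuals(fit1)^2)
  cand <- th[3:(n - 2)]
  best <- NULL
  for (cc in cand) {
    f <- lm(pos ~ th + pmax(th - cc, 0))
    rss <- sum(residuals(f)^2)
    if (is.null(best) || rss < best$rss) best <- list(c = cc, fit = f, rss = rss)
  }
  fstat <- ((rss1 - best$rss) / 2) / (best$rss / (n - 4))
  if (!is.finite(fstat)) {
    # degenerate noiseless cases: 0/0 means the single line already fits
    fstat <- if (rss1 - best$rss > 1e-12 * max(rss1, 1)) Inf else 0
  }
  p <- pf(fstat, 2, n - 4, lower.tail = FALSE)
  single <- p >= alpha
  if (single) {
    cf <- coef(fit1)
    map <- list(breakpoint_h = NA_real_, slow_phase_rate = unname(cf[2]),
                fast_phase_rate = unname(cf[2]),
                intercept = unname(cf[1]), single_phase = TRUE)
  } else {
    cf <- coef(best$fit)
    map <- list(breakpoint_h = best$c, slow_phase_rate = unname(cf[2]),
                fast_phase_rate = unname(cf[2] + cf[3]),
                intercept = unname(cf[1]), single_phase = FALSE)
  }
  pos_at <- function(t) {
    if (map$single_phase) {
      map$intercept + map$slow_phase_rate * t
    } else {
      map$intercept + map$slow_phase_rate * t +
        (map$fast_phase_rate - map$slow_phase_rate) * pmax(t - map$breakpoint_h, 0)
    }
  }
  if (map$fast_phase_rate <= 0) {
    abort("Fitted advection rate is not positive; cannot invert the trajectory.")
  }
  # time at which the fitted front reaches the border (position = 100%)
  t100 <- if (!map$single_phase && pos_at(map$breakpoint_h) < 100) {
    map$breakpoint_h + (100 - pos_at(map$breakpoint_h)) / map$fast_phase_rate
  } else {
    (100 - map$intercept) / map$slow_phase_rate
  }
  structure(c(map, list(
    t100_h = t100, pos_at = pos_at,
    f_statistic = fstat, p_value = p,
    t_range_h = range(th), pos_range = range(pos),
    data = tibble(t_h = th, position_percent = pos,
                  fitted = pos_at(th)))),
    class = "position_time_map")
}

#' @export
print.position_time_map <- function(x, ...) {
  if (x$single_phase) {
    cat(sprintf("<position_time_map> single phase, %.2f %%PSM/h\n",
                x$slow_phase_rate))
  } else {
    cat(sprintf(
      "<position_time_map> breakpoint %.2f h; %.2f then %.2f %%PSM/h\n",
      x$breakpoint_h, x$slow_phase_rate, x$fast_phase_rate))
  }
  invisible(x)
}

#' Translate PSM position into remaining developmental time
#'
#' Inverts the fitted advection trajectory to express a PSM position as
#' hours remaining before that material reaches the forming-somite border:
#' `position_to_time(map, 100)` is 0 h by construction and the remaining
#' time decreases monotonically as position approaches 100%. Positions
#' outside the track's observed position range are still evaluated on the
#' fitted model but flagged as extrapolated.
#'
#' @param map A [fit_position_time()] map.
#' @param position_percent Numeric vector of positions in `[0, 100]`.
#' @return Tibble: `position_percent`, `hours_before_border`,
#'   `extrapolated`.
#' @export
position_to_time <- function(map, position_percent) {
  stopifnot(inherits(map, "position_time_map"))
  p <- position_percent
  if (any(p < 0 | p > 100)) abort("position_percent must be in [0, 100].")
  # invert the piecewise-linear trajectory (strictly increasing)
  t_at <- function(pp) {
    if (map$single_phase) {
      (pp - map$intercept) / map$slow_phase_rate
    } else {
      pb <- map$pos_at(map$breakpoint_h)
      ifelse(pp <= pb,
             (pp - map$intercept) / map$slow_phase_rate,
             map$breakpoint_h + (pp - pb) / map$fast_phase_rate)
    }
  }
  hrs <- map$t100_h - t_at(p)
  extr <- p < map$pos_range[1] | p > map$pos_range[2]
  tibble(position_percent = p, hours_before_border = hrs,
         extrapolated = extr)
}

#' Annotate onset landmarks with developmental time
#'
#' Adds, for each fitted onset landmark, the approximate time (hours before
#' the material reaches the forming-somite border) at which the onset
#' occurs, using a position-to-time map. Landmarks beyond 100% (somite
#' levels) are clamped to 0 h remaining.
#'
#' @param profiles Output of [fit_domain_profiles()] or
#'   [polarity_profile()].
#' @param map A [fit_position_time()] map.
#' @return `profiles` with `t_inflection_h` and `t_height10_h` columns.
#' @export
annotate_landmark_times <- function(profiles, map) {
  clamp <- function(p) pmin(pmax(p, 0), 100)
  t_of <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    if (any(ok)) {
      out[ok] <- position_to_time(map, clamp(p[ok]))$hours_before_border
    }
    out
  }
  profiles$t_inflection_h <- t_of(profiles$x_inflection)
  profiles$t_height10_h <- t_of(profiles$x_height10)
  profiles
}
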