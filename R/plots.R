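#' Plot a fitted sigmoid profile
#'
#' Scatter of the observations with the fitted 4PL curve and the two onset
#' landmarks: the inflection point (diamond) and the 10%-of-height point
#' (square).
#'
#' @param object A `sigmoid_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  d <- object$data
  xx <- seq(min(d$position_percent), max(d$position_percent), length.out = 200)
  curve <- tibble(position_percent = xx,
                  response = predict.sigmoid_fit(object, xx))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$position_percent, .data$response)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = "PSM distance [%]", y = "response")
  if (object$flag != "no_sigmoid") {
    lmk <- landmarks(object)
    pts <- tibble(
      position_percent = c(lmk$x_inflection, lmk$x_height10),
      response = predict.sigmoid_fit(
        object, c(lmk$x_inflection, lmk$x_height10)),
      landmark = c("inflection", "10% height"))
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(shape = .data$landmark), size = 3,
      colour = "blue") +
      ggplot2::scale_shape_manual(values = c("inflection" = 18,
                                             "10% height" = 15))
  }
  p
}

#' Per-domain profile panel
#'
#' Scatter + fitted curves for each group of a [fit_domain_profiles()] /
#' [polarity_profile()] result, faceted by the grouping columns.
#'
#' @param profiles Output of [fit_domain_profiles()].
#' @param ncol Facet columns.
#' @return A ggplot.
#' @export
plot_profiles <- function(profiles, ncol = 2) {
  by <- setdiff(names(profiles),
                c("a", "b", "x0", "k", "rss", "n", "x_inflection",
                  "x_height10", "f_statistic", "p_value", "flag", "fit",
                  "t_inflection_h", "t_height10_h"))
  pieces <- lapply(seq_len(nrow(profiles)), function(i) {
    f <- profiles$fit[[i]]
    d <- f$data
    d$group <- paste(unlist(profiles[i, by]), collapse = " / ")
    xx <- seq(min(d$position_percent), max(d$position_percent),
              length.out = 200)
    list(points = d,
         curve = tibble(position_percent = xx,
                        response = predict.sigmoid_fit(f, xx),
                        group = d$group[1]))
  })
  pts <- dplyr::bind_rows(lapply(pieces, `[[`, "points"))
  crv <- dplyr::bind_rows(lapply(pieces, `[[`, "curve"))
  ggplot2::ggplot(pts, ggplot2::aes(.data$position_percent, .data$response)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7) +
    ggplot2::geom_line(data = crv, colour = "red") +
    ggplot2::facet_wrap(~group, ncol = ncol, scales = "free_y") +
    ggplot2::labs(x = "PSM distance [%]", y = "response")
}

#' Binned box plot of a response per domain
#'
#' Renders a [binned_boxplot_summary()] as box-and-whisker glyphs per
#' domain along the axis.
#'
#' @param summary Output of [binned_boxplot_summary()].
#' @return A ggplot.
#' @export
plot_binned_boxes <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = factor(.data$bin),
                                        fill = .data$domain)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_low, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_high),
      stat = "identity", position = ggplot2::position_dodge(0.8),
      width = 0.7) +
    ggplot2::labs(x = "PSM distance bin [%]", y = "response")
}

#' Plot a position-to-time map
#'
#' The normalized DiI-front trajectory (position vs time) with the fitted
#' two-segment model and its breakpoint.
#'
#' @param object A `position_time_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.position_time_map <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$t_h, .data$position_percent)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time [h]", y = "PSM position [%]")
  if (!object$single_phase) {
    p <- p + ggplot2::geom_vline(xintercept = object$breakpoint_h,
                                 linetype = 2)
  }
  p
}

#' Colour-coded outline map
#'
#' Draws cell outlines filled by their pseudo-colour AR bin — the section
#' overview used to eyeball where elongation begins.
#'
#' @param outlines Outline tibble.
#' @param ar Per-cell tibble from [aspect_ratio()] (matched by `cell_id`).
#' @param breaks Pseudo-colour breaks (see [ar_colormap()]).
#' @return A ggplot.
#' @export
plot_outline_map <- function(outlines, ar, breaks = 1:7) {
  ar$ar_bin <- factor(ar_colormap(ar$aspect_ratio, breaks))
  polys <- dplyr::bind_rows(lapply(seq_len(nrow(outlines)), function(i) {
    v <- outlines$vertices[[i]]
    tibble(cell_id = outlines$cell_id[i], x = v[, 1], y = v[, 2])
  }))
  polys <- dplyr::left_join(polys, ar[, c("cell_id", "ar_bin")], by = "cell_id")
  ggplot2::ggplot(polys, ggplot2::aes(.data$x, .data$y, group = .data$cell_id,
                                      fill = .data$ar_bin)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "AR bin")
}
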