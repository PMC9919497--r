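sigmoid4 <- function(x, a, b, x0, k) a + (b - a) / (1 + exp(-k * (x - x0)))

#' Fit a four-parameter logistic profile
#'
#' Least-squares fit of the four-parameter logistic (4PL)
#' `y = a + (b - a) / (1 + exp(-k (x - x0)))` to a response (aspect ratio or
#' polarity-index delta) against normalized axis position. `a` and `b` are
#' the lower/upper asymptotes in response units, `x0` the inflection
#' position in % PSM, and `k` the slope in response-units per percentage
#' point. Fitting uses Levenberg-Marquardt from a fixed multi-start grid
#' (`x0` in 25/50/75%, `k` in 0.05/0.2/0.5, asymptotes from the 5th/95th
#' response percentiles, fixed order, no randomness) and keeps the
#' best-RSS converged fit, so the result is deterministic given the data.
#' Decreasing profiles remain reachable (the optimiser may cross `k = 0`,
#' and the 4PL is invariant under swapping the asymptotes with `k -> -k`);
#' such fits are reported with `b >= a` and `k < 0`, flagged
#' `"decreasing"`. If no start converges, a flat fallback
#' (`a = b = mean(y)`) is returned, flagged `"no_sigmoid"`.
#'
#' @param data Data frame of observations, or `NULL` if `position` and
#'   `response` are passed as vectors.
#' @param position,response Column names (character) when `data` is given,
#'   otherwise numeric vectors.
#' @return An object of class `sigmoid_fit`: parameters, `rss`, the flat
#'   (constant-mean) model's `rss_flat`, `n`, a `flag`
#'   (`"ok"`/`"decreasing"`/`"no_sigmoid"`) and the data.
#' @seealso [landmarks()], [fit_domain_profiles()], [tidy.sigmoid_fit()]
#' @export
fit_sigmoid <- function(data = NULL, position = "position_percent",
                        response = "response") {
  if (is.data.frame(data)) {
    x <- data[[position]]; y <- data[[response]]
  } else {
    x <- position; y <- response
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8) abort("Sigmoid fitting needs at least 8 observations.")
  if (diff(range(x)) < 30) {
    abort("Positions must span at least 30 percentage points.")
  }
  ybar <- mean(y)
  rss_flat <- sum((y - ybar)^2)
  a0 <- unname(quantile(y, 0.05)); b0 <- unname(quantile(y, 0.95))
  if (b0 - a0 < 1e-12) b0 <- a0 + max(1e-6, abs(a0) * 1e-6)
  starts <- expand.grid(x0 = c(25, 50, 75), k = c(0.05, 0.2, 0.5))
  df <- data.frame(x = x, y = y)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a + (b - a) / (1 + exp(-k * (x - x0))), data = df,
        start = list(a = a0, b = b0, x0 = starts$x0[i], k = starts$k[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(par = as.list(coef(fit)), rss = rss)
    }
  }
  if (is.null(best)) {
    out <- list(a = ybar, b = ybar, x0 = NA_real_, k = NA_real_,
                rss = rss_flat, rss_flat = rss_flat, n = n,
                flag = "no_sigmoid",
                data = tibble(position_percent = x, response = y))
    return(structure(out, class = "sigmoid_fit"))
  }
  p <- best$par
  # canonical orientation: report b >= a (the 4PL is invariant under
  # swapping (a, b) with k -> -k)
  if (p$b < p$a) {
    tmp <- p$a; p$a <- p$b; p$b <- tmp; p$k <- -p$k
  }
  flag <- if (p$k > 0) "ok" else "decreasing"
  structure(list(a = p$a, b = p$b, x0 = p$x0, k = p$k, rss = best$rss,
                 rss_flat = rss_flat, n = n, flag = flag,
                 data = tibble(position_percent = x, response = y)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> a=%.3g b=%.3g x0=%.3g k=%.3g  rss=%.3g n=%d [%s]\n",
    x$a, x$b, x$x0, x$k, x$rss, x$n, x$flag))
  invisible(x)
}

#' Predict from a sigmoid fit
#' @param object A `sigmoid_fit`.
#' @param newdata Optional numeric vector of positions.
#' @param ... Unused.
#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$data$position_percent
  if (object$flag == "no_sigmoid") return(rep(object$a, length(x)))
  sigmoid4(x, object$a, object$b, object$x0, object$k)
}

#' Onset landmarks of a fitted profile
#'
#' Extracts the two onset landmarks of a fitted 4PL profile — the
#' inflection position `x0` and the position at 10% of the curve's vertical
#' height, which under the 4PL has the closed form
#' `x_height10 = x0 - log(9) / k` — and tests the sigmoid against the
#' constant-mean model with a nested F test:
#' `F = ((RSS_flat - RSS_sig) / 3) / (RSS_sig / (n - 4))`, with p from
#' `F(3, n - 4)`. A flat profile (core cells) yields p near 1; a genuine
#' onset yields a small p. Fits with `k <= 0` are reported on the
#' decreasing branch and flagged.
#'
#' @param fit A `sigmoid_fit` not flagged `"no_sigmoid"`.
#' @return A one-row tibble: `x_inflection`, `x_height10`, `f_statistic`,
#'   `p_value`, `flag`.
#' @export
landmarks <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (fit$flag == "no_sigmoid") {
    abort("Fit is flagged 'no_sigmoid'; landmarks are undefined.")
  }
  x10 <- fit$x0 - log(9) / fit$k
  fstat <- ((fit$rss_flat - fit$rss) / 3) / (fit$rss / (fit$n - 4))
  fstat <- max(fstat, 0)
  p <- pf(fstat, 3, fit$n - 4, lower.tail = FALSE)
  tibble(x_inflection = fit$x0, x_height10 = x10,
         f_statistic = fstat, p_value = p, flag = fit$flag)
}

#' Fit per-domain profiles with landmarks
#'
#' Convenience wrapper running [fit_sigmoid()] and [landmarks()] for each
#' domain (and optionally each marker) of a per-cell or per-slice table.
#' Core cells are expected to come out flat (large p); surface domains to
#' show an onset whose `x0` orders dorsal < medial < ventral/lateral for
#' cell elongation.
#'
#' @param data Table with at least a grouping column, a position column and
#'   a response column.
#' @param response,position,by Column names; `by` may name several grouping
#'   columns (default `"domain"`).
#' @return A tibble with one row per group: 4PL parameters, landmarks, fit
#'   diagnostics and a `fit` list-column of `sigmoid_fit` objects.
#' @export
fit_domain_profiles <- function(data, response = "aspect_ratio",
                                position = "position_percent",
                                by = "domain") {
  groups <- unique(data[by])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(data))
    for (col in by) sel <- sel & data[[col]] == groups[[col]][i]
    d <- data[sel, ]
    fit <- fit_sigmoid(d, position = position, response = response)
    lm_row <- if (fit$flag == "no_sigmoid") {
      tibble(x_inflection = NA_real_, x_height10 = NA_real_,
             f_statistic = 0, p_value = 1, flag = "no_sigmoid")
    } else {
      landmarks(fit)
    }
    dplyr::bind_cols(groups[i, , drop = FALSE],
                     tibble(a = fit$a, b = fit$b, x0 = fit$x0, k = fit$k,
                            rss = fit$rss, n = fit$n),
                     lm_row, tibble(fit = list(fit)))
  })
  dplyr::bind_rows(rows)
}

#' Pairwise group comparisons
#'
#' Runs the comparison designs used for per-domain cell statistics: Welch's
#' two-sided t test and the Wilcoxon rank-sum test for every contrast,
#' reporting group sizes, statistics, raw p values and Holm-adjusted p
#' values (adjustment across all contrasts of the table; raw p is always
#' kept alongside).
#'
#' Designs and the columns they require:
#' * `between_domains_within_bin`: all domain pairs within each `bin`
#'   (columns `domain`, `bin`).
#' * `same_domain_across_bins`: all bin pairs within each `domain`.
#' * `left_vs_right`: left vs right `side` within each `bin` (column
#'   `side`; `bin` optional).
#' * `anterior_vs_posterior`: anterior vs posterior `domain` within each
#'   `somite_index`.
#'
#' Contrasts with fewer than 3 observations in either group are skipped
#' with a message.
#'
#' @param data Per-cell table.
#' @param design One of the four design names above.
#' @param response Response column (default `"aspect_ratio"`).
#' @return Tibble of contrasts: strata, groups, `n1`, `n2`, `t_statistic`,
#'   `p_t`, `p_t_holm`, `w_statistic`, `p_wilcoxon`, `p_wilcoxon_holm`.
#' @export
compare_groups <- function(data,
                           design = c("between_domains_within_bin",
                                      "same_domain_across_bins",
                                      "left_vs_right",
                                      "anterior_vs_posterior"),
                           response = "aspect_ratio") {
  design <- match.arg(design)
  need <- function(cols) {
    miss <- setdiff(cols, names(data))
    if (length(miss)) abort(sprintf("Design '%s' needs column(s): %s",
                                    design, paste(miss, collapse = ", ")))
  }
  contrasts <- switch(design,
    between_domains_within_bin = {
      need(c("domain", "bin"))
      do.call(rbind, lapply(unique(data$bin), function(b) {
        doms <- sort(unique(data$domain[data$bin == b]))
        if (length(doms) < 2) return(NULL)
        cbind(strata = as.character(b), t(utils::combn(doms, 2)))
      }))
    },
    same_domain_across_bins = {
      need(c("domain", "bin"))
      do.call(rbind, lapply(unique(data$domain), function(d) {
        bins <- sort(unique(data$bin[data$domain == d]))
        if (length(bins) < 2) return(NULL)
        cbind(strata = as.character(d), t(utils::combn(as.character(bins), 2)))
      }))
    },
    left_vs_right = {
      need("side")
      strata <- if ("bin" %in% names(data)) unique(as.character(data$bin)) else "all"
      cbind(strata = strata, "left", "right")
    },
    anterior_vs_posterior = {
      need(c("domain", "somite_index"))
      s <- sort(unique(data$somite_index[data$domain %in% c("anterior", "posterior")]))
      if (!length(s)) NULL else cbind(strata = as.character(s), "anterior", "posterior")
    })
  if (is.null(contrasts) || nrow(contrasts) == 0) {
    abort("No contrasts available for this design on the given table.")
  }
  bin_chr <- if ("bin" %in% names(data)) as.character(data$bin) else
    rep("all", nrow(data))
  pick <- function(strata, grp) {
    sel <- switch(design,
      between_domains_within_bin = bin_chr == strata & data$domain == grp,
      same_domain_across_bins = data$domain == strata & bin_chr == grp,
      left_vs_right = (strata == "all" | bin_chr == strata) &
        data$side == grp,
      anterior_vs_posterior = as.character(data$somite_index) == strata &
        data$domain == grp)
    data[[response]][sel & !is.na(data[[response]])]
  }
  rows <- lapply(seq_len(nrow(contrasts)), function(i) {
    g1 <- pick(contrasts[i, 1], contrasts[i, 2])
    g2 <- pick(contrasts[i, 1], contrasts[i, 3])
    if (length(g1) < 3 || length(g2) < 3) {
      inform(sprintf("Skipping contrast %s: %s vs %s (group too small).",
                     contrasts[i, 1], contrasts[i, 2], contrasts[i, 3]))
      return(NULL)
    }
    tt <- t.test(g1, g2, var.equal = FALSE)
    wt <- suppressWarnings(wilcox.test(g1, g2, exact = FALSE))
    tibble(strata = unname(contrasts[i, 1]), group1 = unname(contrasts[i, 2]),
           group2 = unname(contrasts[i, 3]), n1 = length(g1), n2 = length(g2),
           t_statistic = unname(tt$statistic), p_t = tt$p.value,
           w_statistic = unname(wt$statistic), p_wilcoxon = wt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$p_t_holm <- p.adjust(out$p_t, method = "holm")
    out$p_wilcoxon_holm <- p.adjust(out$p_wilcoxon, method = "holm")
  }
  out
}

#' Binned box-plot summary
#'
#' Summarises a response per domain in position bins centred on
#' `bin_centers` with half-width `bin_halfwidth`, as used for box plots of
#' AR per domain versus PSM distance in transverse sections. Bin intervals
#' are closed; a value exactly on a shared edge of two touching bins is
#' assigned to the lower bin.
#'
#' @param data Per-cell table with `domain`, a position column and a
#'   response column.
#' @param bin_centers Numeric centres (% PSM); bins must not overlap.
#' @param bin_halfwidth Half-width of each bin (%).
#' @param response,position Column names.
#' @return Tibble per (domain, bin): `n`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high` (1.5 IQR rule) and `n_outliers`.
#' @export
binned_boxplot_summary <- function(data, bin_centers, bin_halfwidth,
                                   response = "aspect_ratio",
                                   position = "position_percent") {
  bc <- sort(bin_centers)
  if (any(diff(bc) < 2 * bin_halfwidth - 1e-9)) {
    abort("Bins overlap: centres must be at least 2 * halfwidth apart.")
  }
  x <- data[[position]]
  bin <- rep(NA_real_, length(x))
  for (ctr in bc) {  # ascending: a shared edge lands in the lower bin
    hit <- is.na(bin) & x >= ctr - bin_halfwidth & x <= ctr + bin_halfwidth
    bin[hit] <- ctr
  }
  d <- tibble(domain = data$domain, bin = bin, y = data[[response]])
  d <- d[!is.na(d$bin) & !is.na(d$y), ]
  box_stats <- function(y) {
    q <- unname(stats::quantile(y, c(0.25, 0.5, 0.75)))
    iqr <- q[3] - q[1]
    lo <- min(y[y >= q[1] - 1.5 * iqr])
    hi <- max(y[y <= q[3] + 1.5 * iqr])
    tibble(n = length(y), median = q[2], q1 = q[1], q3 = q[3],
           whisker_low = lo, whisker_high = hi,
           n_outliers = sum(y < lo | y > hi))
  }
  d |>
    dplyr::group_by(.data$domain, .data$bin) |>
    dplyr::reframe(box_stats(.data$y)) |>
    dplyr::ungroup()
}
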