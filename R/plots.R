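#' Plot a log-binned void-area distribution
#'
#' Log-log frequency plot of enclosed-void sizes, one line per condition
#' when a `condition` column (or attribute) is present — the standard view
#' in which a power-law tail appears as a straight line.
#'
#' @param object A `binned_distribution`, a `void_area_set`, or a data
#'   frame with `area_cm2` (and optionally `condition`) columns.
#' @param bins_per_decade Used when `object` still needs binning.
#' @param normalized Plot density (default) or raw counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_distribution <- function(object, normalized = TRUE, ...) {
  df <- dplyr::filter(as_tibble(object), .data$count > 0)
  yvar <- if (normalized) "density" else "count"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data[[yvar]])) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "enclosed area (cm²)",
                  y = if (normalized) "density" else "frequency")
}

#' @rdname autoplot.binned_distribution
#' @export
autoplot.void_area_set <- function(object, bins_per_decade = 5,
                                   normalized = TRUE, ...) {
  autoplot(log_binned_frequency(object, bins_per_decade), normalized = normalized)
}

#' Plot void-area distributions per condition
#'
#' @param areas Data frame with `area_cm2` and `condition` columns (areas
#'   pooled per growth condition).
#' @param bins_per_decade Bins per decade (default 5).
#' @param normalized Density (default) or counts.
#' @return A ggplot object.
#' @export
plot_void_distributions <- function(areas, bins_per_decade = 5,
                                    normalized = TRUE) {
  stopifnot(all(c("condition", "area_cm2") %in% names(areas)))
  df <- purrr::imap_dfr(
    split(areas$area_cm2, areas$condition),
    function(x, cond) {
      dplyr::mutate(as_tibble(log_binned_frequency(x, bins_per_decade)),
                    condition = cond)
    }
  )
  df <- dplyr::filter(df, .data$count > 0)
  yvar <- if (normalized) "density" else "count"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data[[yvar]],
                                   colour = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "enclosed area (cm²)",
                  y = if (normalized) "density" else "frequency",
                  colour = "condition")
}

#' Plot a simulated or observed relative-humidity series
#'
#' @param object An `rh_series` tibble (from [simulate_humidity()]) or any
#'   data frame with `time_d`/`time_h` and `rh_percent` columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rh_series <- function(object, ...) {
  df <- as_tibble(object)
  if (!"time_d" %in% names(df) && "time_h" %in% names(df)) {
    df$time_d <- df$time_h / 24
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_d, y = .data$rh_percent)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "relative humidity (%)") +
    ggplot2::coord_cartesian(ylim = c(0, 100))
}

#' Plot group phenotype summaries with confidence intervals
#'
#' @param summary Output of [summarize_by_group()].
#' @return A ggplot object: mean and 95% CI per group, facetted by
#'   phenotype.
#' @export
plot_group_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.2
    ) +
    ggplot2::facet_wrap(~phenotype, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Display a root mask
#'
#' @param x A [root_mask()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.root_mask <- function(x, ...) {
  nr <- nrow(x$grid)
  graphics::image(
    x = (seq_len(ncol(x$grid)) - 1) * x$pixel_size,
    y = (seq_len(nr) - 1) * x$pixel_size,
    z = t(x$grid[nr:1, ]) * 1,
    col = c("white", "black"), asp = 1, xlab = "mm", ylab = "mm",
    main = x$source_id, ...
  )
  invisible(x)
}
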