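#' Plot directional wave power over time
#'
#' Line plot of mean forward/backward wave power (dB) against window center
#' time, one line per direction, facetted by axis (and band when several
#' are present). Zero dB — parity with the segment's mean temporal power —
#' is drawn as the reference line.
#'
#' @param df long tibble from [compute_wave_power()].
#' @return A ggplot object.
#' @export
plot_wave_timecourse <- function(df) {
  keys <- intersect(c("time", "direction", "axis", "band"), names(df))
  summ <- df %>%
    group_by(across(all_of(keys))) %>%
    summarise(power_db = mean(.data$power_db), .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$time,
                                          y = .data$power_db,
                                          colour = .data$direction)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from display onset (s)",
                  y = "wave power (dB)", colour = NULL) +
    ggplot2::theme_minimal()
  facets <- intersect(c("axis", "band"), keys)
  if (length(facets)) {
    p <- p + ggplot2::facet_grid(rows = if ("band" %in% facets &&
                                            length(unique(summ$band)) > 1)
      ggplot2::vars(.data$band) else NULL,
      cols = if ("axis" %in% facets) ggplot2::vars(.data$axis) else NULL)
  }
  p
}

#' Plot condition-cell means
#'
#' Bar plot of condition-cell values (participant means with standard
#' errors) against a condition factor, split by direction.
#'
#' @param cells condition-cell tibble from [aggregate_trials()].
#' @param factor condition column to put on the x axis.
#' @return A ggplot object.
#' @export
plot_condition_cells <- function(cells, factor) {
  summ <- cells %>%
    group_by(.data[[factor]], .data$direction) %>%
    summarise(m = mean(.data$value),
              se = sd(.data$value) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = base::factor(.data[[factor]]),
                                     y = .data$m,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$se,
                                        ymax = .data$m + .data$se),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.2) +
    ggplot2::labs(x = factor, y = "wave power (dB)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname timecourse_bf
#' @param object a `bf_timecourse` tibble.
#' @param ... unused.
#' @export
autoplot.bf_timecourse <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 3
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$bf10)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$exceeds)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time from display onset (s)",
                  y = "BF10 (contra vs ipsi)",
                  colour = sprintf("BF10 > %g", thr)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
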