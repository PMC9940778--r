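#' Plot baseline-relative mobility trends by channel
#'
#' Line plot of relative mobility change per wave for each channel (optionally
#' restricted to one subgroup), with an optional stringency-index ribbon in the
#' background — the standard trends view for a channel comparison.
#'
#' @param panel Aligned panel from [run_pipeline()] /
#'   [relative_change_from_baseline()] with columns `week_start`,
#'   `rel_change_pct`, `channel` and optionally `subgroup`.
#' @param subgroup Subgroup label to plot (default `"population"` when a
#'   `subgroup` column is present).
#' @param stringency Optional tibble `date`, `stringency` drawn as a scaled
#'   background area.
#' @return A ggplot object.
#' @export
plot_trends <- function(panel, subgroup = "population", stringency = NULL) {
  if ("subgroup" %in% names(panel))
    panel <- dplyr::filter(panel, .data$subgroup == !!subgroup)
  p <- ggplot2::ggplot(panel, ggplot2::aes(.data$week_start, .data$rel_change_pct,
                                           colour = .data$channel))
  if (!is.null(stringency)) {
    rng <- range(panel$rel_change_pct, na.rm = TRUE)
    s <- dplyr::mutate(stringency,
                       scaled = rng[1] + .data$stringency / 100 * diff(rng))
    p <- p + ggplot2::geom_area(data = s,
                                ggplot2::aes(.data$date, .data$scaled),
                                inherit.aes = FALSE, fill = "grey85")
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "Mobility change vs. baseline week (%)",
                  colour = "Channel") +
    ggplot2::theme_minimal()
}

#' Scatter of two channels' relative changes with trend lines
#'
#' One point per wave (and subgroup), with an OLS trend line per subgroup and
#' the 1:1 line for reference — the subgroup-correlation view.
#'
#' @param panel Aligned panel in long form (`channel`, `wave`, `subgroup`,
#'   `rel_change_pct`).
#' @param x_channel,y_channel Channel names to place on the axes.
#' @return A ggplot object.
#' @export
plot_channel_scatter <- function(panel, x_channel, y_channel) {
  wide <- panel |>
    dplyr::filter(.data$channel %in% c(x_channel, y_channel)) |>
    dplyr::select(dplyr::any_of(c("wave", "subgroup")), "channel",
                  "rel_change_pct") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "rel_change_pct")
  aes_base <- if ("subgroup" %in% names(wide))
    ggplot2::aes(.data[[x_channel]], .data[[y_channel]], colour = .data$subgroup)
  else ggplot2::aes(.data[[x_channel]], .data[[y_channel]])
  ggplot2::ggplot(wide, aes_base) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.6) +
    ggplot2::labs(x = paste(x_channel, "change vs. baseline (%)"),
                  y = paste(y_channel, "change vs. baseline (%)")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mob_did <- function(object, ...) {
  cm <- object$cell_means
  cm$period <- factor(cm$period, c("pre", "post"))
  ggplot2::ggplot(cm, ggplot2::aes(.data$period, .data$mean,
                                   group = .data$group, colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "Cell mean",
                  subtitle = sprintf("DiD effect = %.2f (SE %.2f)",
                                     object$effect, object$se)) +
    ggplot2::theme_minimal()
}
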