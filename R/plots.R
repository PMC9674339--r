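#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_col geom_path labs scale_x_log10 scale_y_log10 coord_polar
#'   facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot MSD curves and their log-log fits
#'
#' @param object An `msd_fit`.
#' @param ... Unused.
#' @return A ggplot: per-track xi(n) on log-log axes with the fitted
#'   power law overlaid.
#' @export
autoplot.msd_fit <- function(object, ...) {
  curve <- dplyr::filter(as_tibble(object$curve), .data$xi > 0)
  fits <- object$fits
  pred <- curve %>%
    dplyr::left_join(fits, by = "object_id") %>%
    dplyr::mutate(fit = exp(.data$intercept) * .data$n^.data$alpha)
  ggplot(curve, aes(x = .data$n, y = .data$xi, group = .data$object_id)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_line(data = pred, aes(y = .data$fit), colour = "firebrick",
              linewidth = 0.4) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "step size n", y = expression(xi(n) ~ (mu * m^2)),
         title = "Mean square displacement",
         subtitle = paste0("median alpha = ",
                           signif(stats::median(fits$alpha), 3))) +
    theme_minimal()
}

#' Plot event-aligned average centrosome dynamics
#'
#' @param object An `aligned_windows` tibble from
#'   [align_and_average_windows()].
#' @param ... Unused.
#' @return A ggplot with mean +/- SD ribbons for the centrosome-centre
#'   distance, the alignment angle and the phagosome-centre distance against
#'   time from onset.
#' @export
autoplot.aligned_windows <- function(object, ...) {
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(-c("rel_t", "n"),
                        names_to = c("series", "stat"),
                        names_pattern = "(d_cs_cc|theta|d_p_cc)_(mean|sd)") %>%
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  ggplot(long, aes(x = .data$rel_t, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                alpha = 0.25, fill = "steelblue") +
    geom_line(colour = "steelblue4") +
    facet_wrap(~ .data$series, scales = "free_y", ncol = 1,
               labeller = ggplot2::as_labeller(c(
                 d_cs_cc = "centrosome-centre distance (um)",
                 theta = "alignment angle (rad)",
                 d_p_cc = "phagosome-centre distance (um)"))) +
    labs(x = "time from onset (min)", y = NULL,
         title = "Event-aligned centrosome dynamics (mean +/- SD)") +
    theme_minimal()
}

#' Plot a radial probability map
#'
#' @param object A `radial_map` from [radial_probability_map()].
#' @param ... Unused.
#' @return A ggplot bar chart of probability mass per normalised radius bin.
#' @export
autoplot.radial_map <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_low + df$bin_high) / 2
  ggplot(df, aes(x = .data$mid, y = .data$mass)) +
    geom_col(width = df$bin_high - df$bin_low, fill = "grey35") +
    labs(x = "centrosome radius r / R", y = "probability mass",
         title = "Radial location of the centrosome") +
    theme_minimal()
}

#' Plot the spatiotemporal event correlation
#'
#' @param object A `spacetime_fit` from [spacetime_correlation()].
#' @param ... Unused.
#' @return A ggplot of waiting time against spatial separation with the OLS
#'   line and its confidence band.
#' @export
autoplot.spacetime_fit <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$dd_um, y = .data$dt_min)) +
    geom_ribbon(data = object$band,
                aes(x = .data$dd_um, y = .data$fit,
                    ymin = .data$lwr, ymax = .data$upr),
                alpha = 0.2, fill = "steelblue") +
    geom_line(data = object$band, aes(y = .data$fit), colour = "steelblue4") +
    geom_point(alpha = 0.7) +
    labs(x = "separation of consecutive targets (um)",
         y = "waiting time (min)",
         title = sprintf("dt ~ dd: r = %.2f", object$r)) +
    theme_minimal()
}

#' Polar plot of centrosome tracks relative to the phagosome axis
#'
#' @param polar One or more [polar_track()] outputs bound together.
#' @return A ggplot in polar coordinates; the phagosome direction is at
#'   angle 0.
#' @export
plot_polar_tracks <- function(polar) {
  ggplot(polar, aes(x = .data$phi, y = .data$r, group = .data$event_id,
                    colour = .data$rel_t)) +
    geom_path() +
    coord_polar(theta = "x", start = -pi / 2, direction = -1) +
    labs(x = "angle from phagosome axis (rad)", y = "r (um)",
         colour = "t - onset (min)",
         title = "Centrosome tracks in the cell frame") +
    theme_minimal()
}
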