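# ggplot2 figure helpers (ggplot2 is in Suggests; each function checks).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
}

#' Polar map of signed single-scattering intensity
#'
#' Log-scale polar rendering of the [polar_docp_map()] table: radius is
#' log10 intensity, color encodes helicity flip (negative signed DOCP)
#' versus preservation, one panel per sphere diameter.
#'
#' @param map Output of [polar_docp_map()].
#' @param floor Smallest intensity decade to display.
#' @return A ggplot object.
#' @export
plot_polar_docp <- function(map, floor = 1e-4) {
  need_ggplot()
  map$logI <- pmax(log10(pmax(map$intensity, floor)), log10(floor))
  map$response <- ifelse(map$signed_docp < 0, "flipped", "preserved")
  mirror <- map; mirror$theta_deg <- -mirror$theta_deg
  both <- rbind(map, mirror)
  ggplot2::ggplot(both,
                  ggplot2::aes(x = .data$theta_deg,
                               y = .data$logI - log10(floor),
                               color = .data$response)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::coord_polar(theta = "x", start = pi) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 45)) +
    ggplot2::scale_color_manual(values = c(flipped = "red",
                                           preserved = "blue")) +
    ggplot2::facet_wrap(~diameter_um, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "scattering angle (deg)",
                  y = "log10 relative intensity") +
    ggplot2::theme_minimal()
}

#' Flipped/preserved radial profile plot
#'
#' @param flipped,preserved `radial_profile` objects.
#' @param normalize Scale both curves by the common peak.
#' @return A ggplot object.
#' @export
plot_profiles <- function(flipped, preserved, normalize = TRUE) {
  need_ggplot()
  df <- rbind(data.frame(channel = "flipped", radius_mm = flipped$radius_mm,
                         value = flipped$value),
              data.frame(channel = "preserved",
                         radius_mm = preserved$radius_mm,
                         value = preserved$value))
  if (normalize) df$value <- df$value / max(df$value, na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_mm, y = .data$value,
                                   color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(flipped = "red",
                                           preserved = "blue")) +
    ggplot2::labs(x = "radial distance (mm)", y = "intensity (norm.)") +
    ggplot2::theme_minimal()
}

#' Per-channel statistics profile plot (mean N or mean angle)
#'
#' @param flipped,preserved `radial_profile` objects from
#'   [event_count_profile()] or [mean_angle_profile()].
#' @param ylab Axis label.
#' @param r_max_mm Optional radial cut-off.
#' @return A ggplot object.
#' @export
plot_statistics_profiles <- function(flipped, preserved,
                                     ylab = "mean scattering events N",
                                     r_max_mm = NULL) {
  need_ggplot()
  df <- rbind(data.frame(channel = "flipped", radius_mm = flipped$radius_mm,
                         value = flipped$value),
              data.frame(channel = "preserved",
                         radius_mm = preserved$radius_mm,
                         value = preserved$value))
  if (!is.null(r_max_mm)) df <- df[df$radius_mm <= r_max_mm, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_mm, y = .data$value,
                                   color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(flipped = "red",
                                           preserved = "blue")) +
    ggplot2::labs(x = "radial distance (mm)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Response-surface tile plot
#'
#' @param surface A [build_response_surface()] result.
#' @param n_grid Interpolation resolution.
#' @return A ggplot object.
#' @export
plot_response_surface <- function(surface, n_grid = 61) {
  need_ggplot()
  dq <- seq(min(surface$diameters_um), max(surface$diameters_um),
            length.out = n_grid)
  mq <- seq(min(surface$mu_s_cm), max(surface$mu_s_cm),
            length.out = n_grid)
  df <- expand.grid(diameter_um = dq, mu_s_cm = mq)
  df$shrm_norm <- surface_query(surface, df$diameter_um, df$mu_s_cm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diameter_um,
                                   y = .data$mu_s_cm,
                                   fill = .data$shrm_norm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "sphere diameter (um)",
                  y = "scattering coefficient (1/cm)",
                  fill = "SHRM (norm.)") +
    ggplot2::theme_minimal()
}
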