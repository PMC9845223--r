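#' Plot an arrival-point heat map
#'
#' Tile plot of the count grid in the velocity frame, optionally overlaid
#' with an arrival circle (e.g. the FS prediction or an extent estimate).
#'
#' @param object A `heatmap_grid`.
#' @param circle Optional one-row data frame with `x_c`, `y_c`, `r_c` (an
#'   [circle_from_extent()] row) or an [arrival_circle()] row.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.heatmap_grid <- function(object, circle = NULL, ...) {
  occ <- which(object$counts > 0, arr.ind = TRUE)
  s <- object$cell_size
  df <- tibble::tibble(
    x = (occ[, 1] - 1 + object$ix0 + 0.5) * s,
    y = (occ[, 2] - 1 + object$iy0 + 0.5) * s,
    n = object$counts[occ]
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$n)) +
    ggplot2::geom_tile(width = s, height = s) +
    ggplot2::scale_fill_viridis_c(name = "count") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (m, along initial velocity)", y = "y (m)",
      title = sprintf("Arrival points, Δt = %g s, v0 ∈ [%g, %g) m/s",
                      object$delta_t, object$v0_bin[1], object$v0_bin[2])) +
    ggplot2::theme_minimal()
  if (!is.null(circle)) {
    if (all(c("center_x", "center_y", "radius") %in% names(circle))) {
      circle <- tibble::tibble(x_c = circle$center_x, y_c = circle$center_y,
                               r_c = circle$radius)
    }
    th <- seq(0, 2 * pi, length.out = 181)
    ring <- tibble::tibble(x = circle$x_c[1] + circle$r_c[1] * cos(th),
                           y = circle$y_c[1] + circle$r_c[1] * sin(th))
    p <- p + ggplot2::geom_path(data = ring,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                inherit.aes = FALSE, linetype = "dashed")
  }
  p
}

#' Plot circle geometry against initial speed for a kinetic fit
#'
#' Shows the two observables behind the parameter estimates: the circle
#' centre `x_c` versus bin speed with the through-origin regression line
#' (slope `A`), and the radius `r_c` with its mean — flat under the FS
#' model.
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot (facetted).
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  est <- object$estimates
  df <- dplyr::bind_rows(
    tibble::tibble(v0 = est$v0_mid, value = est$x_c, what = "x_c (m)"),
    tibble::tibble(v0 = est$v0_mid, value = est$r_c, what = "r_c (m)")
  )
  ref <- dplyr::bind_rows(
    tibble::tibble(v0 = range(est$v0_mid),
                   value = object$slope * range(est$v0_mid),
                   what = "x_c (m)"),
    tibble::tibble(v0 = range(est$v0_mid), value = object$mean_r_c,
                   what = "r_c (m)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v0, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = ref, linetype = "dashed") +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "initial speed v0 (m/s)", y = NULL,
                  title = sprintf(
                    "Δt = %g s: alpha = %.2f 1/s, Vmax = %.2f m/s",
                    object$delta_t, object$alpha, object$vmax)) +
    ggplot2::theme_minimal()
}

#' Plot a speed distribution
#'
#' @param dist A [speed_distribution()] tibble.
#' @param log_y Semi-log scale to show the near-exponential tail.
#' @return A ggplot.
#' @export
plot_speed_distribution <- function(dist, log_y = FALSE) {
  p <- ggplot2::ggplot(dist, ggplot2::aes(x = .data$bin_mid,
                                          y = .data$density)) +
    ggplot2::geom_col(width = dist$bin_hi[1] - dist$bin_lo[1],
                      fill = "steelblue") +
    ggplot2::labs(x = "speed (m/s)", y = "density") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot an averaged MSD curve on log-log axes
#'
#' Reference slopes 2 (ballistic) and 1 (diffusive) are drawn as guides;
#' the crossover between them marks the straight-run timescale.
#'
#' @param curve An [average_msd()] tibble.
#' @return A ggplot.
#' @export
plot_msd <- function(curve) {
  anchor <- curve[which.min(abs(curve$tau - 10)), ]
  guides <- dplyr::bind_rows(
    tibble::tibble(tau = range(curve$tau),
                   msd = anchor$msd * (tau / anchor$tau)^2,
                   slope = "beta = 2"),
    tibble::tibble(tau = range(curve$tau),
                   msd = anchor$msd * (tau / anchor$tau),
                   slope = "beta = 1")
  )
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$tau, y = .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = guides,
                       ggplot2::aes(linetype = .data$slope), alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"),
                  y = expression(MSD ~ (m^2))) +
    ggplot2::theme_minimal()
}
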