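#' Through-origin regression of circle centres on initial speed
#'
#' The FS closed form predicts the arrival-circle centre at exactly
#' \eqn{x_c = A(\alpha, \Delta t)\, v_0} — strict proportionality, zero
#' intercept — so the default regression is constrained through the origin
#' and its slope is the estimate of `A`. Bins are represented by their
#' midpoint `v0 + delta_v0 / 2` and weighted equally. Bins whose lower edge
#' exceeds `v0_max` (default 6 m/s) are excluded: fast-initial-speed bins
#' are sparse (a fast player rarely reverses within the window), which
#' biases their extent-based estimates.
#'
#' @param estimates Per-bin circle estimates ([estimate_circles()] output).
#' @param v0_max Largest bin lower edge used, m/s; default 6.
#' @param free_intercept Fit an unconstrained line instead (diagnostic; the
#'   returned value is still the slope).
#' @return The slope (seconds), a numeric scalar with the number of bins
#'   used as attribute `n_bins`.
#' @export
center_regression <- function(estimates, v0_max = 6, free_intercept = FALSE) {
  check_tracking_cols(estimates, c("v0_lo", "v0_mid", "x_c"))
  use <- dplyr::filter(estimates, .data$v0_lo <= v0_max)
  if (nrow(use) < 2) {
    stop("need at least 2 speed bins with lower edge <= `v0_max`.",
         call. = FALSE)
  }
  fit <- if (free_intercept) {
    stats::lm(x_c ~ v0_mid, data = use)
  } else {
    stats::lm(x_c ~ 0 + v0_mid, data = use)
  }
  slope <- unname(stats::coef(fit)[["v0_mid"]])
  attr(slope, "n_bins") <- nrow(use)
  slope
}

#' Mean arrival-circle radius over speed bins
#'
#' The FS radius `B` does not depend on the initial speed, so the per-bin
#' radii are pooled by an unweighted mean over bins with lower edge up to
#' `v0_max`.
#'
#' @inheritParams center_regression
#' @return Mean radius, m.
#' @export
mean_radius <- function(estimates, v0_max = 6) {
  check_tracking_cols(estimates, c("v0_lo", "r_c"))
  use <- dplyr::filter(estimates, .data$v0_lo <= v0_max)
  if (nrow(use) == 0) stop("no speed bins with lower edge <= `v0_max`.",
                           call. = FALSE)
  mean(use$r_c)
}

#' Estimate kinetic parameters from per-bin circle estimates
#'
#' Combines the two geometric observables of the arrival circles at one
#' interval into the FS kinetic parameters: the centre-vs-speed slope is
#' inverted for the drag-to-mass ratio (`alpha`, via the monotone relation
#' `A(alpha, delta_t) = slope`), and the mean radius then yields the
#' terminal speed `vmax = mean_r_c / (delta_t - A)`. By construction
#' `coef_B(fit, delta_t)` reproduces `mean_r_c` exactly.
#'
#' @inheritParams center_regression
#' @param delta_t Arrival interval the estimates were built at, s.
#' @return An object of class `kinetic_fit`: a list with `delta_t`, `slope`,
#'   `alpha` (1/s), `mean_r_c` (m), `vmax` (m/s), `v0_max`, `n_bins_used`
#'   and the input `estimates`. Has [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()] methods.
#' @examples
#' est <- tibble::tibble(v0_lo = seq(0, 6, 0.3), v0_mid = v0_lo + 0.15,
#'                       x_c = coef_A(1.5, 2) * v0_mid, y_c = 0,
#'                       r_c = coef_B(kinetic_params(1.5, 9), 2))
#' estimate_params(est, delta_t = 2)
#' @export
estimate_params <- function(estimates, delta_t, v0_max = 6,
                            free_intercept = FALSE) {
  stopifnot(is.numeric(delta_t), length(delta_t) == 1L, delta_t > 0)
  slope <- center_regression(estimates, v0_max, free_intercept)
  alpha <- invert_alpha(as.numeric(slope), delta_t)
  r_c <- mean_radius(estimates, v0_max)
  vmax <- vmax_from_radius(r_c, alpha, delta_t)
  structure(list(delta_t = delta_t, slope = as.numeric(slope), alpha = alpha,
                 mean_r_c = r_c, vmax = vmax, v0_max = v0_max,
                 n_bins_used = attr(slope, "n_bins"),
                 free_intercept = free_intercept, estimates = estimates),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<kinetic_fit> delta_t = %g s (%d bins, v0 <= %g m/s)\n",
           "  slope A  = %.4f s\n  alpha    = %.4f 1/s\n",
           "  mean r_c = %.4f m\n  vmax     = %.4f m/s\n"),
    x$delta_t, x$n_bins_used, x$v0_max, x$slope, x$alpha, x$mean_r_c, x$vmax))
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated quantity (`term`,
#'   `estimate`, `unit`).
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "alpha", "mean_r_c", "vmax"),
    estimate = c(x$slope, x$alpha, x$mean_r_c, x$vmax),
    unit = c("s", "1/s", "m", "m/s")
  )
}

#' Glance at a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `delta_t`, `slope`, `alpha`, `mean_r_c`,
#'   `vmax`, `n_bins_used`, `v0_max`.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(delta_t = x$delta_t, slope = x$slope, alpha = x$alpha,
                 mean_r_c = x$mean_r_c, vmax = x$vmax,
                 n_bins_used = x$n_bins_used, v0_max = x$v0_max)
}

#' Sweep the arrival interval and refit kinetic parameters
#'
#' Runs the full chain — arrival points in the velocity frame, per-bin heat
#' maps, isolated-cell filtering, extent circles, parameter estimation — for
#' each requested interval. The FS model assumes `alpha` and `vmax` are
#' constants; plotting the fitted values against `delta_t` tests that
#' assumption.
#'
#' @param records Velocity records ([compute_velocity()] output).
#' @param delta_t Numeric vector of intervals, s.
#' @param v0_range,delta_v0,cell_factor,c,strict Heat-map settings; see
#'   [estimate_circles()]. `cell_factor` scales the cell side as
#'   `cell_factor * delta_t` (default 0.2); `c = NULL` selects
#'   [default_c()] per interval.
#' @param v0_max,free_intercept Fit settings; see [estimate_params()].
#' @return A tibble with one row per interval that could be fitted
#'   (columns as [glance.kinetic_fit()] plus a `fit` list-column holding
#'   each `kinetic_fit`); failures are reported as warnings and skipped.
#' @export
sweep_delta_t <- function(records, delta_t, v0_range = c(0, 6),
                          delta_v0 = 0.3, cell_factor = 0.2, c = NULL,
                          strict = FALSE, v0_max = 6, free_intercept = FALSE) {
  stopifnot(is.numeric(delta_t))
  rows <- purrr::map(delta_t, function(dt) {
    tryCatch({
      pts <- arrival_points(records, dt)
      cc <- if (is.null(c)) default_c(dt) else c
      est <- estimate_circles(pts, dt, v0_range = v0_range,
                              delta_v0 = delta_v0,
                              cell_size = cell_factor * dt, c = cc,
                              strict = strict)
      fit <- estimate_params(est, dt, v0_max = v0_max,
                             free_intercept = free_intercept)
      out <- glance(fit)
      out$fit <- list(fit)
      out
    }, error = function(e) {
      warning(sprintf("delta_t = %g s failed: %s", dt, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  dplyr::bind_rows(rows)
}
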