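infer_interval <- function(tracks) {
  si <- attr(tracks, "sample_interval")
  if (!is.null(si)) return(si)
  tt <- sort(unique(tracks$time_s))
  if (length(tt) < 2) stop("cannot infer sampling interval from one frame.",
                           call. = FALSE)
  stats::median(diff(tt))
}

check_tracking_cols <- function(tracks, cols) {
  miss <- setdiff(cols, names(tracks))
  if (length(miss) > 0) {
    stop("tracking data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

#' Finite-difference velocity over a fixed lag
#'
#' The per-frame velocity is defined as the backward difference
#' \eqn{v(t) = (x(t) - x(t - lag)) / lag} with a lag of 1 s by default — the
#' standard estimator for optical tracking data, where frame-to-frame
#' differences would be dominated by measurement noise. No smoothing is
#' applied; downstream binning absorbs the residual noise. Records in the
#' first `lag` seconds of each segment, where the difference is undefined,
#' are dropped.
#'
#' @param tracks Tracking tibble with columns `segment_id`, `time_s`,
#'   `player_id`, `x_m`, `y_m` (and optionally `role`, `team`).
#' @param lag Velocity lag, s; must be a positive multiple of the sampling
#'   interval.
#' @return A tibble: the input rows for which velocity is defined, with
#'   added columns `vx`, `vy` (m/s) and `speed` (m/s). The sampling interval
#'   is carried in attribute `sample_interval`.
#' @examples
#' trk <- generate_tracking(tracking_config(n_outfield = 1, n_segments = 1,
#'                                          segment_duration = 10, seed = 2))
#' head(compute_velocity(trk))
#' @export
compute_velocity <- function(tracks, lag = 1) {
  check_tracking_cols(tracks, c("segment_id", "time_s", "player_id", "x_m", "y_m"))
  si <- infer_interval(tracks)
  k <- lag / si
  if (abs(k - round(k)) > 1e-6 || lag <= 0) {
    stop(sprintf("`lag` (%g s) must be a positive multiple of the sampling interval (%g s).",
                 lag, si), call. = FALSE)
  }
  k <- as.integer(round(k))
  out <- tracks |>
    dplyr::arrange(.data$segment_id, .data$player_id, .data$time_s) |>
    dplyr::group_by(.data$segment_id, .data$player_id) |>
    dplyr::mutate(
      vx = (.data$x_m - dplyr::lag(.data$x_m, k)) / lag,
      vy = (.data$y_m - dplyr::lag(.data$y_m, k)) / lag
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$vx)) |>
    dplyr::mutate(speed = sqrt(.data$vx^2 + .data$vy^2))
  if (nrow(out) == 0) {
    warning("no segment is longer than `lag`; returning an empty result.")
  }
  attr(out, "sample_interval") <- si
  out
}

#' Speed distribution histogram
#'
#' Normalised histogram of instantaneous speeds, optionally restricted by
#' role. Match data shows a walking peak near 1 m/s for everyone and a
#' jogging peak near 3 m/s for outfield players, with near-exponential decay
#' beyond; goalkeepers lack the fast tail, which is why sprint analyses
#' exclude them.
#'
#' @param records Output of [compute_velocity()] (needs `speed`, and `role`
#'   if `role_filter` is not `"all"`).
#' @param role_filter `"OUT"` (default), `"GK"`, or `"all"`.
#' @param bin_width Histogram bin width, m/s.
#' @return A tibble with columns `bin_lo`, `bin_mid`, `bin_hi`, `n`,
#'   `density` (densities integrate to 1).
#' @export
speed_distribution <- function(records, role_filter = "OUT", bin_width = 0.1) {
  check_tracking_cols(records, "speed")
  stopifnot(bin_width > 0)
  if (!identical(role_filter, "all")) {
    check_tracking_cols(records, "role")
    records <- dplyr::filter(records, .data$role == role_filter)
  }
  v <- records$speed
  if (length(v) == 0) stop("no records after role filtering.", call. = FALSE)
  idx <- floor(v / bin_width)
  tab <- table(idx)
  lo <- as.numeric(names(tab)) * bin_width
  n <- as.integer(tab)
  tibble::tibble(bin_lo = lo, bin_mid = lo + bin_width / 2,
                 bin_hi = lo + bin_width, n = n,
                 density = n / (sum(n) * bin_width))
}

# Log-spaced unique frame lags from 1 to max_lag.
log_spaced_lags <- function(max_lag, n_points) {
  if (max_lag < 1) return(integer())
  lags <- unique(round(exp(seq(log(1), log(max_lag), length.out = n_points))))
  lags[lags >= 1 & lags <= max_lag]
}

#' Mean squared displacement per player and segment
#'
#' For each (segment, player) time series of length `T`, the MSD at lag
#' `tau` is the long-time average
#' \deqn{MSD(\tau) = \frac{1}{T-\tau}\sum_{t=0}^{T-\tau} |x(t+\tau)-x(t)|^2,}
#' summing over all sampled frames `t`. Lags run up to `T/2` (bounding the
#' variance of the average) and are log-spaced by default, which is where a
#' log-log scaling fit operates anyway.
#'
#' The scaling exponent beta in \eqn{MSD \sim \tau^\beta} distinguishes
#' ballistic motion (beta = 2, straight runs) from diffusive motion
#' (beta = 1, direction randomised).
#'
#' @param tracks Tracking tibble (see [compute_velocity()] for columns).
#' @param tau Optional numeric vector of lags, s; defaults to ~`n_tau`
#'   log-spaced multiples of the sampling interval up to half the segment
#'   length. Lags not below the segment length are excluded.
#' @param n_tau Number of log-spaced lags when `tau` is `NULL`.
#' @return A tibble with columns `segment_id`, `player_id`, `tau`, `msd`,
#'   `n_pairs`.
#' @export
compute_msd <- function(tracks, tau = NULL, n_tau = 60) {
  check_tracking_cols(tracks, c("segment_id", "time_s", "player_id", "x_m", "y_m"))
  si <- infer_interval(tracks)
  tracks <- dplyr::arrange(tracks, .data$segment_id, .data$player_id,
                           .data$time_s)
  groups <- dplyr::group_split(tracks, .data$segment_id, .data$player_id)
  res <- purrr::map(groups, function(g) {
    n <- nrow(g)
    if (is.null(tau)) {
      lags <- log_spaced_lags(floor((n - 1) / 2), n_tau)
    } else {
      lags <- round(tau / si)
      if (any(abs(lags - tau / si) > 1e-6)) {
        stop("`tau` values must be multiples of the sampling interval.",
             call. = FALSE)
      }
      lags <- lags[lags >= 1 & lags <= n - 1]
    }
    if (length(lags) == 0) return(NULL)
    x <- g$x_m
    y <- g$y_m
    msd <- vapply(lags, function(k) {
      dx <- x[(k + 1):n] - x[1:(n - k)]
      dy <- y[(k + 1):n] - y[1:(n - k)]
      mean(dx * dx + dy * dy)
    }, numeric(1))
    tibble::tibble(segment_id = g$segment_id[1], player_id = g$player_id[1],
                   tau = lags * si, msd = msd, n_pairs = n - lags)
  })
  dplyr::bind_rows(res)
}

#' Average MSD curves over players and segments
#'
#' Pointwise mean of per-(segment, player) MSD curves on a common lag grid,
#' the analogue of averaging a game's MSD over all outfield players.
#'
#' @param curves Output of [compute_msd()].
#' @return A tibble with columns `tau`, `msd`, `n_curves`.
#' @export
average_msd <- function(curves) {
  check_tracking_cols(curves, c("tau", "msd"))
  if (nrow(curves) == 0) stop("no MSD curves to average.", call. = FALSE)
  if (all(c("segment_id", "player_id") %in% names(curves))) {
    grids <- curves |>
      dplyr::group_by(.data$segment_id, .data$player_id) |>
      dplyr::summarise(key = paste(signif(.data$tau, 10), collapse = ","),
                       .groups = "drop")
    if (length(unique(grids$key)) > 1) {
      stop("MSD curves are not on a common tau grid; recompute with a shared `tau`.",
           call. = FALSE)
    }
  }
  curves |>
    dplyr::group_by(.data$tau) |>
    dplyr::summarise(msd = mean(.data$msd), n_curves = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$tau)
}

#' Fit the MSD scaling exponent
#'
#' Least-squares slope of `log(msd)` against `log(tau)` over a lag window:
#' the scaling exponent beta. Requires at least 3 points with positive MSD
#' inside the window.
#'
#' @param curve An averaged MSD tibble (columns `tau`, `msd`).
#' @param tau_window Length-2 numeric `(lo, hi)` in seconds, inclusive.
#' @return The fitted exponent `beta` (numeric scalar).
#' @examples
#' curve <- tibble::tibble(tau = 1:20, msd = (1:20)^2)
#' fit_msd_exponent(curve, c(1, 8))  # exactly 2
#' @export
fit_msd_exponent <- function(curve, tau_window) {
  check_tracking_cols(curve, c("tau", "msd"))
  stopifnot(is.numeric(tau_window), length(tau_window) == 2L,
            tau_window[1] < tau_window[2])
  sel <- curve$tau >= tau_window[1] & curve$tau <= tau_window[2]
  pts <- curve[sel, ]
  if (nrow(pts) < 3) {
    stop("need at least 3 MSD points inside `tau_window`.", call. = FALSE)
  }
  if (any(pts$msd <= 0)) {
    stop("MSD values in the fit window must be positive for a log-log fit.",
         call. = FALSE)
  }
  fit <- stats::lm(log(msd) ~ log(tau), data = pts)
  unname(stats::coef(fit)[2])
}
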