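#' Configuration for the end-to-end validation pipeline
#'
#' Bundles every setting of [run_validation()]: where the tracking data
#' comes from (a CSV path or a generator configuration), the arrival
#' intervals to analyse, the speed binning, the heat-map cell scaling and
#' isolated-cell threshold, the MSD fit windows, and an output directory.
#'
#' @param input Optional path to a tracking CSV; when `NULL`, data is
#'   generated from `generator`.
#' @param generator A [tracking_config()] used when `input` is `NULL`.
#' @param delta_t Arrival intervals to analyse, s.
#' @param delta_v0 Speed-bin width, m/s; default 0.3.
#' @param v0_range Range of bin lower edges, m/s; default `c(0, 6)`.
#' @param v0_max_fit Largest bin lower edge entering the fits, m/s;
#'   default 6.
#' @param cell_factor Heat-map cell side as a multiple of `delta_t`;
#'   default 0.2.
#' @param c Isolated-cell threshold override; `NULL` (default) uses
#'   [default_c()] per interval.
#' @param lag Velocity lag, s; default 1.
#' @param msd_windows Named list of `tau` fit windows (s) for the MSD
#'   exponents; defaults to the ballistic window `c(1, 8)` and diffusive
#'   window `c(20, 100)` flanking the ~10 s straight-run timescale.
#' @param out_dir Optional directory for [write_report()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            generator = tracking_config(),
                            delta_t = c(1, 2),
                            delta_v0 = 0.3,
                            v0_range = c(0, 6),
                            v0_max_fit = 6,
                            cell_factor = 0.2,
                            c = NULL,
                            lag = 1,
                            msd_windows = list(ballistic = c(1, 8),
                                               diffusive = c(20, 100)),
                            out_dir = NULL) {
  stopifnot(is.null(input) || (is.character(input) && length(input) == 1),
            inherits(generator, "tracking_config") || !is.null(input),
            is.numeric(delta_t), length(delta_t) >= 1, all(delta_t > 0),
            is.numeric(delta_v0), delta_v0 > 0,
            is.numeric(v0_range), length(v0_range) == 2,
            is.numeric(cell_factor), cell_factor > 0,
            is.numeric(lag), lag > 0, is.list(msd_windows))
  structure(list(input = input, generator = generator, delta_t = delta_t,
                 delta_v0 = delta_v0, v0_range = v0_range,
                 v0_max_fit = v0_max_fit, cell_factor = cell_factor, c = c,
                 lag = lag, msd_windows = msd_windows, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full sprint-model validation pipeline
#'
#' Orchestrates the whole analysis on one dataset: load (or generate)
#' tracking data, estimate velocities, summarise the speed distribution,
#' compute and average the MSD and fit its scaling exponents, then for each
#' arrival interval build per-speed-bin velocity-frame heat maps, filter
#' isolated cells, estimate boundary circles, and invert the circle
#' geometry into the FS kinetic parameters.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A list of class `validation_report` with elements `tracks`
#'   (invisible input data), `speed_distribution`, `msd` (averaged curve),
#'   `msd_exponents` (tibble window/beta), `circles` (all per-bin circle
#'   estimates), and `fits` (per-interval kinetic fits, one row per
#'   `delta_t`).
#' @export
run_validation <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(config$input)) {
    say("reading tracking data from %s", config$input)
    tracks <- read_tracking(config$input)
  } else {
    if (is.null(config$generator)) {
      stop("no `input` file and no `generator` configuration.", call. = FALSE)
    }
    say("generating synthetic tracking data (seed %d)", config$generator$seed)
    tracks <- generate_tracking(config$generator)
  }
  say("%d samples, %d players, %d segments", nrow(tracks),
      dplyr::n_distinct(tracks$player_id),
      dplyr::n_distinct(tracks$segment_id))

  vel <- compute_velocity(tracks, lag = config$lag)
  say("velocity records: %d", nrow(vel))
  spd <- speed_distribution(vel, role_filter = "OUT")

  out_tracks <- if ("role" %in% names(tracks)) {
    dplyr::filter(tracks, .data$role != "GK")
  } else tracks
  msd_curves <- compute_msd(out_tracks)
  msd_avg <- average_msd(msd_curves)
  exps <- purrr::imap(config$msd_windows, function(w, nm) {
    beta <- tryCatch(fit_msd_exponent(msd_avg, w), error = function(e) NA_real_)
    tibble::tibble(window = nm, tau_lo = w[1], tau_hi = w[2],
                   beta = as.numeric(beta))
  }) |> dplyr::bind_rows()
  say("MSD exponents: %s",
      paste(sprintf("%s %.3f", exps$window, exps$beta), collapse = ", "))

  fits <- sweep_delta_t(vel, config$delta_t, v0_range = config$v0_range,
                        delta_v0 = config$delta_v0,
                        cell_factor = config$cell_factor, c = config$c,
                        v0_max = config$v0_max_fit)
  circles <- purrr::map(fits$fit, function(f) f$estimates) |>
    dplyr::bind_rows()
  if (nrow(fits) > 0) {
    say("kinetic fits:\n%s",
        paste(utils::capture.output(print(
          dplyr::select(fits, -dplyr::any_of("fit")))), collapse = "\n"))
  }
  report <- structure(list(tracks = tracks, speed_distribution = spd,
                           msd = msd_avg, msd_exponents = exps,
                           circles = circles, fits = fits,
                           config = config),
                      class = "validation_report")
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    say("report written to %s", config$out_dir)
  }
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  samples: %d  players: %d  segments: %d\n", nrow(x$tracks),
              dplyr::n_distinct(x$tracks$player_id),
              dplyr::n_distinct(x$tracks$segment_id)))
  cat("  MSD exponents:\n")
  for (i in seq_len(nrow(x$msd_exponents))) {
    cat(sprintf("    beta[%g, %g s] = %.3f\n", x$msd_exponents$tau_lo[i],
                x$msd_exponents$tau_hi[i], x$msd_exponents$beta[i]))
  }
  cat("  kinetic fits:\n")
  for (i in seq_len(nrow(x$fits))) {
    cat(sprintf("    delta_t = %g s: alpha = %.3f 1/s, vmax = %.3f m/s\n",
                x$fits$delta_t[i], x$fits$alpha[i], x$fits$vmax[i]))
  }
  invisible(x)
}
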