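#' Default walk/jog/sprint behavioural states
#'
#' Players in match tracking data show a bimodal speed distribution — a
#' walking peak near 1 m/s, a jogging peak near 3 m/s — with a
#' near-exponential tail produced by occasional sprints. The generator
#' emulates this with a three-state Markov switching process; within a state
#' the player follows FS dynamics with state-specific terminal speed.
#'
#' Dwell times are exponential with the given means; on a dwell end the next
#' state is drawn from the transition row of the current state. With the
#' defaults the long-run time shares are roughly 46% walk, 47% jog, 7%
#' sprint, giving a mean speed near 2.3 m/s (about 12 km covered per 90
#' minutes, typical of an outfield player).
#'
#' @param alpha Drag-to-mass ratio used in every state, 1/s.
#' @param vmax Named numeric vector of terminal speeds (m/s) for
#'   `walk`, `jog`, `sprint`.
#' @param dwell_mean Named numeric vector of mean dwell times (s).
#' @param transition 3x3 row-stochastic matrix (zero diagonal) of switch
#'   probabilities, rows and columns ordered walk, jog, sprint.
#' @return A list of class `behaviour_states`.
#' @export
behaviour_states <- function(alpha = 1.3,
                             vmax = c(walk = 1, jog = 3, sprint = 8),
                             dwell_mean = c(walk = 12, jog = 10, sprint = 3),
                             transition = rbind(walk   = c(0, 0.85, 0.15),
                                                jog    = c(0.65, 0, 0.35),
                                                sprint = c(0.35, 0.65, 0))) {
  nm <- c("walk", "jog", "sprint")
  stopifnot(all(nm %in% names(vmax)), all(nm %in% names(dwell_mean)))
  vmax <- vmax[nm]; dwell_mean <- dwell_mean[nm]
  if (any(vmax <= 0) || any(dwell_mean <= 0) || alpha <= 0) {
    stop("state speeds, dwell times and alpha must all be positive.",
         call. = FALSE)
  }
  transition <- as.matrix(transition)
  colnames(transition) <- nm
  if (!all(dim(transition) == c(3, 3)) || any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-8) || any(diag(transition) != 0)) {
    stop("`transition` must be 3x3, row-stochastic, with zero diagonal.",
         call. = FALSE)
  }
  structure(list(alpha = alpha, vmax = vmax, dwell_mean = dwell_mean,
                 transition = transition, names = nm),
            class = "behaviour_states")
}

#' Configuration for the synthetic tracking generator
#'
#' Describes a synthetic "match": how many players, how many contiguous play
#' segments and how long, the sampling interval, the behavioural-state model,
#' the straight-run persistence, the measurement noise, and the pitch.
#'
#' Straight-line persistence: each player keeps a fixed driving direction for
#' an exponentially distributed run (mean `mean_run_duration`, default 10 s)
#' and then redraws it uniformly; the direction is also redrawn when a sprint
#' starts (players launch sprints toward a fresh target). This yields the
#' ballistic-to-diffusive MSD crossover around the run timescale.
#'
#' Noise: isotropic zero-mean displacement per sample. The default Gaussian
#' sigma of 0.5 m puts ~95% of per-axis errors within the +-1 m accuracy
#' quoted for optical tracking systems; `noise_model = "uniform_disc"` uses
#' a uniform disc of radius `2 * noise_sigma` instead.
#'
#' Pitch: players start uniformly inside `start_box` (default a standard
#' 105 m x 68 m pitch). By default `pitch_bounds = NULL`, i.e. trajectories
#' are not confined: every downstream statistic here (velocity-frame heat
#' maps, MSD) is translation-invariant, and hard-confining independent
#' walkers would saturate the MSD at the pitch scale, an artifact real
#' players — who drift with the flow of play — do not show. Supplying
#' `pitch_bounds = c(xmin, xmax, ymin, ymax)` clamps positions and redraws
#' directions toward the interior within 2 m of a bound.
#'
#' @param n_outfield Number of outfield players; positive integer.
#' @param include_goalkeeper Add two goalkeepers (one per team)? Goalkeepers
#'   only alternate walk/jog and are excluded from sprint analyses.
#' @param n_segments Number of contiguous play segments.
#' @param segment_duration Segment length T, s; at least 2 s.
#' @param sample_interval Sampling interval, s; default 0.04.
#' @param states A [behaviour_states()] object.
#' @param mean_run_duration Mean straight-run duration, s; default 10.
#' @param noise_sigma Noise scale, m; default 0.5.
#' @param noise_model `"gaussian"` (default) or `"uniform_disc"`.
#' @param pitch_bounds `NULL` (default, unconfined) or
#'   `c(xmin, xmax, ymin, ymax)` in m.
#' @param start_box Rectangle for initial positions,
#'   `c(xmin, xmax, ymin, ymax)` in m.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return A validated list of class `tracking_config`.
#' @examples
#' cfg <- tracking_config(n_outfield = 2, n_segments = 1,
#'                        segment_duration = 30, seed = 7)
#' @export
tracking_config <- function(n_outfield = 20,
                            include_goalkeeper = TRUE,
                            n_segments = 12,
                            segment_duration = 300,
                            sample_interval = 0.04,
                            states = behaviour_states(),
                            mean_run_duration = 10,
                            noise_sigma = 0.5,
                            noise_model = c("gaussian", "uniform_disc"),
                            pitch_bounds = NULL,
                            start_box = c(-52.5, 52.5, -34, 34),
                            seed = 1L) {
  noise_model <- match.arg(noise_model)
  bad <- character()
  chk <- function(ok, field) if (!isTRUE(ok)) bad <<- c(bad, field)
  chk(is.numeric(n_outfield) && length(n_outfield) == 1 && n_outfield >= 1 &&
        n_outfield == round(n_outfield), "n_outfield")
  chk(is.logical(include_goalkeeper) && length(include_goalkeeper) == 1,
      "include_goalkeeper")
  chk(is.numeric(n_segments) && length(n_segments) == 1 && n_segments >= 1 &&
        n_segments == round(n_segments), "n_segments")
  chk(is.numeric(segment_duration) && length(segment_duration) == 1 &&
        segment_duration >= 2, "segment_duration")
  chk(is.numeric(sample_interval) && length(sample_interval) == 1 &&
        sample_interval > 0, "sample_interval")
  chk(inherits(states, "behaviour_states"), "states")
  chk(is.numeric(mean_run_duration) && length(mean_run_duration) == 1 &&
        mean_run_duration > 0, "mean_run_duration")
  chk(is.numeric(noise_sigma) && length(noise_sigma) == 1 && noise_sigma >= 0,
      "noise_sigma")
  chk(is.null(pitch_bounds) ||
        (is.numeric(pitch_bounds) && length(pitch_bounds) == 4 &&
           pitch_bounds[1] < pitch_bounds[2] && pitch_bounds[3] < pitch_bounds[4]),
      "pitch_bounds")
  chk(is.numeric(start_box) && length(start_box) == 4 &&
        start_box[1] < start_box[2] && start_box[3] < start_box[4], "start_box")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed")
  if (length(bad) > 0) {
    stop("invalid tracking_config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_outfield = as.integer(n_outfield),
                 include_goalkeeper = include_goalkeeper,
                 n_segments = as.integer(n_segments),
                 segment_duration = segment_duration,
                 sample_interval = sample_interval,
                 states = states,
                 mean_run_duration = mean_run_duration,
                 noise_sigma = noise_sigma,
                 noise_model = noise_model,
                 pitch_bounds = pitch_bounds,
                 start_box = start_box,
                 seed = as.integer(seed)),
            class = "tracking_config")
}

# Simulate one player over one segment; returns data.frame of frames.
# Piecewise-exact FS propagation: within each piece (constant state and
# direction) all frames come from the closed form, so sprint intervals
# satisfy the model exactly per straight run.
simulate_player_segment <- function(config, role) {
  st <- config$states
  dt <- config$sample_interval
  nf <- round(config$segment_duration / dt)
  t_total <- nf * dt
  times <- (0:nf) * dt
  xs <- numeric(nf + 1)
  ys <- numeric(nf + 1)

  gk <- identical(role, "GK")
  state_names <- st$names
  # goalkeepers only walk/jog, with walking dominant
  trans <- if (gk) rbind(c(0, 1, 0), c(1, 0, 0), c(0.5, 0.5, 0)) else st$transition
  dwell <- if (gk) c(20, 4, 1) else st$dwell_mean
  share <- {
    p <- rep(1 / 3, 3)
    for (i in 1:50) p <- as.numeric(p %*% trans)
    w <- p * dwell
    w / sum(w)
  }

  s <- sample.int(3L, 1L, prob = share)
  theta <- stats::runif(1, 0, 2 * pi)
  n_hat <- c(cos(theta), sin(theta))
  vm <- st$vmax[[s]]
  pos <- c(stats::runif(1, config$start_box[1], config$start_box[2]),
           stats::runif(1, config$start_box[3], config$start_box[4]))
  vel <- vm * n_hat
  xs[1] <- pos[1]; ys[1] <- pos[2]

  bounds <- config$pitch_bounds
  draw_direction <- function(pos) {
    if (!is.null(bounds)) {
      near <- pos[1] < bounds[1] + 2 || pos[1] > bounds[2] - 2 ||
        pos[2] < bounds[3] + 2 || pos[2] > bounds[4] - 2
      if (near) {
        ctr <- c(mean(bounds[1:2]), mean(bounds[3:4]))
        base <- atan2(ctr[2] - pos[2], ctr[1] - pos[1])
        th <- base + stats::runif(1, -pi / 2, pi / 2)
        return(c(cos(th), sin(th)))
      }
    }
    th <- stats::runif(1, 0, 2 * pi)
    c(cos(th), sin(th))
  }

  t_cur <- 0
  next_dir <- stats::rexp(1, 1 / config$mean_run_duration)
  next_state <- stats::rexp(1, 1 / dwell[s])
  i_done <- 0L  # frames filled so far (excluding frame 0)

  while (t_cur < t_total - 1e-9) {
    t_ev <- min(next_dir, next_state, t_total)
    i_hi <- min(floor(t_ev / dt + 1e-9), nf)
    if (i_hi > i_done) {
      idx <- (i_done + 1L):i_hi
      tau <- times[idx + 1L] - t_cur
      a <- coef_A(st$alpha, tau)
      b <- vm * (tau - a)
      xs[idx + 1L] <- pos[1] + a * vel[1] + b * n_hat[1]
      ys[idx + 1L] <- pos[2] + a * vel[2] + b * n_hat[2]
      i_done <- i_hi
    }
    # advance exact state to the event time
    pr <- fs_propagate(pos, vel, n_hat, st$alpha, vm, t_ev - t_cur)
    pos <- c(pr$x, pr$y); vel <- c(pr$vx, pr$vy)
    t_cur <- t_ev
    if (t_cur >= t_total - 1e-9) break
    redraw <- FALSE
    if (next_dir <= next_state) {
      redraw <- TRUE
      next_dir <- t_cur + stats::rexp(1, 1 / config$mean_run_duration)
    }
    if (next_state <= t_cur + 1e-12) {
      s_new <- sample.int(3L, 1L, prob = trans[s, ])
      if (s_new == 3L && s != 3L) redraw <- TRUE  # sprint entry: new target
      s <- s_new
      vm <- st$vmax[[s]]
      next_state <- t_cur + stats::rexp(1, 1 / dwell[s])
    }
    if (redraw) n_hat <- draw_direction(pos)
    if (!is.null(bounds)) {
      pos[1] <- min(max(pos[1], bounds[1]), bounds[2])
      pos[2] <- min(max(pos[2], bounds[3]), bounds[4])
    }
  }
  if (!is.null(bounds)) {
    xs <- pmin(pmax(xs, bounds[1]), bounds[2])
    ys <- pmin(pmax(ys, bounds[3]), bounds[4])
  }
  data.frame(time_s = times, x_m = xs, y_m = ys)
}

#' Generate a synthetic tracking dataset
#'
#' Produces a seeded, reproducible tracking dataset with the statistical
#' structure of optical match-tracking data: 0.04 s sampling, contiguous
#' play segments, a walking/jogging bimodal speed distribution with a sprint
#' tail, straight runs of ~10 s followed by random direction changes (the
#' ballistic-to-diffusive MSD crossover), FS dynamics within each behavioural
#' state, and isotropic positional noise.
#'
#' @param config A [tracking_config()].
#' @return A tibble with columns `segment_id`, `time_s`, `player_id`, `team`,
#'   `role` (`"GK"`/`"OUT"`), `x_m`, `y_m`, ordered by segment, player, time.
#'   The sampling interval is attached as attribute `sample_interval`.
#' @examples
#' trk <- generate_tracking(tracking_config(n_outfield = 2, n_segments = 1,
#'                                          segment_duration = 20, seed = 1))
#' dplyr::count(trk, player_id)
#' @export
generate_tracking <- function(config = tracking_config()) {
  stopifnot(inherits(config, "tracking_config"))
  n_gk <- if (config$include_goalkeeper) 2L else 0L
  n_players <- config$n_outfield + n_gk
  roles <- c(rep("OUT", config$n_outfield), rep("GK", n_gk))
  teams <- rep(c("A", "B"), length.out = n_players)
  ids <- sprintf("P%02d", seq_len(n_players))

  withr::local_seed(config$seed)
  pieces <- vector("list", config$n_segments * n_players)
  k <- 0L
  for (seg in seq_len(config$n_segments)) {
    seg_id <- sprintf("S%02d", seg)
    for (p in seq_len(n_players)) {
      df <- simulate_player_segment(config, roles[p])
      df$segment_id <- seg_id
      df$player_id <- ids[p]
      df$team <- teams[p]
      df$role <- roles[p]
      k <- k + 1L
      pieces[[k]] <- df
    }
  }
  out <- dplyr::bind_rows(pieces)
  out <- tibble::as_tibble(out[, c("segment_id", "time_s", "player_id",
                                   "team", "role", "x_m", "y_m")])
  if (config$noise_sigma > 0) {
    out <- add_noise(out, config$noise_sigma, model = config$noise_model)
  }
  attr(out, "sample_interval") <- config$sample_interval
  out
}

#' Add isotropic positional noise to tracking data
#'
#' Perturbs every sample's position independently, emulating optical
#' tracking error. Gaussian noise with per-axis standard deviation
#' `noise_sigma` (default interpretation: the quoted +-1 m accuracy is ~2
#' sigma); alternatively uniform noise on a disc of radius `2 * noise_sigma`.
#'
#' @param tracks A tracking tibble (needs columns `x_m`, `y_m`).
#' @param noise_sigma Noise scale, m; non-negative. Zero is the identity.
#' @param seed Optional integer seed for reproducible noise.
#' @param model `"gaussian"` or `"uniform_disc"`.
#' @return `tracks` with perturbed `x_m`, `y_m`.
#' @export
add_noise <- function(tracks, noise_sigma = 0.5, seed = NULL,
                      model = c("gaussian", "uniform_disc")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(tracks), all(c("x_m", "y_m") %in% names(tracks)))
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1 || noise_sigma < 0) {
    stop("`noise_sigma` must be a single non-negative number.", call. = FALSE)
  }
  if (noise_sigma == 0) return(tracks)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(tracks)
  if (model == "gaussian") {
    dx <- stats::rnorm(n, 0, noise_sigma)
    dy <- stats::rnorm(n, 0, noise_sigma)
  } else {
    r <- 2 * noise_sigma * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    dx <- r * cos(th)
    dy <- r * sin(th)
  }
  tracks$x_m <- tracks$x_m + dx
  tracks$y_m <- tracks$y_m + dy
  tracks
}

#' Generate an idealised sprint ensemble
#'
#' Emits arrival points of the exact FS closed form for a single initial
#' speed: `n_directions` driving directions evenly spaced on the circle, each
#' held constant for `delta_t` seconds from initial velocity `(v0, 0)`.
#' The output is already in the velocity frame (start at the origin, initial
#' velocity along +x), so the noise-free points lie exactly on the arrival
#' circle with centre `(A v0, 0)` and radius `B`. Optional Gaussian noise
#' (sd `noise_sigma` per axis) is added to the arrival positions only,
#' emulating tracking error on the later sample.
#'
#' This is the idealised input for validating the heat-map and
#' circle-estimation stages against the closed form.
#'
#' @param params A [kinetic_params()] object.
#' @param v0 Initial speed, m/s; non-negative.
#' @param delta_t Arrival interval, s; positive.
#' @param n_directions Number of directions; at least 1.
#' @param noise_sigma Arrival-point noise sd, m; default 0 (exact).
#' @param seed Optional integer seed (used only when `noise_sigma > 0`).
#' @return A tibble with columns `angle` (rad), `v0`, `ax`, `ay`
#'   (velocity-frame arrival coordinates, m).
#' @examples
#' ens <- generate_sprint_ensemble(kinetic_params(1.23, 14.53), v0 = 6,
#'                                 delta_t = 1, n_directions = 8)
#' @export
generate_sprint_ensemble <- function(params, v0, delta_t, n_directions = 720,
                                     noise_sigma = 0, seed = NULL) {
  params <- as_kinetic_params(params)
  stopifnot(is.numeric(v0), length(v0) == 1L, v0 >= 0,
            is.numeric(delta_t), length(delta_t) == 1L, delta_t > 0,
            is.numeric(n_directions), length(n_directions) == 1L,
            n_directions >= 1, noise_sigma >= 0)
  angles <- 2 * pi * (seq_len(n_directions) - 1) / n_directions
  a <- coef_A(params$alpha, delta_t)
  b <- coef_B(params, delta_t)
  ax <- a * v0 + b * cos(angles)
  ay <- b * sin(angles)
  if (noise_sigma > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    ax <- ax + stats::rnorm(n_directions, 0, noise_sigma)
    ay <- ay + stats::rnorm(n_directions, 0, noise_sigma)
  }
  tibble::tibble(angle = angles, v0 = v0, ax = ax, ay = ay)
}
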