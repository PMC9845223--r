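test_that("generation is a deterministic function of the seed", {
  a <- small_dataset(seed = 9L)
  b <- small_dataset(seed = 9L)
  expect_identical(a, b)
  c <- small_dataset(seed = 10L)
  expect_false(identical(a$x_m, c$x_m))
})

test_that("dataset structure follows the tracking schema", {
  trk <- small_dataset()
  expect_named(trk, c("segment_id", "time_s", "player_id", "team", "role",
                      "x_m", "y_m"))
  expect_setequal(unique(trk$role), c("OUT", "GK"))
  expect_equal(dplyr::n_distinct(trk$player_id), 5)  # 3 outfield + 2 GK
  expect_equal(dplyr::n_distinct(trk$player_id[trk$role == "GK"]), 2)
})

test_that("per-series timestamps are uniform at the sampling interval", {
  trk <- small_dataset()
  steps <- trk |>
    dplyr::group_by(segment_id, player_id) |>
    dplyr::summarise(ok = all(abs(diff(time_s) - 0.04) < 1e-9),
                     .groups = "drop")
  expect_true(all(steps$ok))
})

test_that("single-state noise-free generation follows the closed form", {
  # one behavioural state at terminal speed, no direction changes within
  # the segment: motion must be exactly uniform and linear
  st <- behaviour_states(alpha = 1.3, vmax = c(walk = 4, jog = 4, sprint = 4),
                         dwell_mean = c(walk = 1e6, jog = 1e6, sprint = 1e6))
  cfg <- tracking_config(n_outfield = 1, include_goalkeeper = FALSE,
                         n_segments = 1, segment_duration = 20,
                         states = st, mean_run_duration = 1e6,
                         noise_sigma = 0, seed = 3L)
  trk <- generate_tracking(cfg)
  # state switches keep vmax = 4, so velocity never changes magnitude or,
  # absent direction events, direction: displacement is linear in t
  d <- sqrt((trk$x_m - trk$x_m[1])^2 + (trk$y_m - trk$y_m[1])^2)
  expect_equal(d, 4 * trk$time_s, tolerance = 1e-9)
})

test_that("generated speeds are bimodal near the walking and jogging peaks", {
  trk <- match_dataset()
  vel <- match_velocity()
  spd <- speed_distribution(vel, "OUT", bin_width = 0.2)
  dens <- spd$density
  peaks <- spd$bin_mid[which(dens > dplyr::lag(dens, default = 0) &
                               dens > dplyr::lead(dens, default = 0))]
  top2 <- sort(head(peaks[order(-dens[match(peaks, spd$bin_mid)])], 2))
  expect_lt(abs(top2[1] - 1), 0.5)
  expect_lt(abs(top2[2] - 3), 0.5)
})

test_that("outfield speed distribution decays log-linearly beyond the jog peak", {
  spd <- speed_distribution(match_velocity(), "OUT", bin_width = 0.25)
  tail <- dplyr::filter(spd, bin_mid >= 3.5, bin_mid <= 5, density > 0)
  fit <- stats::lm(log(density) ~ bin_mid, data = tail)
  expect_lt(stats::coef(fit)[2], -0.5)            # clearly decaying
  expect_gt(summary(fit)$r.squared, 0.95)         # close to log-linear
  # and the distribution dies out beyond the sprint terminal speed
  expect_lt(sum(spd$density[spd$bin_mid > 9.5]) * 0.25, 0.01)
})

test_that("noise has the configured scale and is seed-reproducible", {
  base <- small_dataset(noise = 0)
  expect_identical(add_noise(base, 0), base)
  n1 <- add_noise(base, 0.5, seed = 21L)
  n2 <- add_noise(base, 0.5, seed = 21L)
  expect_identical(n1, n2)
  off <- n1$x_m - base$x_m
  expect_equal(stats::sd(off), 0.5, tolerance = 0.04)
  expect_equal(mean(off), 0, tolerance = 0.02)
  # ~95% of per-axis errors within +-1 m
  expect_gt(mean(abs(off) <= 1), 0.93)
  expect_error(add_noise(base, -0.1), "non-negative")
  disc <- add_noise(base, 0.5, seed = 1L, model = "uniform_disc")
  r <- sqrt((disc$x_m - base$x_m)^2 + (disc$y_m - base$y_m)^2)
  expect_lte(max(r), 1 + 1e-12)
})

test_that("sprint ensembles lie exactly on the arrival circle", {
  p <- kinetic_params(1.23, 14.53)
  ens <- generate_sprint_ensemble(p, v0 = 6, delta_t = 1, n_directions = 720)
  a <- coef_A(1.23, 1)
  b <- coef_B(p, 1)
  r <- sqrt((ens$ax - a * 6)^2 + ens$ay^2)
  expect_equal(r, rep(b, 720), tolerance = 1e-12)
  # standing start: every later position at distance B from the origin
  ens0 <- generate_sprint_ensemble(p, v0 = 0, delta_t = 2, n_directions = 90)
  expect_equal(sqrt(ens0$ax^2 + ens0$ay^2), rep(coef_B(p, 2), 90),
               tolerance = 1e-12)
  # with noise, 95% of radial deviations within +-1 m by construction
  ensn <- generate_sprint_ensemble(p, v0 = 6, delta_t = 1,
                                   n_directions = 4000, noise_sigma = 0.5,
                                   seed = 8L)
  rn <- sqrt((ensn$ax - a * 6)^2 + ensn$ay^2)
  expect_gt(mean(abs(rn - b) <= 1), 0.93)
})

test_that("invalid generator configurations name the offending fields", {
  expect_error(tracking_config(n_outfield = 0), "n_outfield")
  expect_error(tracking_config(segment_duration = 1), "segment_duration")
  expect_error(tracking_config(noise_sigma = -1), "noise_sigma")
  expect_error(tracking_config(n_outfield = -1, noise_sigma = -1),
               "n_outfield, noise_sigma")
  expect_error(behaviour_states(transition = diag(3)), "diagonal|stochastic")
})

test_that("pitch bounds confine positions and redirect near the edge", {
  cfg <- tracking_config(n_outfield = 2, include_goalkeeper = FALSE,
                         n_segments = 1, segment_duration = 120,
                         pitch_bounds = c(-20, 20, -15, 15),
                         start_box = c(-20, 20, -15, 15),
                         noise_sigma = 0, seed = 12L)
  trk <- generate_tracking(cfg)
  expect_true(all(trk$x_m >= -20 & trk$x_m <= 20))
  expect_true(all(trk$y_m >= -15 & trk$y_m <= 15))
})
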