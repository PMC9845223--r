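# Shared fixtures, built in code. The match-scale dataset (20 outfield
# players, 60 minutes) is expensive, so it is generated once per test run
# and cached for every test that needs it.

.fixture_cache <- new.env(parent = emptyenv())

# Default study-scale dataset: 20 outfield + 2 GK, 12 x 300 s, sprint
# alpha = 1.3 1/s, V_max = 8 m/s, noise sigma = 0.5 m.
match_dataset <- function() {
  if (is.null(.fixture_cache$match)) {
    .fixture_cache$match <- generate_tracking(tracking_config(seed = 101L))
  }
  .fixture_cache$match
}

match_velocity <- function() {
  if (is.null(.fixture_cache$vel)) {
    .fixture_cache$vel <- compute_velocity(match_dataset())
  }
  .fixture_cache$vel
}

# A small fast dataset for plumbing tests.
small_dataset <- function(seed = 5L, noise = 0.5) {
  generate_tracking(tracking_config(
    n_outfield = 3, include_goalkeeper = TRUE, n_segments = 2,
    segment_duration = 60, noise_sigma = noise, seed = seed))
}

# Hand-built noise-free tracking tibble from a position function of time.
tracks_from_path <- function(fun, t_end = 10, dt = 0.04, player = "P01",
                             segment = "S01", role = "OUT") {
  tt <- seq(0, t_end, by = dt)
  xy <- t(vapply(tt, fun, numeric(2)))
  out <- tibble::tibble(segment_id = segment, time_s = tt, player_id = player,
                        team = "A", role = role, x_m = xy[, 1], y_m = xy[, 2])
  attr(out, "sample_interval") <- dt
  out
}
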