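test_that("velocity-frame transform translates, rotates and preserves norms", {
  expect_equal(velocity_frame_point(c(10, 5), c(2, 0), c(14, 5)), c(ax = 4, ay = 0))
  expect_equal(velocity_frame_point(c(10, 5), c(0, 2), c(10, 9)), c(ax = 4, ay = 0))
  expect_equal(velocity_frame_point(c(0, 0), c(1, 1), c(1, 1)),
               c(ax = sqrt(2), ay = 0), tolerance = 1e-12)
  withr::local_seed(17L)
  for (i in 1:50) {
    pos <- stats::rnorm(2, 0, 30)
    vel <- stats::rnorm(2, 0, 4)
    lat <- stats::rnorm(2, 0, 30)
    out <- velocity_frame_point(pos, vel, lat)
    expect_equal(sqrt(sum(out^2)), sqrt(sum((lat - pos)^2)),
                 tolerance = 1e-12)
  }
  expect_error(velocity_frame_point(c(0, 0), c(0, 0), c(1, 1)),
               "zero velocity")
})

test_that("heat-map binning uses half-open origin-anchored cells", {
  pts <- tibble::tibble(v0 = c(3, 3, 3), ax = c(4.05, 4.19, 0.2),
                        ay = c(0.05, 0.12, 0))
  g <- build_heatmap(pts, delta_t = 1, v0_bin = c(2.85, 3.15),
                     cell_size = 0.2)
  expect_equal(g$n_points, 3L)
  expect_equal(sum(g$counts > 0), 2)          # two occupied cells
  # the two points near (4.1, 0.1) share cell [4.0,4.2) x [0.0,0.2)
  expect_equal(max(g$counts), 2)
  # boundary point 0.2 goes to the higher-index cell [0.2, 0.4)
  occ <- which(g$counts > 0, arr.ind = TRUE)
  xs <- (occ[, 1] - 1 + g$ix0) * 0.2
  expect_true(any(abs(xs - 0.2) < 1e-9))
  # all speeds outside the bin: empty but valid
  g0 <- build_heatmap(pts, 1, c(5, 5.3), cell_size = 0.2)
  expect_equal(g0$n_points, 0L)
})

test_that("the c threshold follows the interval schedule", {
  expect_identical(default_c(0.5), 8L)
  expect_identical(default_c(1), 6L)
  expect_identical(default_c(2), 6L)
  expect_identical(default_c(3), 6L)
  expect_identical(default_c(4), 4L)
})

test_that("isolated-cell filtering matches a brute-force neighbour count", {
  brute <- function(occ, c, strict = FALSE) {
    nx <- nrow(occ); ny <- ncol(occ)
    keep <- matrix(FALSE, nx, ny)
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      if (!occ[i, j]) next
      nb <- 0L
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny && occ[ii, jj])
          nb <- nb + 1L
      }
      keep[i, j] <- if (strict) nb > c else nb >= c
    }
    keep
  }
  as_grid <- function(counts, delta_t = 1) {
    structure(list(counts = counts, ix0 = 0L, iy0 = 0L, cell_size = 0.2,
                   delta_t = delta_t, v0_bin = c(0, 0.3),
                   n_points = sum(counts)),
              class = "heatmap_grid")
  }
  withr::local_seed(33L)
  for (rep in 1:6) {
    counts <- matrix(rbinom(30 * 24, 1, 0.45), 30, 24)
    cc <- sample(0:8, 1)
    f <- filter_isolated_cells(as_grid(counts), c = cc)
    expect_identical(f$counts > 0, counts > 0 & brute(counts > 0, cc))
    if (cc <= 7) {
      fs <- filter_isolated_cells(as_grid(counts), c = cc, strict = TRUE)
      expect_identical(fs$counts > 0,
                       counts > 0 & brute(counts > 0, cc, strict = TRUE))
    }
  }
  # full block with c = 8: interior survives, border does not
  block <- matrix(1L, 10, 10)
  fb <- filter_isolated_cells(as_grid(block), c = 8)
  expect_true(all(fb$counts[2:9, 2:9] == 1))
  expect_true(all(fb$counts[c(1, 10), ] == 0))
  expect_true(all(fb$counts[, c(1, 10)] == 0))
  # a single occupied cell is removed for any c >= 1
  single <- matrix(0L, 5, 5); single[3, 3] <- 4L
  expect_true(all(filter_isolated_cells(as_grid(single), 4)$counts == 0))
  # contraction: survivors are a subset of the input occupancy
  expect_true(all((fb$counts > 0) <= (block > 0)))
  # idempotence when the survivor set is stable (filled block, c = 3:
  # even corner cells have 3 neighbours, so everything is kept)
  f3 <- filter_isolated_cells(as_grid(block), c = 3)
  expect_identical(f3$counts, block)
  expect_identical(filter_isolated_cells(f3, c = 3)$counts, block)
  expect_error(filter_isolated_cells(as_grid(block), 9), "\\[0, 8\\]")
  expect_error(filter_isolated_cells(as_grid(block), 8, strict = TRUE),
               "never")
})

test_that("extent circle reproduces direct substitution and rasterised circles", {
  # extents x in [2,10], y in [-4,4] -> centre (6, 0), r = 4; built from
  # cell centres, so supply cells whose centres give those extents
  s <- 0.2
  pts <- tibble::tibble(
    v0 = 1, ax = c(2, 10, 6, 6) - s / 2, ay = c(0, 0, -4, 4) - s / 2)
  g <- build_heatmap(pts, 1, c(0.85, 1.15), cell_size = s)
  cc <- circle_from_extent(g)
  expect_equal(cc$x_c, 6 - s / 2, tolerance = 1e-9)
  expect_equal(cc$y_c, 0 - s / 2, tolerance = 1e-9)
  expect_equal(cc$r_c, 4, tolerance = 1e-9)
  # rasterised circle oracle
  th <- seq(0, 2 * pi, length.out = 2000)
  rho <- 5.3; a <- 2.1
  ptsc <- tibble::tibble(v0 = 1, ax = a + rho * cos(th), ay = rho * sin(th))
  gc <- build_heatmap(ptsc, 1, c(0.85, 1.15), cell_size = s)
  est <- circle_from_extent(gc)
  expect_lt(abs(est$x_c - a), s)
  expect_lt(abs(est$y_c), s)
  expect_lt(abs(est$r_c - rho), s)
  empty <- build_heatmap(ptsc, 1, c(8, 8.3), cell_size = s)
  expect_error(circle_from_extent(empty), "empty")
})

test_that("noise-free sprint ensembles yield the predicted circle per bin", {
  p <- kinetic_params(1.23, 14.53)
  ens <- generate_sprint_ensemble(p, v0 = 6, delta_t = 1, n_directions = 720)
  g <- build_heatmap(ens, 1, c(5.85, 6.15), cell_size = 0.2)
  # every occupied cell centre within one cell of the true circle radius
  occ <- which(g$counts > 0, arr.ind = TRUE)
  cx <- (occ[, 1] - 1 + g$ix0 + 0.5) * 0.2
  cy <- (occ[, 2] - 1 + g$iy0 + 0.5) * 0.2
  r <- sqrt((cx - coef_A(1.23, 1) * 6)^2 + cy^2)
  expect_true(all(abs(r - coef_B(p, 1)) < 0.2 * sqrt(2)))
  est <- circle_from_extent(g)
  expect_lt(abs(est$x_c - 3.452), 0.2)
  expect_lt(abs(est$y_c), 0.2)
  expect_lt(abs(est$r_c - 6.170), 0.2)
})

test_that("arrival points use overlapping windows and exclude goalkeepers", {
  trk <- dplyr::bind_rows(
    tracks_from_path(function(t) c(2 * t, 0), t_end = 4),
    tracks_from_path(function(t) c(0, 3 * t), t_end = 4, player = "P02",
                     role = "GK"))
  v <- compute_velocity(trk)
  pts <- arrival_points(v, delta_t = 1)
  expect_true(all(pts$player_id == "P01"))
  # uniform motion: every window arrives at (v * delta_t, 0) in the frame
  expect_equal(pts$ax, rep(2, nrow(pts)), tolerance = 1e-9)
  expect_equal(pts$ay, rep(0, nrow(pts)), tolerance = 1e-9)
  # overlapping windows at the native rate: (4 - 1 - 1) s of starts + 1
  expect_equal(nrow(pts), sum(v$player_id == "P01") - 25)
  expect_error(arrival_points(v, delta_t = 0.03), "multiple")
})
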