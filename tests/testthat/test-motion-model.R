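test_that("coefficient A matches direct evaluation and its limits", {
  expect_equal(coef_A(2.7, 0), 0)
  expect_equal(coef_A(1.23, 1), 0.575371888064342, tolerance = 1e-12)
  # alpha -> 0 limit approaches t without cancellation
  expect_equal(coef_A(1e-10, 3), 3, tolerance = 1e-9)
  expect_lt(coef_A(0.5, 2), 2)
  expect_lt(coef_A(0.5, 2), 1 / 0.5)
  expect_error(coef_A(-1, 1), "positive")
  expect_error(coef_A(1, -0.1), "non-negative")
})

test_that("coefficient B matches direct evaluation and starts at zero", {
  p1 <- kinetic_params(1.23, 14.53)
  expect_equal(coef_B(p1, 0), 0)
  expect_equal(coef_B(p1, 1), 6.16984646642511, tolerance = 1e-12)
  expect_equal(coef_B(kinetic_params(1.04, 11.19), 2), 12.9645856485597,
               tolerance = 1e-12)
  expect_error(coef_B(p1, -1), "non-negative")
})

test_that("A and B are monotone in their arguments", {
  alphas <- seq(0.1, 10, length.out = 40)
  expect_true(all(diff(coef_A(alphas, 1.7)) < 0))
  tt <- seq(0.1, 6, length.out = 40)
  expect_true(all(diff(coef_A(0.9, tt)) > 0))
  expect_true(all(diff(coef_B(kinetic_params(0.9, 5), tt)) > 0))
  vs <- seq(1, 12, length.out = 20)
  bb <- vapply(vs, function(v) coef_B(kinetic_params(0.9, v), 2), numeric(1))
  expect_true(all(diff(bb) > 0))
})

test_that("arrival points lie on the arrival circle for every direction", {
  p <- kinetic_params(1.23, 14.53)
  v0 <- c(5, -2)
  t <- 1.4
  circ <- arrival_circle(v0, p, t)
  ang <- 2 * pi * (0:359) / 360
  for (i in seq(1, 360, by = 17)) {
    pt <- arrival_point(v0, c(cos(ang[i]), sin(ang[i])), p, t)
    expect_equal(sqrt(sum((pt - c(circ$center_x, circ$center_y))^2)),
                 circ$radius, tolerance = 1e-12)
  }
  # spec'd closed-form spot values
  expect_equal(arrival_point(c(5, 0), c(-1, 0), p, 1),
               c(0.575371888 * 5 - 6.169846466, 0), tolerance = 1e-8)
  c2 <- arrival_circle(c(6, 0), p, 1)
  expect_equal(c(c2$center_x, c2$center_y, c2$radius),
               c(3.45223133, 0, 6.16984647), tolerance = 1e-7)
  # steady state: sprinting at terminal speed gives uniform linear motion
  expect_equal(arrival_point(c(14.53, 0), c(1, 0), p, 3), c(14.53 * 3, 0),
               tolerance = 1e-10)
  # standing start moves exactly B along the driving direction
  expect_equal(arrival_point(c(0, 0), c(0, 1), p, 2), c(0, coef_B(p, 2)))
  expect_error(arrival_point(c(1, 0), c(1, 1), p, 1), "unit vector")
})

test_that("alpha inversion is the exact inverse of A", {
  expect_equal(invert_alpha(coef_A(1.5, 2), 2), 1.5, tolerance = 1e-9)
  expect_equal(invert_alpha(0.58, 1), 1.21000965, tolerance = 1e-6)
  expect_equal(invert_alpha(0.84, 2), 1.04248796, tolerance = 1e-6)
  for (alpha in c(0.1, 0.7, 3, 10)) {
    for (t in c(0.2, 1, 5)) {
      expect_equal(invert_alpha(coef_A(alpha, t), t), alpha,
                   tolerance = 1e-6)
    }
  }
  expect_error(invert_alpha(2.5, 2), "< t")
  expect_error(invert_alpha(0, 2), "positive")
})

test_that("terminal-speed inversion round-trips B", {
  expect_equal(vmax_from_radius(0, 1.3, 2), 0)
  expect_equal(vmax_from_radius(6.16, 1.23, 1), 14.5068116, tolerance = 1e-6)
  expect_equal(vmax_from_radius(12.94, 1.04, 2), 11.1687796, tolerance = 1e-6)
  p <- kinetic_params(0.77, 9.3)
  expect_equal(vmax_from_radius(coef_B(p, 1.6), p$alpha, 1.6), p$vmax,
               tolerance = 1e-9)
  expect_error(vmax_from_radius(-1, 1.3, 1), "non-negative")
})

test_that("RK4 integration reproduces the closed form and its limits", {
  # constant coefficients: closed-form oracle
  m <- 70
  alpha <- 1.3
  vmax <- 7.8
  mod <- extended_model(m, force = m * alpha * vmax, drag = m * alpha,
                        direction = c(1, 0))
  tr <- simulate_motion(mod, v0 = c(2, 0), t_end = 5, dt = 1e-3)
  cf <- arrival_point(c(2, 0), c(1, 0), kinetic_params(alpha, vmax), 5)
  expect_lt(max(abs(c(tr$x[nrow(tr)], tr$y[nrow(tr)]) - cf)), 1e-8)
  # drag-only limit: speed decays, position -> x0 + v0 / alpha
  mod0 <- extended_model(m, force = 0, drag = m * alpha, direction = c(1, 0))
  tr0 <- simulate_motion(mod0, v0 = c(3, 1), t_end = 15, dt = 1e-3)
  expect_lt(sqrt(tr0$vx[nrow(tr0)]^2 + tr0$vy[nrow(tr0)]^2), 1e-6)
  expect_equal(c(tr0$x[nrow(tr0)], tr0$y[nrow(tr0)]), c(3, 1) / alpha,
               tolerance = 1e-6)
  # terminal state: v0 = vmax * n gives uniform linear motion
  trs <- simulate_motion(mod, v0 = c(vmax, 0), t_end = 2, dt = 1e-3)
  expect_equal(trs$x, vmax * trs$time, tolerance = 1e-9)
  # direction is normalised defensively at each evaluation
  mod2 <- extended_model(m, force = m * alpha * vmax, drag = m * alpha,
                         direction = function(t) c(2, 0))
  tr2 <- simulate_motion(mod2, v0 = c(2, 0), t_end = 1, dt = 1e-3)
  expect_equal(tr2$x[nrow(tr2)], tr$x[tr$time == 1], tolerance = 1e-12)
})

test_that("time-varying coefficients are integrated and validated", {
  m <- 70
  # k(t) ramps: no closed form needed, just finiteness and direction
  mod <- extended_model(m, force = function(t) 500 + 50 * t,
                        drag = function(t) 60 + 10 * t)
  tr <- simulate_motion(mod, t_end = 3, dt = 1e-3)
  expect_true(all(is.finite(c(tr$x, tr$vx))))
  expect_true(all(diff(tr$x) > 0))
  bad <- extended_model(m, force = function(t) ifelse(t > 1, NaN, 100),
                        drag = 60)
  expect_error(simulate_motion(bad, t_end = 2, dt = 0.01), "non-finite")
})
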