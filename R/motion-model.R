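#' Kinetic parameters of the Fujimura–Sugihara sprint model
#'
#' The Fujimura–Sugihara (FS) model describes a sprinting player by the
#' equation of motion \eqn{m \ddot{x} = F n - k \dot{x}}: a constant-magnitude
#' driving force along a unit direction \eqn{n}, opposed by viscous resistance
#' proportional to velocity. Only two combinations of \eqn{m}, \eqn{F}, \eqn{k}
#' are identifiable from trajectories: the drag-to-mass ratio
#' \eqn{\alpha = k/m} (1/s) and the terminal sprint speed
#' \eqn{V_{max} = F/k} (m/s). These are the model's "kinetic parameters".
#'
#' @param alpha Drag-to-mass ratio \eqn{\alpha} in 1/s; must be positive.
#' @param vmax Terminal sprint speed \eqn{V_{max}} in m/s; must be positive.
#'
#' @return An object of class `kinetic_params`: a named list with elements
#'   `alpha` and `vmax`.
#' @examples
#' kinetic_params(alpha = 1.3, vmax = 7.8)
#' @export
kinetic_params <- function(alpha, vmax) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a single positive finite number (1/s).", call. = FALSE)
  }
  if (!is.numeric(vmax) || length(vmax) != 1L || !is.finite(vmax) || vmax <= 0) {
    stop("`vmax` must be a single positive finite number (m/s).", call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), vmax = as.numeric(vmax)),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> alpha = %.4g 1/s, vmax = %.4g m/s\n",
              x$alpha, x$vmax))
  invisible(x)
}

as_kinetic_params <- function(params) {
  if (inherits(params, "kinetic_params")) return(params)
  if (is.list(params) && all(c("alpha", "vmax") %in% names(params))) {
    return(kinetic_params(params$alpha, params$vmax))
  }
  stop("`params` must be a `kinetic_params` object (see `kinetic_params()`).",
       call. = FALSE)
}

#' Velocity-decay coefficient A of the FS closed form
#'
#' The closed-form solution of the FS model from initial position
#' \eqn{x_0 = (0,0)} and initial velocity \eqn{v_0} is
#' \deqn{x(t) = A(\alpha, t)\, v_0 + B(\alpha, V_{max}, t)\, n,}
#' with \eqn{A(\alpha, t) = (1 - e^{-\alpha t}) / \alpha}. `A` has units of
#' seconds, satisfies \eqn{0 \le A < \min(t, 1/\alpha)} for \eqn{t > 0}, and is
#' strictly decreasing in `alpha` and increasing in `t`. It is evaluated via
#' `expm1()` so that the \eqn{\alpha \to 0} limit (`A -> t`) is reached without
#' cancellation — the parameter inversion probes brackets near zero.
#'
#' @param alpha Drag-to-mass ratio, 1/s; positive (vectorised).
#' @param t Time, s; non-negative (vectorised).
#' @return `A(alpha, t)`, numeric.
#' @seealso [coef_B()], [invert_alpha()]
#' @examples
#' coef_A(1.23, 1)  # 0.5753706...
#' @export
coef_A <- function(alpha, t) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("`alpha` must be positive and finite.", call. = FALSE)
  }
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be non-negative and finite.", call. = FALSE)
  }
  -expm1(-alpha * t) / alpha
}

#' Sprint-reach coefficient B of the FS closed form
#'
#' \eqn{B(\alpha, V_{max}, t) = V_{max}\,(t - A(\alpha, t))} is the distance
#' (m) a player gains along the driving direction in `t` seconds — the radius
#' of the arrival circle. `B` is zero at `t = 0`, strictly increasing in `t`
#' and in `vmax`, and asymptotically linear with slope `vmax`.
#'
#' @param params A [kinetic_params()] object.
#' @param t Time, s; non-negative (vectorised).
#' @return `B(alpha, vmax, t)`, numeric, metres.
#' @examples
#' coef_B(kinetic_params(1.23, 14.53), 1)  # 6.1699...
#' @export
coef_B <- function(params, t) {
  params <- as_kinetic_params(params)
  params$vmax * (t - coef_A(params$alpha, t))
}

#' Arrival point of the FS model
#'
#' Evaluates the closed form \eqn{x(t) = A v_0 + B n} for one initial
#' velocity and driving direction. The point lies at distance exactly
#' \eqn{B} from the circle centre \eqn{A v_0}.
#'
#' @param v0 Initial velocity, numeric length-2 vector (m/s).
#' @param n_hat Driving direction, numeric length-2 unit vector.
#' @param params A [kinetic_params()] object.
#' @param t Time, s.
#' @param tol Tolerance on `|n_hat| - 1`; default `1e-6`.
#' @return Numeric length-2 position (m), relative to the start.
#' @examples
#' arrival_point(c(5, 0), c(-1, 0), kinetic_params(1.23, 14.53), 1)
#' @export
arrival_point <- function(v0, n_hat, params, t, tol = 1e-6) {
  params <- as_kinetic_params(params)
  stopifnot(is.numeric(v0), length(v0) == 2L, is.numeric(n_hat),
            length(n_hat) == 2L, length(t) == 1L)
  nrm <- sqrt(sum(n_hat^2))
  if (abs(nrm - 1) > tol) {
    stop(sprintf("`n_hat` must be a unit vector (|n_hat| = %.6g).", nrm),
         call. = FALSE)
  }
  coef_A(params$alpha, t) * v0 + coef_B(params, t) * n_hat
}

#' Arrival circle of the FS model
#'
#' Sweeping the driving direction over all angles, the arrival points after
#' `t` seconds lie on a circle with centre \eqn{A(\alpha,t)\,v_0} and radius
#' \eqn{B(\alpha,V_{max},t)} — the locus of positions reachable by an
#' all-out sprint in every direction.
#'
#' @inheritParams arrival_point
#' @return A one-row tibble with columns `center_x`, `center_y` (m),
#'   `radius` (m) and `delta_t` (s).
#' @examples
#' arrival_circle(c(6, 0), kinetic_params(1.23, 14.53), 1)
#' @export
arrival_circle <- function(v0, params, t) {
  params <- as_kinetic_params(params)
  stopifnot(is.numeric(v0), length(v0) == 2L, length(t) == 1L)
  a <- coef_A(params$alpha, t)
  tibble::tibble(center_x = a * v0[1], center_y = a * v0[2],
                 radius = coef_B(params, t), delta_t = as.numeric(t))
}

#' Invert the coefficient A for the drag-to-mass ratio
#'
#' In the FS model the arrival-circle centre grows as \eqn{x_c = A(\alpha, t)
#' v_0}, so a measured proportionality coefficient (`slope`, in seconds)
#' between centre and initial speed determines \eqn{\alpha}. Since
#' \eqn{A(\cdot, t)} is strictly decreasing with range \eqn{(0, t)}, the root
#' of \eqn{A(\alpha, t) = slope} is unique and is found by bracketed
#' bisection (`uniroot`) on \eqn{\alpha \in [10^{-8}, 10^{3}]}, widening the
#' upper bracket if needed.
#'
#' @param slope Measured coefficient of `v0`, in seconds; must lie in
#'   `(0, t)`.
#' @param t Time horizon (the heat-map interval), s; positive.
#' @param tol Convergence tolerance on `alpha`; default `1e-12`.
#' @return The drag-to-mass ratio `alpha` (1/s) with
#'   `coef_A(alpha, t) == slope` to within `1e-9`.
#' @examples
#' invert_alpha(0.58, 1)   # ~1.211
#' invert_alpha(0.84, 2)   # ~1.042
#' @export
invert_alpha <- function(slope, t, tol = 1e-12) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.numeric(t),
            length(t) == 1L, is.finite(slope), is.finite(t), t > 0)
  if (slope <= 0) {
    stop("`slope` must be positive: A(alpha, t) > 0 for all alpha > 0.",
         call. = FALSE)
  }
  if (slope >= t) {
    stop(sprintf(
      "`slope` (%.6g) must be < t (%.6g): A(alpha, t) < t for alpha > 0.",
      slope, t), call. = FALSE)
  }
  lower <- 1e-8
  upper <- 1e3
  while (coef_A(upper, t) > slope) upper <- upper * 10
  root <- stats::uniroot(function(a) coef_A(a, t) - slope,
                         lower = lower, upper = upper, tol = tol)$root
  root
}

#' Terminal speed from the arrival-circle radius
#'
#' Inverts \eqn{B = V_{max} (t - A(\alpha, t))}: given a measured circle
#' radius `r_c` and an already-estimated `alpha`, the terminal speed is
#' \eqn{V_{max} = r_c / (t - A(\alpha, t))}. The denominator is strictly
#' positive for `alpha > 0`, `t > 0`.
#'
#' @param r_c Circle radius, m; non-negative.
#' @param alpha Drag-to-mass ratio, 1/s; positive.
#' @param t Time horizon, s; positive.
#' @return Terminal speed `vmax`, m/s.
#' @examples
#' vmax_from_radius(6.16, 1.23, 1)    # ~14.51
#' vmax_from_radius(12.94, 1.04, 2)   # ~11.17
#' @export
vmax_from_radius <- function(r_c, alpha, t) {
  stopifnot(is.numeric(r_c), is.numeric(alpha), is.numeric(t),
            length(t) == 1L, t > 0)
  if (any(r_c < 0)) stop("`r_c` must be non-negative.", call. = FALSE)
  r_c / (t - coef_A(alpha, t))
}

#' Variable-coefficient extension of the FS model
#'
#' Specifies the generalised equation of motion
#' \eqn{m \ddot{x}(t) = F(t) n(t) - k(t) \dot{x}(t)} in which the driving
#' force magnitude, drag coefficient and driving direction may vary with
#' time. With constant coefficients it reduces to the standard FS model.
#'
#' @param mass Player mass `m`, kg; positive scalar.
#' @param force Driving force magnitude `F(t)`, N: a non-negative scalar or a
#'   function of time.
#' @param drag Drag coefficient `k(t)`, N s/m: a positive scalar or a
#'   function of time.
#' @param direction Driving direction `n(t)`: a length-2 vector or a function
#'   of time returning one. It is re-normalised to unit length at every
#'   evaluation, so user-supplied callables need not return exact unit
#'   vectors.
#' @return An object of class `extended_model`.
#' @examples
#' extended_model(mass = 70, force = 70 * 1.3 * 7.8, drag = 70 * 1.3,
#'                direction = c(1, 0))
#' @export
extended_model <- function(mass, force, drag, direction = c(1, 0)) {
  stopifnot(is.numeric(mass), length(mass) == 1L, is.finite(mass), mass > 0)
  as_fun <- function(x, what, check) {
    if (is.function(x)) {
      return(x)
    }
    check(x, what)
    function(t) x
  }
  chk_force <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
      stop(sprintf("`%s` must be a non-negative finite scalar or a function.", what),
           call. = FALSE)
  }
  chk_drag <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("`%s` must be a positive finite scalar or a function.", what),
           call. = FALSE)
  }
  chk_dir <- function(x, what) {
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
        sum(x^2) == 0)
      stop(sprintf("`%s` must be a non-zero length-2 vector or a function.", what),
           call. = FALSE)
  }
  structure(list(mass = mass,
                 force = as_fun(force, "force", chk_force),
                 drag = as_fun(drag, "drag", chk_drag),
                 direction = as_fun(direction, "direction", chk_dir)),
            class = "extended_model")
}

#' Numerically integrate the (extended) FS equation of motion
#'
#' Integrates \eqn{m \ddot{x} = F(t) n(t) - k(t) \dot{x}} with a classical
#' fixed-step 4th-order Runge–Kutta scheme (via [deSolve::ode()],
#' `method = "rk4"`), chosen for bit-reproducibility over adaptive stepping.
#' With constant coefficients the result matches the closed form
#' ([arrival_point()]) to better than 1e-6 m over 10 s at `dt = 1e-4` —
#' the correctness oracle for this integrator.
#'
#' @param model An [extended_model()] specification.
#' @param x0,v0 Initial position and velocity, length-2 numeric vectors
#'   (m and m/s). Defaults: origin, at rest.
#' @param t_end Integration horizon, s; non-negative.
#' @param dt Fixed step size, s; positive.
#' @return A tibble with columns `time`, `x`, `y`, `vx`, `vy`.
#' @examples
#' m <- extended_model(70, force = 70 * 1.3 * 7.8, drag = 70 * 1.3)
#' tail(simulate_motion(m, v0 = c(2, 0), t_end = 2, dt = 0.01), 1)
#' @export
simulate_motion <- function(model, x0 = c(0, 0), v0 = c(0, 0), t_end, dt = 1e-3) {
  stopifnot(inherits(model, "extended_model"),
            is.numeric(x0), length(x0) == 2L,
            is.numeric(v0), length(v0) == 2L,
            length(t_end) == 1L, t_end >= 0, length(dt) == 1L, dt > 0)
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end - 1e-12) times <- c(times, t_end)
  deriv <- function(t, state, parms) {
    f <- model$force(t)
    k <- model$drag(t)
    n <- model$direction(t)
    if (!all(is.finite(c(f, k, n))) || k <= 0) {
      stop(sprintf("non-finite or invalid coefficients at t = %.6g", t),
           call. = FALSE)
    }
    n <- n / sqrt(sum(n^2))
    list(c(state[3], state[4],
           (f * n[1] - k * state[3]) / model$mass,
           (f * n[2] - k * state[4]) / model$mass))
  }
  out <- deSolve::ode(y = c(x = x0[1], y = x0[2], vx = v0[1], vy = v0[2]),
                      times = times, func = deriv, parms = NULL,
                      method = "rk4")
  tibble::tibble(time = out[, "time"], x = out[, "x"], y = out[, "y"],
                 vx = out[, "vx"], vy = out[, "vy"])
}

# Exact one-interval propagation of the constant-coefficient FS model:
# returns position and velocity after dt given current pos/vel, direction
# n (unit), alpha and vmax. Vectorised over dt. Used by the generator so
# sprint intervals satisfy the closed form exactly per straight run.
fs_propagate <- function(pos, vel, n_hat, alpha, vmax, dt) {
  a <- coef_A(alpha, dt)
  decay <- exp(-alpha * dt)
  b <- vmax * (dt - a)
  list(
    x = pos[1] + a * vel[1] + b * n_hat[1],
    y = pos[2] + a * vel[2] + b * n_hat[2],
    vx = vel[1] * decay + vmax * (1 - decay) * n_hat[1],
    vy = vel[2] * decay + vmax * (1 - decay) * n_hat[2]
  )
}
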