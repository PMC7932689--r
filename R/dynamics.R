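#' Time derivative of the ARSLIP state
#'
#' Equations of motion of the ARSLIP point mass in polar coordinates,
#' from the Euler-Lagrange equations:
#' \deqn{\ddot r = r \dot\theta^2 + (k_s/m)(R - r) - g \cos\theta}
#' \deqn{\ddot\theta = -2 \dot\theta \dot r / r - k_a \theta / (m r^2) + (g/r) \sin\theta}
#' With `k_a = 0` this is exactly the SLIP system.
#'
#' @param state A [com_state()].
#' @param p An [arslip_params()].
#' @return A named numeric vector `(r_dot, theta_dot, r_ddot, theta_ddot)`.
#' @export
arslip_derivatives <- function(state, p) {
  stopifnot(inherits(state, "com_state"), inherits(p, "arslip_params"))
  r <- state$r; th <- state$theta; rd <- state$r_dot; thd <- state$theta_dot
  if (r <= 0)
    stop("arslip_derivatives: r <= 0 (singular)", call. = FALSE)
  c(r_dot = rd,
    theta_dot = thd,
    r_ddot = r * thd^2 + p$k_s / p$m * (p$R - r) - p$g * cos(th),
    theta_ddot = -2 * thd * rd / r - p$k_a * th / (p$m * r^2) +
      p$g / r * sin(th))
}

#' Total mechanical energy of the ARSLIP system
#'
#' Kinetic plus elastic plus gravitational energy (gravitational
#' reference at the foothold):
#' `E = m/2 (r_dot^2 + r^2 theta_dot^2) + k_s/2 (R - r)^2 + k_a/2 theta^2 + m g r cos(theta)`.
#' The system is conservative, so `E` is constant along any trajectory;
#' the integrator is verified against this invariant.
#'
#' @inheritParams arslip_derivatives
#' @return Energy (J).
#' @export
total_energy <- function(state, p) {
  stopifnot(inherits(state, "com_state"), inherits(p, "arslip_params"))
  0.5 * p$m * (state$r_dot^2 + state$r^2 * state$theta_dot^2) +
    arslip_potential(state, p) +
    p$m * p$g * state$r * cos(state$theta)
}

# integrate the ARSLIP/SLIP ODEs with the compiled right-hand side.
# y0 = c(r, theta, r_dot, theta_dot); times need not start at 0.
# Returns the deSolve matrix; signals a "fall" condition as an error of
# class "arslip_fall" when the leg collapses or |theta| reaches pi/2.
integrate_arslip <- function(y0, times, p, rtol = 1e-10, atol = 1e-12) {
  t0 <- times[1]
  out <- deSolve::ode(
    y = unname(y0), times = times - t0, func = "arslip_derivs",
    parms = c(p$k_s, p$k_a, p$R, p$m, p$g),
    dllname = "arslip", initfunc = "arslip_init",
    rootfunc = "arslip_root", nroot = 2,
    method = "lsodar", rtol = rtol, atol = atol)
  if (nrow(out) < length(times)) {
    troot <- attr(out, "troot")
    cnd <- structure(
      class = c("arslip_fall", "error", "condition"),
      list(message = sprintf("fall during integration at t = %g s",
                             t0 + troot[1]),
           call = NULL, time = t0 + troot[1]))
    stop(cnd)
  }
  out[, 1] <- out[, 1] + t0
  colnames(out) <- c("time", "r", "theta", "r_dot", "theta_dot")
  out
}

# build a com_trajectory data.frame from an integration matrix
as_com_trajectory <- function(out) {
  r <- out[, "r"]; th <- out[, "theta"]
  rd <- out[, "r_dot"]; thd <- out[, "theta_dot"]
  traj <- data.frame(
    t = out[, "time"],
    x = r * sin(th),
    z = r * cos(th),
    v = rd * sin(th) + r * cos(th) * thd,   # horizontal speed dx/dt
    r = r, theta = th, r_dot = rd, theta_dot = thd)
  class(traj) <- c("com_trajectory", "data.frame")
  traj
}

#' Simulate one ARSLIP (or SLIP) stance phase
#'
#' Integrates the equations of motion from touch-down initial conditions
#' and returns the CoM track sampled exactly at `t_grid`.  The state at
#' `t_grid[1]` is `(r0, -alpha, r_dot0, theta_dot0)`: the leg points
#' backwards at the angle of attack and swings forwards through
#' mid-stance.  Uses an adaptive-step integrator (relative tolerance
#' 1e-10, absolute 1e-12) whose accuracy is audited through the drift of
#' [total_energy()] (kept below 1e-8 relative).
#'
#' @param p An [arslip_params()] (`k_a = 0` for SLIP).
#' @param ic An [initial_conditions()].
#' @param t_grid Strictly increasing time samples (s).
#' @return A `com_trajectory` data.frame with columns `t`, `x`, `z`, `v`
#'   (horizontal position/height/speed; `x` relative to the foothold)
#'   plus the polar state columns `r`, `theta`, `r_dot`, `theta_dot`.
#'   Errors with a "fall" condition if the leg collapses or `|theta|`
#'   reaches pi/2 before the end of `t_grid`.
#' @examples
#' p <- arslip_params(k_s = 0.009, k_a = 1.1e-8, R = 2.042e-3, m = 1.123e-6)
#' ic <- initial_conditions(alpha = 0.3, r0 = 1.9e-3, theta_dot0 = 12)
#' traj <- simulate_step(p, ic, seq(0, 0.04, by = 1/380))
#' @export
simulate_step <- function(p, ic, t_grid) {
  stopifnot(inherits(p, "arslip_params"), inherits(ic, "step_ic"))
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("simulate_step: t_grid must be strictly increasing", call. = FALSE)
  y0 <- c(ic$r0, -ic$alpha, ic$r_dot0, ic$theta_dot0)
  as_com_trajectory(integrate_arslip(y0, t_grid, p))
}

#' Simulate a mid-stance-anchored, time-symmetric step
#'
#' Starts the CoM exactly at mid-stance (`theta = 0`, `r = r_m`,
#' `r_dot = 0`) with dimensionless angular speed `Omega`
#' (`theta_dot = Omega sqrt(g/R)`) and extends the trajectory
#' `half_duration` both forwards and backwards in time.  Because the
#' system is conservative and mirror-symmetric in `theta`, the backward
#' half is the time-reflection of the forward half with `theta` and `x`
#' negated, so height and horizontal speed are exactly even in time.
#' This is the probe used for the fly-like / cockroach-like regime
#' classification: the sign of `v(dt) - v(0)` tells whether mid-stance
#' is a speed maximum or minimum.
#'
#' @param p An [arslip_params()].
#' @param r_m Mid-stance leg length (m).
#' @param Omega Dimensionless mid-stance angular speed.
#' @param half_duration Half window length (s).
#' @param n Number of samples per half (default 200).
#' @return A `com_trajectory` data.frame spanning `[-half_duration,
#'   half_duration]`.
#' @export
simulate_symmetric_step <- function(p, r_m, Omega, half_duration, n = 200) {
  stopifnot(inherits(p, "arslip_params"), r_m > 0, half_duration > 0)
  t_half <- seq(0, half_duration, length.out = n + 1)
  y0 <- c(r_m, 0, 0, Omega * sqrt(p$g / p$R))
  fwd <- integrate_arslip(y0, t_half, p)
  # mirror: t -> -t, theta -> -theta, r_dot -> -r_dot
  bwd <- fwd[-1, , drop = FALSE]
  bwd[, "time"] <- -bwd[, "time"]
  bwd[, "theta"] <- -bwd[, "theta"]
  bwd[, "r_dot"] <- -bwd[, "r_dot"]
  out <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE], fwd)
  as_com_trajectory(out)
}
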