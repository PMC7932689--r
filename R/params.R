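#' Mechanical state of the centre of mass in polar coordinates
#'
#' The CoM of a walking insect supported by one effective leg is described
#' in polar coordinates anchored at the (effective) foothold: the leg
#' length `r`, the leg angle `theta` from the vertical (positive in the
#' walking direction, so `theta = 0` at mid-stance), and their time
#' derivatives.
#'
#' @param r Leg length (m), must be positive.
#' @param theta Leg angle from the vertical (rad).
#' @param r_dot Radial speed (m/s).
#' @param theta_dot Angular speed (rad/s).
#' @return An object of class `com_state`.
#' @examples
#' com_state(r = 2e-3, theta = -0.2, r_dot = 0, theta_dot = 15)
#' @export
com_state <- function(r, theta, r_dot = 0, theta_dot = 0) {
  vals <- c(r, theta, r_dot, theta_dot)
  names(vals) <- c("r", "theta", "r_dot", "theta_dot")
  if (!all(is.finite(vals)))
    stop("com_state: all fields must be finite", call. = FALSE)
  if (r <= 0)
    stop("com_state: leg length r must be > 0", call. = FALSE)
  structure(as.list(vals), class = "com_state")
}

#' ARSLIP model parameters
#'
#' The angular and radial spring-loaded inverted pendulum (ARSLIP) is a
#' point mass `m` on a single massless effective leg with a radial spring
#' (stiffness `k_s`, natural length `R`) and an angular spring (stiffness
#' `k_a`) that pulls the leg back towards the vertical.  `k_a = 0` gives
#' exactly the classical SLIP model.
#'
#' @param k_s Radial spring constant (N/m), > 0.
#' @param k_a Angular spring constant (N m/rad), >= 0.
#' @param R Natural leg length (m), > 0.
#' @param m Body mass (kg), > 0.
#' @param g Gravitational acceleration (m/s^2).
#' @return An object of class `arslip_params`.
#' @examples
#' # fly-scale values
#' arslip_params(k_s = 0.009, k_a = 1.1e-8, R = 2.042e-3, m = 1.123e-6)
#' @export
arslip_params <- function(k_s, k_a = 0, R, m, g = 9.807) {
  vals <- c(k_s, k_a, R, m, g)
  names(vals) <- c("k_s", "k_a", "R", "m", "g")
  if (!all(is.finite(vals)))
    stop("arslip_params: all fields must be finite", call. = FALSE)
  if (k_s <= 0 || R <= 0 || m <= 0 || g <= 0)
    stop("arslip_params: k_s, R, m, g must be > 0", call. = FALSE)
  if (k_a < 0)
    stop("arslip_params: k_a must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "arslip_params")
}

#' Springy-tripod model parameters
#'
#' Three identical linear-spring legs (stiffness `k`, natural length
#' `R_tri`) support a point mass.  The front and hind legs are planted
#' `L` ahead of and behind the middle foothold along the walking
#' direction; `r_m` is the CoM height at mid-stance.  The tripod shape is
#' summarised by the ratio `L / r_m`.
#'
#' @param k Per-leg spring constant (N/m), > 0.
#' @param R_tri Per-leg natural length (m), > 0.
#' @param L Half tripod spread along the walking direction (m), >= 0.
#' @param r_m Mid-stance CoM height (m), > 0.
#' @param m Body mass (kg), > 0.
#' @param g Gravitational acceleration (m/s^2).
#' @return An object of class `tripod_params`.
#' @examples
#' tripod_params(k = 0.004, R_tri = 2e-3, L = 2.1e-3, r_m = 1.4e-3, m = 1.123e-6)
#' @export
tripod_params <- function(k, R_tri, L, r_m, m, g = 9.807) {
  vals <- c(k, R_tri, L, r_m, m, g)
  names(vals) <- c("k", "R_tri", "L", "r_m", "m", "g")
  if (!all(is.finite(vals)))
    stop("tripod_params: all fields must be finite", call. = FALSE)
  if (k <= 0 || R_tri <= 0 || r_m <= 0 || m <= 0 || g <= 0)
    stop("tripod_params: k, R_tri, r_m, m, g must be > 0", call. = FALSE)
  if (L < 0)
    stop("tripod_params: L must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "tripod_params")
}

#' Initial conditions for a simulated step
#'
#' A step starts with the leg inclined at the angle of attack `alpha`
#' (the magnitude of `theta` at touch-down; the leg points backwards, so
#' `theta0 = -alpha`), with leg length `r0` and the measured radial and
#' angular speeds.
#'
#' @param alpha Angle of attack (rad), magnitude of theta at step start.
#' @param r0 Initial leg length (m), > 0.
#' @param r_dot0 Initial radial speed (m/s).
#' @param theta_dot0 Initial angular speed (rad/s).
#' @return An object of class `step_ic`.
#' @export
initial_conditions <- function(alpha, r0, r_dot0 = 0, theta_dot0 = 0) {
  vals <- c(alpha, r0, r_dot0, theta_dot0)
  names(vals) <- c("alpha", "r0", "r_dot0", "theta_dot0")
  if (!all(is.finite(vals)))
    stop("initial_conditions: all fields must be finite", call. = FALSE)
  if (r0 <= 0)
    stop("initial_conditions: r0 must be > 0", call. = FALSE)
  structure(as.list(vals), class = "step_ic")
}

#' @export
print.com_state <- function(x, ...) {
  cat(sprintf("CoM state: r = %g m, theta = %g rad, r_dot = %g m/s, theta_dot = %g rad/s\n",
              x$r, x$theta, x$r_dot, x$theta_dot))
  invisible(x)
}

#' @export
print.arslip_params <- function(x, ...) {
  cat(sprintf("ARSLIP parameters: k_s = %g N/m, k_a = %g N m/rad, R = %g m, m = %g kg, g = %g m/s^2\n",
              x$k_s, x$k_a, x$R, x$m, x$g))
  invisible(x)
}

#' @export
print.tripod_params <- function(x, ...) {
  cat(sprintf("Springy-tripod parameters: k = %g N/m, R_tri = %g m, L = %g m, r_m = %g m (L/r_m = %.3g), m = %g kg\n",
              x$k, x$R_tri, x$L, x$r_m, x$L / x$r_m, x$m))
  invisible(x)
}

# canonical leg labels, front (pro) to rear (meta); tripod A = R1-L2-R3
LEG_LABELS <- c("R1", "L1", "R2", "L2", "R3", "L3")
TRIPOD_A <- c("R1", "L2", "R3")
TRIPOD_B <- c("L1", "R2", "L3")
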