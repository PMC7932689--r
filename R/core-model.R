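#' Elastic potential energy of the springy tripod
#'
#' Sum of the elastic energies of the three legs.  With the CoM at polar
#' position (r, theta) above the middle foothold, the front and hind leg
#' lengths are `l_minus = sqrt(r^2 + L^2 - 2 r L sin(theta))` and
#' `l_plus = sqrt(r^2 + L^2 + 2 r L sin(theta))`, so that
#' `V = k/2 [(R_tri - l_minus)^2 + (R_tri - l_plus)^2 + (R_tri - r)^2]`.
#'
#' @param state A [com_state()] (only `r` and `theta` are used).
#' @param p A [tripod_params()].
#' @return Elastic potential energy (J), always >= 0.
#' @examples
#' p <- tripod_params(k = 1, R_tri = 1, L = 1, r_m = 1, m = 1)
#' tripod_potential(com_state(r = 1, theta = 0), p)   # (1 - sqrt(2))^2
#' @export
tripod_potential <- function(state, p) {
  stopifnot(inherits(state, "com_state"), inherits(p, "tripod_params"))
  r <- state$r; th <- state$theta
  sq_m <- r^2 + p$L^2 - 2 * r * p$L * sin(th)
  sq_p <- r^2 + p$L^2 + 2 * r * p$L * sin(th)
  if (sq_m < 0 || sq_p < 0)
    stop("tripod_potential: negative expression under square root",
         call. = FALSE)
  l_m <- sqrt(sq_m); l_p <- sqrt(sq_p)
  0.5 * p$k * ((p$R_tri - l_m)^2 + (p$R_tri - l_p)^2 + (p$R_tri - r)^2)
}

#' Elastic potential energy of the ARSLIP model
#'
#' `V = k_s/2 (R - r)^2 + k_a/2 theta^2`.  With `k_a = 0` this is the
#' SLIP elastic energy.
#'
#' @inheritParams tripod_potential
#' @param p An [arslip_params()].
#' @return Elastic potential energy (J), always >= 0.
#' @export
arslip_potential <- function(state, p) {
  stopifnot(inherits(state, "com_state"), inherits(p, "arslip_params"))
  0.5 * p$k_s * (p$R - state$r)^2 + 0.5 * p$k_a * state$theta^2
}

#' Reduce a springy tripod to its equivalent ARSLIP model
#'
#' Expands the tripod potential to quadratic order about mid-stance
#' (`r = r_m`, `theta = 0`) and matches it to the ARSLIP potential: the
#' first and second derivatives with respect to `r` and `theta` of the
#' two potentials agree at that point (the cross derivative vanishes by
#' the mirror symmetry of the tripod).  This yields
#' \deqn{k_a = 2 k L^2 r_m^2 R_{tri} / (L^2 + r_m^2)^{3/2}}
#' \deqn{k_s = k [3 - 2 L^2 R_{tri} / (L^2 + r_m^2)^{3/2}]}
#' and the ARSLIP natural length `R` from the radial-force match
#' `k_s (R - r_m) = k [R_tri - r_m (3 - 2 R_tri / sqrt(L^2 + r_m^2))]`.
#'
#' Geometries for which the quadratic radial stiffness `k_s` would be
#' non-positive (very wide, flat tripods with long natural legs) lie
#' outside the validity of the quadratic expansion and are rejected.
#'
#' @param p A [tripod_params()].
#' @return An [arslip_params()] with `m` and `g` copied from `p`.
#' @examples
#' p <- tripod_params(k = 1, R_tri = 1, L = 1, r_m = 1, m = 1)
#' tripod_to_arslip(p)    # k_s = 2.2929, k_a = 0.70711, R = 0.74452
#' @export
tripod_to_arslip <- function(p) {
  stopifnot(inherits(p, "tripod_params"))
  if (p$L == 0 && p$r_m == 0)
    stop("tripod_to_arslip: L and r_m cannot both be 0", call. = FALSE)
  s <- sqrt(p$L^2 + p$r_m^2)
  k_a <- 2 * p$k * p$L^2 * p$r_m^2 * p$R_tri / s^3
  k_s <- p$k * (3 - 2 * p$L^2 * p$R_tri / s^3)
  if (k_s <= 0)
    stop("tripod_to_arslip: geometry outside quadratic-expansion validity (k_s <= 0)",
         call. = FALSE)
  force_rm <- p$k * (p$R_tri - p$r_m * (3 - 2 * p$R_tri / s))
  R <- p$r_m + force_rm / k_s
  if (R <= 0)
    stop("tripod_to_arslip: geometry outside quadratic-expansion validity (R <= 0)",
         call. = FALSE)
  arslip_params(k_s = k_s, k_a = k_a, R = R, m = p$m, g = p$g)
}

#' Nondimensionalize ARSLIP parameters, speed and state
#'
#' Units: mass in body masses `m`, length in natural leg lengths `R`,
#' acceleration in `g` (so the time unit is `sqrt(R/g)`).  This gives the
#' dimensionless spring constants `gamma_s = k_s R / (m g)` and
#' `gamma_a = k_a / (m g R)`, the Froude number `Fr = v^2 / (R g)`, and,
#' for a mechanical state, `r_bar = r / R` and the dimensionless angular
#' speed `Omega = theta_dot sqrt(R / g)`.
#'
#' @param p An [arslip_params()].
#' @param v Optional horizontal speed (m/s) for the Froude number.
#' @param state Optional [com_state()] at mid-stance.
#' @return A list of class `nondim_quantities` with `gamma_s`, `gamma_a`
#'   and, when the inputs are given, `Fr`, `r_bar`, `r_bar_m`, `Omega`.
#' @examples
#' p <- arslip_params(k_s = 0.009, k_a = 1.1e-8, R = 2.042e-3, m = 1.123e-6)
#' nondimensionalize(p)   # gamma_s ~ 1.67, gamma_a ~ 0.49
#' @export
nondimensionalize <- function(p, v = NULL, state = NULL) {
  stopifnot(inherits(p, "arslip_params"))
  out <- list(
    gamma_s = p$k_s * p$R / (p$m * p$g),
    gamma_a = p$k_a / (p$m * p$g * p$R)
  )
  if (!is.null(v)) out$Fr <- v^2 / (p$R * p$g)
  if (!is.null(state)) {
    stopifnot(inherits(state, "com_state"))
    out$r_bar <- state$r / p$R
    out$r_bar_m <- state$r / p$R
    out$Omega <- state$theta_dot * sqrt(p$R / p$g)
  }
  structure(out, class = "nondim_quantities")
}

#' Reconstruct dimensional ARSLIP parameters from dimensionless ones
#'
#' Inverse of [nondimensionalize()]: given `gamma_s`, `gamma_a` and the
#' scales `(m, R, g)`, returns the dimensional [arslip_params()].
#'
#' @param gamma_s Dimensionless radial spring constant.
#' @param gamma_a Dimensionless angular spring constant.
#' @param m Body mass (kg).
#' @param R Natural leg length (m).
#' @param g Gravitational acceleration (m/s^2).
#' @return An [arslip_params()].
#' @export
dimensionalize <- function(gamma_s, gamma_a, m, R, g = 9.807) {
  arslip_params(k_s = gamma_s * m * g / R,
                k_a = gamma_a * m * g * R,
                R = R, m = m, g = g)
}

#' Numerical derivatives of the tripod potential at mid-stance
#'
#' Central-difference first and second partial derivatives of
#' [tripod_potential()] at `(r_m, 0)`.  Used as an independent check of
#' the analytic quadratic reduction in [tripod_to_arslip()].  Step sizes
#' scale with `r_m` (radial) and 1 rad (angular); second differences use
#' a larger step than first differences to balance truncation against
#' roundoff.
#'
#' @param p A [tripod_params()].
#' @return A list with `dV_dr`, `d2V_dr2`, `d2V_dtheta2`, `d2V_drdtheta`
#'   evaluated at mid-stance.
#' @export
tripod_potential_derivatives <- function(p) {
  stopifnot(inherits(p, "tripod_params"))
  V <- function(r, th) tripod_potential(com_state(r = r, theta = th), p)
  h1 <- 6e-6 * p$r_m      # ~ eps^(1/3) for first differences
  h2 <- 1.2e-4 * p$r_m    # ~ eps^(1/4) for second differences
  ht <- 1.2e-4            # angular steps are absolute (theta ~ O(1) rad)
  rm <- p$r_m
  list(
    dV_dr = (V(rm + h1, 0) - V(rm - h1, 0)) / (2 * h1),
    d2V_dr2 = (V(rm + h2, 0) - 2 * V(rm, 0) + V(rm - h2, 0)) / h2^2,
    d2V_dtheta2 = (V(rm, ht) - 2 * V(rm, 0) + V(rm, -ht)) / ht^2,
    d2V_drdtheta = (V(rm + h2, ht) - V(rm + h2, -ht)
                    - V(rm - h2, ht) + V(rm - h2, -ht)) / (4 * h2 * ht)
  )
}
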