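#' Classify tripod walking kinematics as fly-like or cockroach-like
#'
#' For a dimensionless per-leg stiffness `gamma_leg = k R_tri / (m g)`
#' and tripod shape `L / r_m`, builds the corresponding springy tripod
#' in nondimensional units (`m = g = r_m = 1`), reduces it to ARSLIP,
#' and probes a mid-stance-anchored step at the speed implied by the
#' Froude number.  Mid-stance is a speed maximum for fly-like
#' kinematics (the angular spring wins) and a speed minimum for
#' cockroach-like kinematics (the radial spring and gravity win); the
#' classification is the sign of the speed margin
#' `v(dt) - v(0)` at `dt = dt_frac` of the probe half-duration.
#'
#' The per-leg natural length `R_tri` is set by mid-stance radial force
#' balance: the mapped radial spring force at `r_m` equals the body
#' weight, which makes the construction depend only on
#' `(gamma_leg, L/r_m, Fr)`.  Set `convention = "rm"` to instead pin
#' `R_tri = r_m`.
#'
#' @param gamma_leg Dimensionless per-leg stiffness (> 0).
#' @param L_over_rm Tripod shape ratio (> 0).
#' @param Fr Froude number of the probe step (default 0.01).
#' @param dt_frac Probe offset as a fraction of the half-duration.
#' @param convention `"force_balance"` (default) or `"rm"` for the
#'   `R_tri` closure.
#' @param force_ka_zero Disable the angular spring (SLIP limit).
#' @return A `regime_point` list: `gamma_leg`, `L_over_rm`, `Fr`,
#'   `label` ("fly_like"/"cockroach_like"), `margin` (signed,
#'   nondimensional speed units), `gamma_s`, `gamma_a`.
#' @examples
#' classify_kinematics(gamma_leg = 50, L_over_rm = 2)$label   # fly_like
#' @export
classify_kinematics <- function(gamma_leg, L_over_rm, Fr = 0.01,
                                dt_frac = 0.02,
                                convention = c("force_balance", "rm"),
                                force_ka_zero = FALSE) {
  convention <- match.arg(convention)
  stopifnot(gamma_leg > 0, L_over_rm > 0, Fr > 0)
  tp <- nondim_tripod(gamma_leg, L_over_rm, convention)
  p <- tripod_to_arslip(tp)
  if (force_ka_zero)
    p <- arslip_params(k_s = p$k_s, k_a = 0, R = p$R, m = p$m, g = p$g)
  r_m <- tp$r_m
  # Fr = v^2/(R g) with v = r_m * theta_dot at mid-stance
  Omega <- sqrt(Fr) * p$R / r_m
  half <- 0.25 * 2 * pi * sqrt(p$m / p$k_s)
  dt <- dt_frac * half
  times <- sort(unique(c(0, dt, seq(0, half, length.out = 26))))
  y0 <- c(r_m, 0, 0, Omega * sqrt(p$g / p$R))
  out <- integrate_arslip(y0, times, p)
  v <- out[, "r_dot"] * sin(out[, "theta"]) +
    out[, "r"] * cos(out[, "theta"]) * out[, "theta_dot"]
  margin <- v[which.min(abs(times - dt))] - v[1]
  structure(list(
    gamma_leg = gamma_leg, L_over_rm = L_over_rm, Fr = Fr,
    label = if (margin < 0) "fly_like" else "cockroach_like",
    margin = margin,
    gamma_s = p$k_s * p$R / (p$m * p$g),
    gamma_a = p$k_a / (p$m * p$g * p$R)),
    class = "regime_point")
}

# nondimensional springy tripod (m = g = r_m = 1) for a given per-leg
# gamma and shape; R_tri from mid-stance force balance or R_tri = r_m
nondim_tripod <- function(gamma_leg, L_over_rm, convention) {
  r_m <- 1; L <- L_over_rm; m <- 1; g <- 1
  if (convention == "rm") {
    R_tri <- r_m
  } else {
    s <- sqrt(L^2 + r_m^2)
    den <- gamma_leg * (1 + 2 * r_m / s) - 1
    if (den <= 0)
      stop("nondim_tripod: leg too soft to support the body at this geometry",
           call. = FALSE)
    R_tri <- 3 * gamma_leg * r_m / den
  }
  k <- gamma_leg * m * g / R_tri
  tripod_params(k = k, R_tri = R_tri, L = L, r_m = r_m, m = m, g = g)
}

#' Critical leg stiffness separating fly-like from cockroach-like
#'
#' For each tripod shape in `L_over_rm_grid`, finds by bisection the
#' per-leg stiffness `gamma_crit` at which the mid-stance speed margin
#' changes sign: stiffer legs give fly-like kinematics (mid-stance
#' speed maximum), softer give cockroach-like.  The initial bracket is
#' expanded geometrically if it does not straddle the boundary; shapes
#' with no crossing inside `gamma_range` are reported unbounded (NA).
#'
#' @param L_over_rm_grid Shape ratios (each > 0).
#' @param Fr Froude number (default 0.01).
#' @param tol Relative bisection tolerance on gamma (default 1e-3).
#' @param gamma_range Search range for the bracket.
#' @param ... Passed on to [classify_kinematics()].
#' @return A data.frame `L_over_rm`, `gamma_crit`, `margin_at_crit`.
#' @export
boundary_curve <- function(L_over_rm_grid, Fr = 0.01, tol = 1e-3,
                           gamma_range = c(0.1, 1000), ...) {
  margin_at <- function(gamma, lr) {
    tryCatch(classify_kinematics(gamma, lr, Fr = Fr, ...)$margin,
             error = function(e) NA_real_)
  }
  rows <- lapply(L_over_rm_grid, function(lr) {
    # feasibility limit of the force-balance closure
    g_min <- 1 / (1 + 2 / sqrt(lr^2 + 1))
    lo <- max(gamma_range[1], 1.02 * g_min)
    hi <- min(gamma_range[2], 1e3)
    # probe on a log grid for a sign change
    gs <- exp(seq(log(lo), log(hi), length.out = 25))
    ms <- vapply(gs, margin_at, numeric(1), lr = lr)
    ok <- which(is.finite(ms))
    sgn <- sign(ms[ok])
    flip <- which(sgn[-1] != sgn[-length(sgn)])
    if (!length(flip))
      return(data.frame(L_over_rm = lr, gamma_crit = NA_real_,
                        margin_at_crit = NA_real_))
    a <- gs[ok[flip[1]]]; b <- gs[ok[flip[1] + 1]]
    ma <- ms[ok[flip[1]]]
    while (b / a - 1 > tol) {
      mid <- sqrt(a * b)
      mm <- margin_at(mid, lr)
      if (!is.finite(mm)) break
      if (sign(mm) == sign(ma)) { a <- mid; ma <- mm } else b <- mid
    }
    gc <- sqrt(a * b)
    data.frame(L_over_rm = lr, gamma_crit = gc,
               margin_at_crit = margin_at(gc, lr))
  })
  do.call(rbind, rows)
}

#' Dimensionless radial stiffness as a function of tripod shape
#'
#' Evaluates `gamma_s = k_s R / (m g)` of the ARSLIP reduction over a
#' grid of tripod shapes at fixed per-leg stiffness, under the same
#' `R_tri` closure as [classify_kinematics()].  Narrow, tall tripods
#' (small `L/r_m`) are stiffer; at large `L/r_m` the curve flattens and
#' geometry stops mattering.
#'
#' @param gamma_leg Dimensionless per-leg stiffness.
#' @param L_over_rm_grid Shape ratios.
#' @param convention `R_tri` closure, as in [classify_kinematics()].
#' @return A data.frame `L_over_rm`, `gamma_s`, `gamma_a`.
#' @export
gamma_s_vs_geometry <- function(gamma_leg, L_over_rm_grid,
                                convention = c("force_balance", "rm")) {
  convention <- match.arg(convention)
  rows <- lapply(L_over_rm_grid, function(lr) {
    p <- tripod_to_arslip(nondim_tripod(gamma_leg, lr, convention))
    data.frame(L_over_rm = lr,
               gamma_s = p$k_s * p$R / (p$m * p$g),
               gamma_a = p$k_a / (p$m * p$g * p$R))
  })
  do.call(rbind, rows)
}
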