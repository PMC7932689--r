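#' Configuration for the synthetic walking-data generator
#'
#' Defaults emulate a wild-type fly walking straight in a recording
#' chamber filmed at 380 Hz with ~20 um vertical tracking resolution:
#' stance duration scales as the reciprocal of speed, swing duration
#' decreases weakly and linearly with speed (-0.00018 s per mm/s,
#' intercept 0.03 s), the interleg coordination is an M-tripod with
#' small within-tripod leads, tripod shape L/r_m decreases from 2 to 1
#' as speed (hence Froude number) rises while mid-stance height rises,
#' and every leg has the same linear spring constant `k` and natural
#' length `R_tri` so that the per-step ARSLIP constants follow from
#' geometry alone.
#'
#' Speed inside a bout evolves as a reflected random walk so that
#' consecutive steps have similar speeds, as in real bouts.
#'
#' @param n_steps Number of tripod stances to generate.
#' @param speed_range Bout speed range (m/s).
#' @param frame_rate Sampling rate (Hz).
#' @param sigma_z,sigma_x Gaussian measurement noise SD on CoM height
#'   and horizontal position (m).
#' @param delta_meso_pro,delta_meta_meso M-tripod within-tripod leads
#'   (cycle fractions).
#' @param stance_coef Stance-duration law `stance = stance_coef / v` (m).
#' @param swing_slope_mm,swing_intercept Swing-duration law
#'   `swing = intercept + slope * v_mm` with `v_mm` in mm/s.
#' @param L_over_rm_range Tripod shape range, mapped decreasingly onto
#'   the speed range.
#' @param r_m_range Mid-stance height range (m), mapped increasingly
#'   onto the speed range.
#' @param k,R_tri True per-leg spring constant (N/m) and natural
#'   length (m).  The default `k = NULL` sets the stiffness by static
#'   force balance: the tripod's radial restoring force at the middle
#'   of the geometry range equals the body weight, which is how a
#'   standing fly must load its legs (the effective spring then
#'   oscillates about its loaded fixed point during walking).
#' @param m,R_real,g Fly mass (kg), measured leg length (m), gravity.
#' @param fly_id Identifier carried in the metadata.
#' @param half_width Lateral foothold offset (m).
#' @param leg_amp Leg-track half-amplitude along the body axis (m).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_steps = 20,
                             speed_range = c(0.010, 0.030),
                             frame_rate = 380,
                             sigma_z = 20e-6, sigma_x = 20e-6,
                             delta_meso_pro = 0.05,
                             delta_meta_meso = 0.05,
                             stance_coef = 0.8e-3,
                             swing_slope_mm = -1.8e-4,
                             swing_intercept = 0.03,
                             L_over_rm_range = c(1, 2),
                             r_m_range = c(1.15e-3, 1.35e-3),
                             k = NULL, R_tri = 2.4e-3,
                             m = 1.123e-6, R_real = 2.042e-3, g = 9.807,
                             fly_id = "synth-W1118-1",
                             half_width = 1e-3, leg_amp = 1e-3,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$frame_rate > 0, length(cfg$speed_range) == 2,
            cfg$speed_range[1] > 0, diff(cfg$speed_range) >= 0,
            cfg$L_over_rm_range[1] >= 0.5, cfg$L_over_rm_range[2] <= 8)
  if (is.null(cfg$k)) {
    # per-leg stiffness from static support at the mid-range geometry:
    # tripod radial force at r_m equals the body weight
    r_m <- mean(cfg$r_m_range)
    L <- mean(cfg$L_over_rm_range) * r_m
    s <- sqrt(L^2 + r_m^2)
    denom <- cfg$R_tri - r_m * (3 - 2 * cfg$R_tri / s)
    if (denom <= 0)
      stop("synthetic_config: geometry cannot support the body; supply k",
           call. = FALSE)
    cfg$k <- cfg$m * cfg$g / denom
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# speed-dependent laws: durations (s) and per-step geometry
stance_duration <- function(v, cfg) cfg$stance_coef / v
swing_duration <- function(v, cfg)
  cfg$swing_intercept + cfg$swing_slope_mm * (v * 1000)

speed_norm <- function(v, cfg) {
  rng <- cfg$speed_range
  if (diff(rng) == 0) return(rep(0.5, length(v)))
  pmin(1, pmax(0, (v - rng[1]) / diff(rng)))
}

geometry_for_speed <- function(v, cfg) {
  u <- speed_norm(v, cfg)
  r_m <- cfg$r_m_range[1] + u * diff(cfg$r_m_range)
  lr <- cfg$L_over_rm_range[2] - u * diff(cfg$L_over_rm_range)
  list(r_m = r_m, L_over_rm = lr, L = lr * r_m)
}

#' Generate one noisy synthetic step
#'
#' Simulates a single stance with the ARSLIP forward model (a
#' springy-tripod parameter set is reduced first), samples it at the
#' configured frame rate until the leg angle returns to the angle of
#' attack, and adds Gaussian measurement noise.  If the parameters
#' lead to a fall, the angle of attack is reduced by 20% and the step
#' is retried (up to 5 attempts).
#'
#' @param p_true An [arslip_params()] or [tripod_params()].
#' @param ic An [initial_conditions()].
#' @param cfg A [synthetic_config()] (frame rate and noise are used).
#' @param seed Integer seed for the noise draw.
#' @return A list: `com` (noisy data.frame `t`, `x`, `z`), `clean`
#'   (noise-free `com_trajectory`), `truth` (parameters and the
#'   initial conditions actually used).
#' @export
generate_step <- function(p_true, ic, cfg = synthetic_config(),
                          seed = 1L) {
  p <- if (inherits(p_true, "tripod_params")) tripod_to_arslip(p_true)
  else p_true
  stopifnot(inherits(p, "arslip_params"), inherits(ic, "step_ic"))
  dt <- 1 / cfg$frame_rate
  alpha <- ic$alpha
  for (attempt in 1:5) {
    t_max <- max(4 * pi * sqrt(p$m / p$k_s), 4 * alpha / max(ic$theta_dot0, 1e-9))
    grid <- seq(0, t_max, by = dt)
    ic_try <- initial_conditions(alpha = alpha, r0 = ic$r0,
                                 r_dot0 = ic$r_dot0,
                                 theta_dot0 = ic$theta_dot0)
    traj <- tryCatch(simulate_step(p, ic_try, grid),
                     arslip_fall = function(e) e)
    if (inherits(traj, "arslip_fall")) {
      # a fall after the leg has already swung past +alpha is past the
      # end of the step, not a failed step: keep the pre-fall frames
      grid2 <- grid[grid < traj$time]
      traj <- if (length(grid2) >= 5)
        tryCatch(simulate_step(p, ic_try, grid2),
                 arslip_fall = function(e) e)
      else traj
    }
    done <- !inherits(traj, "arslip_fall") &&
      (alpha == 0 || any(traj$theta[-1] >= alpha))
    if (done) {
      if (alpha > 0) {
        past <- which(traj$theta >= alpha & seq_len(nrow(traj)) > 1)
        traj <- traj[seq_len(past[1]), ]
      }
      set.seed(seed)
      com <- data.frame(
        t = traj$t,
        x = traj$x + stats::rnorm(nrow(traj), 0, cfg$sigma_x),
        z = traj$z + stats::rnorm(nrow(traj), 0, cfg$sigma_z))
      return(list(com = com, clean = traj,
                  truth = list(params = p, ic = ic_try)))
    }
    alpha <- 0.8 * alpha
  }
  stop("generate_step: fall persisted after 5 attempts with reduced angle of attack",
       call. = FALSE)
}

#' Generate a complete synthetic walking dataset
#'
#' Builds an M-tripod footfall schedule with speed-dependent cycle
#' periods, places footholds with the speed-dependent tripod geometry,
#' synthesizes the CoM trajectory by stitching per-step ARSLIP
#' simulations (each step's constants follow from the fly's single
#' per-leg spring through the tripod reduction at that step's
#' geometry, anchored at mid-stance at the step's speed), samples
#' everything at the configured frame rate, adds measurement noise,
#' and emits the ground truth for every step.  Horizontal position is
#' continuous across step boundaries; velocity may jump there, as in
#' the per-step single-effective-leg picture.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `walking_dataset`: `com` (noisy CoM table
#'   `t`, `x`, `z`), `com_clean`, `footfalls` ([footfall_sequence()]),
#'   `leg_tracks` (`t`, `leg`, `y_body`, `stance`), `truth` (one row
#'   per step: window, speed, geometry, mapped ARSLIP constants),
#'   `meta` (fly id, mass, leg length, frame rate, seed).
#' @export
generate_fly_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n_cycles <- ceiling(cfg$n_steps / 2) + 2
  # reflected random walk keeps consecutive speeds similar
  v <- numeric(n_cycles)
  v[1] <- stats::runif(1, cfg$speed_range[1], cfg$speed_range[2])
  step_sd <- 0.05 * diff(cfg$speed_range)
  for (j in seq_len(n_cycles - 1)) {
    cand <- v[j] + stats::rnorm(1, 0, step_sd)
    while (cand < cfg$speed_range[1] || cand > cfg$speed_range[2])
      cand <- if (cand < cfg$speed_range[1]) 2 * cfg$speed_range[1] - cand
      else 2 * cfg$speed_range[2] - cand
    v[j + 1] <- cand
  }
  stance <- stance_duration(v, cfg)
  swing <- swing_duration(v, cfg)
  period <- stance + swing
  t_base <- c(0, cumsum(period[-n_cycles]))

  # footfall schedule: tripod A anchored at t_base, tripod B half a
  # period later, with the M-tripod within-tripod leads
  offs <- c(0, cfg$delta_meso_pro, cfg$delta_meso_pro + cfg$delta_meta_meso)
  legsA <- TRIPOD_A; legsB <- TRIPOD_B
  sched <- list(); ev <- list()
  for (j in seq_len(n_cycles)) {
    for (tri in c("A", "B")) {
      legs <- if (tri == "A") legsA else legsB
      t_tri <- t_base[j] + if (tri == "B") period[j] / 2 else 0
      td <- t_tri + offs * period[j]
      ev[[length(ev) + 1]] <- data.frame(
        cycle = j, tripod = tri, v = v[j],
        first_td = min(td), last_lo = max(td + stance[j]), t_anchor = t_tri)
      sched[[length(sched) + 1]] <- data.frame(
        leg = legs, t_down = td, t_up = td + stance[j], cycle = j,
        tripod = tri)
    }
  }
  ev <- do.call(rbind, ev)
  sched <- do.call(rbind, sched)
  ev <- ev[order(ev$first_td), ]

  # step windows by the midpoint rule; the flanking events are dropped
  ne <- nrow(ev)
  idx <- 2:(ne - 1)
  n_steps <- min(cfg$n_steps, length(idx))
  idx <- idx[seq_len(n_steps)]
  t_start <- (ev$first_td[idx] + ev$last_lo[idx - 1]) / 2
  t_end <- (ev$first_td[idx + 1] + ev$last_lo[idx]) / 2
  t_mid <- (t_start + t_end) / 2

  dt <- 1 / cfg$frame_rate
  frames <- seq(0, max(t_end), by = dt)

  truth <- list(); segs <- list()
  C <- 0                       # global x of the current foothold centre
  x_prev_end <- 0              # global x at the previous window's end
  centres <- rep(NA_real_, ne)
  for (s in seq_along(idx)) {
    vs <- ev$v[idx[s]]
    geom <- geometry_for_speed(vs, cfg)
    tp <- tripod_params(k = cfg$k, R_tri = cfg$R_tri, L = geom$L,
                        r_m = geom$r_m, m = cfg$m, g = cfg$g)
    p <- tripod_to_arslip(tp)
    thd_mid <- vs / geom$r_m
    f_in <- frames[frames >= t_start[s] & frames < t_end[s]]
    tt_abs <- sort(unique(c(f_in, t_start[s], t_end[s])))
    tau <- tt_abs - t_mid[s]
    sim <- simulate_about_midstance(p, geom$r_m, thd_mid, tau)
    # enforce x continuity at the window boundary
    i_lo <- which(tt_abs == t_start[s]); i_hi <- which(tt_abs == t_end[s])
    C <- x_prev_end - sim$x[i_lo]
    x_prev_end <- C + sim$x[i_hi]
    centres[idx[s]] <- C
    keep <- tt_abs %in% f_in
    segs[[s]] <- data.frame(t = tt_abs[keep],
                            x = C + sim$x[keep], z = sim$z[keep],
                            v = sim$v[keep])
    truth[[s]] <- data.frame(
      step_id = s, tripod = ev$tripod[idx[s]], cycle = ev$cycle[idx[s]],
      t_start = t_start[s], t_end = t_end[s], t_mid = t_mid[s],
      v = vs, L = geom$L, r_m = geom$r_m, L_over_rm = geom$L_over_rm,
      theta_dot_mid = thd_mid,
      k_s = p$k_s, k_a = p$k_a, R = p$R,
      gamma_s = p$k_s * p$R / (p$m * p$g),
      gamma_a = p$k_a / (p$m * p$g * p$R))
  }
  truth <- do.call(rbind, truth)
  com_clean <- do.call(rbind, segs)
  com_clean <- com_clean[order(com_clean$t), ]
  rownames(com_clean) <- NULL

  # foothold centres for the flanking (unsimulated) events, by
  # extrapolating the stride
  known <- which(!is.na(centres))
  if (length(known) >= 2)
    centres[-known] <- approx(known, centres[known], xout = seq_len(ne),
                              rule = 2)$y[-known]
  ap <- c(1, 0, -1)            # front, middle, hind
  foot <- do.call(rbind, lapply(seq_len(ne), function(i) {
    legs <- if (ev$tripod[i] == "A") legsA else legsB
    side <- ifelse(substr(legs, 1, 1) == "L", 1, -1)
    geom <- geometry_for_speed(ev$v[i], cfg)
    data.frame(leg = legs, cycle = ev$cycle[i], tripod = ev$tripod[i],
               x_foot = centres[i] + ap * geom$L,
               y_foot = side * cfg$half_width)
  }))
  sched <- merge(sched, foot, by = c("leg", "cycle", "tripod"), sort = FALSE)
  footfalls <- footfall_sequence(
    sched[, c("leg", "t_down", "t_up", "x_foot", "y_foot", "cycle")])

  leg_tracks <- make_leg_tracks(footfalls, frames, cfg$leg_amp)

  noise_x <- stats::rnorm(nrow(com_clean), 0, cfg$sigma_x)
  noise_z <- stats::rnorm(nrow(com_clean), 0, cfg$sigma_z)
  com <- data.frame(t = com_clean$t,
                    x = com_clean$x + noise_x,
                    z = com_clean$z + noise_z)
  structure(list(
    com = com, com_clean = com_clean, footfalls = footfalls,
    leg_tracks = leg_tracks, truth = truth,
    meta = list(fly_id = cfg$fly_id, m = cfg$m, R_real = cfg$R_real,
                g = cfg$g, frame_rate = cfg$frame_rate, seed = cfg$seed,
                generator = paste0("arslip ", utils::packageVersion("arslip")),
                k_true = cfg$k, R_tri_true = cfg$R_tri)),
    class = "walking_dataset")
}

# integrate the ARSLIP model about the mid-stance anchor (theta = 0,
# r = r_m, r_dot = 0, theta_dot = thd) at signed times tau; the
# backward branch is the time-reflection with theta and r_dot negated
simulate_about_midstance <- function(p, r_m, thd, tau) {
  y0 <- c(r_m, 0, 0, thd)
  run <- function(tt) {
    if (length(tt) == 1)
      return(matrix(c(tt, y0), nrow = 1,
                    dimnames = list(NULL, c("time", "r", "theta", "r_dot",
                                            "theta_dot"))))
    integrate_arslip(y0, tt, p)
  }
  pos <- tau[tau >= 0]; neg <- tau[tau < 0]
  parts <- list()
  if (length(pos)) parts$fwd <- run(c(0, pos[pos > 0]))
  if (length(neg)) {
    bk <- run(c(0, sort(-neg)))
    bk[, "time"] <- -bk[, "time"]
    bk[, "theta"] <- -bk[, "theta"]
    bk[, "r_dot"] <- -bk[, "r_dot"]
    parts$bwd <- bk
  }
  out <- do.call(rbind, parts)
  out <- out[match(round(tau, 12), round(out[, "time"], 12)), , drop = FALSE]
  r <- out[, "r"]; th <- out[, "theta"]
  list(t = tau, x = r * sin(th), z = r * cos(th),
       v = out[, "r_dot"] * sin(th) + r * cos(th) * out[, "theta_dot"])
}

# piecewise-linear leg-tip tracks: +amp at touch-down (AEP), -amp at
# lift-off (PEP), linear in between and during the return swing
make_leg_tracks <- function(footfalls, frames, amp) {
  out <- lapply(split(footfalls, footfalls$leg), function(s) {
    s <- s[order(s$t_down), ]
    nodes_t <- as.vector(rbind(s$t_down, s$t_up))
    nodes_y <- rep(c(amp, -amp), nrow(s))
    y <- approx(nodes_t, nodes_y, xout = frames, rule = 2)$y
    stance <- vapply(frames, function(tt)
      any(tt >= s$t_down & tt <= s$t_up), logical(1))
    data.frame(t = frames, leg = s$leg[1], y_body = y, stance = stance)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
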