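#' Footfall sequence
#'
#' Validates and classes a footfall table: one row per stance interval
#' with the leg label, touch-down and lift-off times, and the
#' ground-plane foothold coordinates.
#'
#' @param df A data.frame with columns `leg` (one of R1, L1, R2, L2, R3,
#'   L3), `t_down`, `t_up` (s), and optionally `x_foot`, `y_foot` (m).
#' @return The validated data.frame, classed `footfall_seq`, sorted by
#'   leg and touch-down time.
#' @export
footfall_sequence <- function(df) {
  need <- c("leg", "t_down", "t_up")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("footfall_sequence: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !df$leg %in% LEG_LABELS
  if (any(bad))
    stop(sprintf("footfall_sequence: unknown leg label '%s' at row %d",
                 df$leg[which(bad)[1]], which(bad)[1]), call. = FALSE)
  if (any(df$t_up <= df$t_down))
    stop("footfall_sequence: lift-off must come after touch-down",
         call. = FALSE)
  df <- df[order(df$leg, df$t_down), , drop = FALSE]
  for (lg in unique(df$leg)) {
    s <- df[df$leg == lg, ]
    if (nrow(s) > 1 && any(s$t_down[-1] < s$t_up[-nrow(s)]))
      stop(sprintf("footfall_sequence: overlapping stance intervals for leg %s", lg),
           call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("footfall_seq", "data.frame")
  df
}

#' Synthesize a modified-tripod (M-tripod) footfall schedule
#'
#' In the M-tripod gait the front leg of each tripod leads its middle
#' leg by `delta_meso_pro` cycle fractions and the middle leg leads the
#' rear leg by `delta_meta_meso`; the opposing tripod is shifted by half
#' a period.  Both deltas zero gives the ideal alternating tripod.
#'
#' Footholds advance by `stride` per cycle; front/rear legs are placed
#' `ap_spread` ahead of/behind the tripod centre along x and legs
#' alternate between `+half_width` and `-half_width` laterally.
#'
#' @param delta_meso_pro Front-over-middle lead (cycle fraction, < 0.5).
#' @param delta_meta_meso Middle-over-rear lead (cycle fraction, < 0.5).
#' @param period Cycle period (s).
#' @param duty Duty factor (stance fraction of the cycle), in (0, 1).
#' @param n_cycles Number of full cycles to generate.
#' @param stride Foothold advance per cycle (m).
#' @param ap_spread Anterior-posterior foothold offset (m).
#' @param half_width Lateral foothold offset (m).
#' @param t0 Time of the first R1 touch-down (s).
#' @return A [footfall_sequence()].
#' @examples
#' f <- make_m_tripod(0.05, 0.08, period = 0.1, duty = 0.6, n_cycles = 8)
#' normalized_stance_delays(f)
#' @export
make_m_tripod <- function(delta_meso_pro, delta_meta_meso, period, duty,
                          n_cycles, stride = 2e-3, ap_spread = 2e-3,
                          half_width = 1e-3, t0 = 0) {
  if (duty <= 0 || duty >= 1)
    stop("make_m_tripod: duty must be in (0, 1)", call. = FALSE)
  if (abs(delta_meso_pro) >= 0.5 || abs(delta_meta_meso) >= 0.5)
    stop("make_m_tripod: within-tripod delays must be < 0.5 cycles",
         call. = FALSE)
  # per-leg timing offset (cycle fractions) and anterior-posterior rank
  offs <- c(R1 = 0, L2 = delta_meso_pro,
            R3 = delta_meso_pro + delta_meta_meso,
            L1 = 0.5, R2 = 0.5 + delta_meso_pro,
            L3 = 0.5 + delta_meso_pro + delta_meta_meso)
  ap <- c(R1 = ap_spread, L1 = ap_spread, L2 = 0, R2 = 0,
          R3 = -ap_spread, L3 = -ap_spread)
  side <- c(R1 = -1, R2 = -1, R3 = -1, L1 = 1, L2 = 1, L3 = 1)
  rows <- lapply(names(offs), function(lg) {
    td <- t0 + (seq_len(n_cycles) - 1 + offs[[lg]]) * period
    data.frame(leg = lg, t_down = td, t_up = td + duty * period,
               x_foot = (seq_len(n_cycles) - 1) * stride + ap[[lg]],
               y_foot = side[[lg]] * half_width)
  })
  footfall_sequence(do.call(rbind, rows))
}

#' Stance and swing durations with concurrent body speed
#'
#' Stance duration is lift-off minus touch-down; swing duration is the
#' time to the same leg's next touch-down.  When a CoM trajectory is
#' supplied, the mean horizontal speed over each stance interval is
#' attached; intervals without CoM coverage are flagged rather than
#' dropped.
#'
#' @param f A [footfall_sequence()].
#' @param com Optional CoM trajectory data.frame with columns `t`, `x`
#'   (and optionally `v`).
#' @return A data.frame with one row per stance interval: `leg`,
#'   `t_down`, `t_up`, `stance`, `swing` (NA for the last interval of a
#'   leg), `speed` (NA without CoM coverage), `flagged`.
#' @export
stance_swing_durations <- function(f, com = NULL) {
  stopifnot(inherits(f, "footfall_seq"))
  out <- do.call(rbind, lapply(split(f, f$leg), function(s) {
    s <- s[order(s$t_down), ]
    data.frame(leg = s$leg, t_down = s$t_down, t_up = s$t_up,
               stance = s$t_up - s$t_down,
               swing = c(s$t_down[-1], NA) - s$t_up)
  }))
  rownames(out) <- NULL
  out$speed <- NA_real_
  out$flagged <- FALSE
  if (!is.null(com)) {
    v <- com$v
    if (is.null(v)) v <- finite_diff(com$x, com$t)
    for (i in seq_len(nrow(out))) {
      sel <- com$t >= out$t_down[i] & com$t <= out$t_up[i]
      if (sum(sel) >= 2) out$speed[i] <- mean(abs(v[sel]))
      else out$flagged[i] <- TRUE
    }
  }
  out
}

# centred finite-difference derivative on a possibly non-uniform grid
finite_diff <- function(y, t) {
  n <- length(y)
  if (n < 2) return(rep(NA_real_, n))
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d
}

# wrap a cycle-fraction delay into [-0.5, 0.5]
wrap_half <- function(d) {
  w <- d - round(d)
  w[w <= -0.5] <- w[w <= -0.5] + 1
  w
}

#' Normalized stance-start delays relative to a reference leg
#'
#' For every full cycle of the reference leg (two consecutive
#' touch-downs), computes each other leg's touch-down delay relative to
#' the reference touch-down, divided by the cycle period and mapped into
#' [-0.5, 0.5].  The nearest touch-down of each leg is used, so legs
#' that land slightly before the reference give negative delays.
#'
#' @param f A [footfall_sequence()].
#' @param reference Reference leg label (default "R1").
#' @return A data.frame of class `coordination_result`, one row per
#'   reference cycle: `cycle`, `t_ref`, `period`, `duty`, and one delay
#'   column per non-reference leg.  Zero complete cycles gives zero rows.
#' @export
normalized_stance_delays <- function(f, reference = "R1") {
  stopifnot(inherits(f, "footfall_seq"), reference %in% LEG_LABELS)
  ref <- f[f$leg == reference, ]
  ref <- ref[order(ref$t_down), ]
  others <- setdiff(LEG_LABELS, reference)
  empty <- data.frame(cycle = integer(), t_ref = numeric(),
                      period = numeric(), duty = numeric())
  for (lg in others) empty[[lg]] <- numeric()
  if (nrow(ref) < 2) {
    class(empty) <- c("coordination_result", "data.frame")
    return(empty)
  }
  res <- lapply(seq_len(nrow(ref) - 1), function(i) {
    t_ref <- ref$t_down[i]
    period <- ref$t_down[i + 1] - t_ref
    row <- data.frame(cycle = i, t_ref = t_ref, period = period,
                      duty = (ref$t_up[i] - t_ref) / period)
    for (lg in others) {
      td <- f$t_down[f$leg == lg]
      td <- td[abs(td - t_ref) <= period]
      if (!length(td)) { row[[lg]] <- NA_real_; next }
      w <- wrap_half((td - t_ref) / period)
      # snap float dust at the half-cycle boundary and at zero
      w[abs(w + 0.5) < 1e-9 | abs(w - 0.5) < 1e-9] <- 0.5
      w[abs(w) < 1e-12] <- 0
      best <- which(abs(w) <= min(abs(w)) + 1e-9)
      row[[lg]] <- max(w[best])          # tie (exactly +-0.5) -> positive
    }
    row
  })
  out <- do.call(rbind, res)
  class(out) <- c("coordination_result", "data.frame")
  out
}

# analytic signal via FFT: for x = cos(phi(t)) with slowly varying
# amplitude, Arg(analytic_signal(x)) is the instantaneous phase.
# The record is mirror-padded on both sides first: the FFT treats the
# signal as periodic, and the wrap-around discontinuity of a record
# covering a non-integer number of cycles otherwise leaks phase error
# well into the interior.
analytic_signal <- function(x, pad = TRUE) {
  if (pad) {
    n <- length(x)
    a <- analytic_signal(c(rev(x), x, rev(x)), pad = FALSE)
    return(a[(n + 1):(2 * n)])
  }
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous leg phases from leg-tip tracks
#'
#' Computes each leg's instantaneous phase as the argument of the
#' analytic (Hilbert) signal of the leg-tip position along the body axis
#' `y(t)`.  Swing samples are first replaced by linear interpolation
#' between stance samples (tracking during swing is unreliable), and the
#' track is detrended by a sliding-window mean (window = 2 median cycle
#' periods) so that slow drift in the body frame does not tilt the
#' analytic signal.  Sign convention: stance (anterior extreme to
#' posterior extreme) runs 0 to pi, swing runs -pi to 0.
#'
#' Before the transform the track is band-limited to `lp_harmonics`
#' times the stepping frequency: the phase should be carried by the
#' fundamental and low harmonics, and the kinks introduced by the
#' swing interpolation otherwise scatter the phase at stance
#' transitions.  Set `lp_harmonics = Inf` to disable the filter.
#'
#' @param tracks A data.frame with columns `t`, `leg`, `y_body` (m,
#'   anterior positive) and logical `stance`.
#' @param lp_harmonics Low-pass cutoff in multiples of the median
#'   cycle frequency (default 3).
#' @return A data.frame `t`, `leg`, `phase` (rad, in [-pi, pi]).  If any
#'   leg covers fewer than two full cycles the result carries attribute
#'   `low_confidence = TRUE` and a warning is issued.
#' @export
leg_phases <- function(tracks, lp_harmonics = 3) {
  need <- c("t", "leg", "y_body", "stance")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stop("leg_phases: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  low_conf <- FALSE
  out <- lapply(split(tracks, tracks$leg), function(s) {
    s <- s[order(s$t), ]
    n <- nrow(s)
    y <- s$y_body
    # interpolate across swing gaps
    if (any(s$stance) && any(!s$stance))
      y[!s$stance] <- approx(s$t[s$stance], s$y_body[s$stance],
                             xout = s$t[!s$stance], rule = 2)$y
    # cycle count from stance onsets
    onsets <- s$t[which(diff(c(FALSE, s$stance)) == 1)]
    n_cycles <- length(onsets) - 1
    if (n_cycles < 2) low_conf <<- TRUE
    med_period <- if (n_cycles >= 1) median(diff(onsets)) else diff(range(s$t))
    # sliding-mean detrend, window = 2 median periods
    dt <- median(diff(s$t))
    w <- max(3, round(2 * med_period / dt))
    w <- min(w, n)
    if (w %% 2 == 0) w <- w - 1
    trend <- sliding_mean(y, w)
    yd <- y - trend
    if (is.finite(lp_harmonics) && n_cycles >= 1)
      yd <- fft_lowpass(yd, dt, lp_harmonics / med_period)
    a <- analytic_signal(yd)
    ph <- Arg(a)
    # ensure the phase advances (anterior-positive y gives this already)
    if (mean(diff(unwrap_phase(ph))) < 0) ph <- -ph
    data.frame(t = s$t, leg = s$leg, phase = ph)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (low_conf) {
    warning("leg_phases: a track covers fewer than 2 full cycles; ",
            "phases flagged low-confidence")
    attr(out, "low_confidence") <- TRUE
  }
  out
}

# brick-wall FFT low-pass (applied to mirror-padded signal to avoid
# wrap-around ringing at the record edges)
fft_lowpass <- function(x, dt, fc) {
  n <- length(x)
  xe <- c(rev(x), x, rev(x))
  ne <- length(xe)
  X <- fft(xe)
  fr <- c(0:floor(ne / 2), -(ceiling(ne / 2) - 1):-1) / (ne * dt)
  X[abs(fr) > fc] <- 0
  Re(fft(X, inverse = TRUE) / ne)[(n + 1):(2 * n)]
}

# centred moving average with edge shrinkage
sliding_mean <- function(y, w) {
  n <- length(y)
  half <- (w - 1) / 2
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

unwrap_phase <- function(ph) {
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(ph[1], ph[1] + cumsum(d))
}

#' Phase delays relative to a reference leg
#'
#' For every stance of the reference leg, the normalized phase delay of
#' each other leg is the circular mean of `(phase_leg - phase_ref) / 2 pi`
#' over the reference stance samples, wrapped to [-0.5, 0.5].  Circular
#' (vector) averaging is used because wrapped phase differences must not
#' be averaged arithmetically.
#'
#' @param phases Output of [leg_phases()].
#' @param f A [footfall_sequence()] on the same time base.
#' @param reference Reference leg label.
#' @param edge_frac Fraction of samples at each end of the track to
#'   exclude (analytic-signal edge effects), default 0.1.
#' @return A `coordination_result` data.frame, one row per reference
#'   stance with a delay column per non-reference leg.
#' @export
phase_delays <- function(phases, f, reference = "R1", edge_frac = 0.1) {
  stopifnot(inherits(f, "footfall_seq"))
  ref_ph <- phases[phases$leg == reference, ]
  ref_ph <- ref_ph[order(ref_ph$t), ]
  t_rng <- range(phases$t)
  t_lo <- t_rng[1] + edge_frac * diff(t_rng)
  t_hi <- t_rng[2] - edge_frac * diff(t_rng)
  ref_st <- f[f$leg == reference, ]
  others <- setdiff(unique(phases$leg), reference)
  res <- list()
  for (i in seq_len(nrow(ref_st))) {
    sel <- ref_ph$t >= max(ref_st$t_down[i], t_lo) &
      ref_ph$t <= min(ref_st$t_up[i], t_hi)
    if (sum(sel) < 2) next                     # empty overlap: skip stance
    tt <- ref_ph$t[sel]
    row <- data.frame(cycle = i, t_ref = ref_st$t_down[i],
                      period = NA_real_, duty = NA_real_)
    for (lg in others) {
      ph_l <- phases[phases$leg == lg, ]
      ph_i <- approx(ph_l$t, unwrap_phase(ph_l$phase), xout = tt)$y
      ph_r <- approx(ref_ph$t, unwrap_phase(ref_ph$phase), xout = tt)$y
      # a leg that lags the reference has a smaller phase; report its
      # delay as positive, matching the stance-start convention
      dphi <- ph_r - ph_i
      row[[lg]] <- Arg(mean(exp(1i * dphi))) / (2 * pi)
    }
    res[[length(res) + 1]] <- row
  }
  out <- if (length(res)) do.call(rbind, res) else {
    e <- data.frame(cycle = integer(), t_ref = numeric(),
                    period = numeric(), duty = numeric())
    for (lg in others) e[[lg]] <- numeric()
    e
  }
  class(out) <- c("coordination_result", "data.frame")
  out
}

#' Classify the interleg coordination of one cycle
#'
#' Deterministic template matching on the five normalized delays
#' relative to the reference leg.  Tripod: the two same-tripod legs
#' within `tripod_tol` of 0 and the three opposing-tripod legs within
#' `tripod_tol` of 0.5 (circularly).  Tetrapod: every leg within
#' `tetrapod_tol` of one of the three groups {0, 1/3, -1/3}, with
#' exactly one leg sharing the reference group and two in each other
#' group.  Everything else (including missing legs) is noncanonical.
#'
#' @param delays A named numeric vector or one-row
#'   `coordination_result` with entries for the five non-reference legs.
#' @param reference Reference leg label.
#' @param tripod_tol,tetrapod_tol Template half-widths (cycle
#'   fractions).
#' @return One of `"tripod"`, `"tetrapod"`, `"noncanonical"`.
#' @export
classify_step_gait <- function(delays, reference = "R1",
                               tripod_tol = 0.125, tetrapod_tol = 0.125) {
  if (is.data.frame(delays)) {
    stopifnot(nrow(delays) == 1)
    delays <- unlist(delays[intersect(LEG_LABELS, names(delays))])
  }
  others <- setdiff(LEG_LABELS, reference)
  if (!all(others %in% names(delays)) || anyNA(delays[others]))
    return("noncanonical")
  d <- c(setNames(0, reference), unlist(delays[others]))
  circ_dist <- function(a, b) abs(wrap_half(a - b))
  # within-tripod delays are between adjacent legs (front-middle,
  # middle-rear), as in gait maps; the cross-tripod delay is between
  # the two front legs
  within <- c(circ_dist(d["L2"], d["R1"]), circ_dist(d["R3"], d["L2"]),
              circ_dist(d["R2"], d["L1"]), circ_dist(d["L3"], d["R2"]))
  cross <- circ_dist(d["L1"] - d["R1"], 0.5)
  if (all(within <= tripod_tol) && cross <= tripod_tol)
    return("tripod")
  d <- d[others]
  groups <- c(0, 1 / 3, -1 / 3)
  dist <- vapply(d, function(x) min(circ_dist(x, groups)), numeric(1))
  nearest <- vapply(d, function(x) which.min(circ_dist(x, groups)),
                    integer(1))
  if (all(dist <= tetrapod_tol)) {
    counts <- tabulate(nearest, nbins = 3)
    if (counts[1] == 1 && counts[2] == 2 && counts[3] == 2)
      return("tetrapod")
  }
  "noncanonical"
}

#' Recover M-tripod within-tripod leads from a coordination table
#'
#' Averages, over cycles and over the two tripods, the adjacent-leg
#' delays: front over middle (`delta_meso_pro`) and middle over rear
#' (`delta_meta_meso`), in cycle fractions.  On data generated by
#' [make_m_tripod()] this recovers the configured deltas.
#'
#' @param coord A `coordination_result` from
#'   [normalized_stance_delays()] (reference R1).
#' @return A named numeric vector `delta_meso_pro`, `delta_meta_meso`.
#' @export
m_tripod_deltas <- function(coord) {
  stopifnot(inherits(coord, "coordination_result"))
  dmp <- c(wrap_half(coord$L2 - 0), wrap_half(coord$R2 - coord$L1))
  dmm <- c(wrap_half(coord$R3 - coord$L2), wrap_half(coord$L3 - coord$R2))
  c(delta_meso_pro = mean(dmp, na.rm = TRUE),
    delta_meta_meso = mean(dmm, na.rm = TRUE))
}
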