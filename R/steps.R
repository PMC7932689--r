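#' Segment a walking bout into tripod stance windows
#'
#' Groups the six legs' stances into alternating tripod events
#' (R1-L2-R3 and L1-R2-L3) and sets each step's boundaries at the
#' halfway point between the first touch-down of one tripod and the
#' last lift-off of the preceding tripod.  Events without both flanking
#' tripods are dropped.  The single-support fraction is the fraction of
#' the window during which no opposing-tripod leg is in stance.
#'
#' @param f A [footfall_sequence()] with foothold coordinates.
#' @return A data.frame with one row per tripod stance: `step_id`,
#'   `tripod` ("A" = R1-L2-R3, "B" = L1-R2-L3), `t_start`, `t_end`,
#'   `first_td`, `last_lo`, `single_support_fraction`, and the front /
#'   middle / hind foothold coordinates (`x_front`, `y_front`, ...).
#' @export
tripod_step_windows <- function(f) {
  stopifnot(inherits(f, "footfall_seq"))
  events <- rbind(collect_tripod_events(f, TRIPOD_A, "A"),
                  collect_tripod_events(f, TRIPOD_B, "B"))
  if (is.null(events) || nrow(events) < 3)
    stop("tripod_step_windows: need at least one tripod alternation",
         call. = FALSE)
  events <- events[order(events$first_td), ]
  n <- nrow(events)
  keep <- 2:(n - 1)
  out <- events[keep, , drop = FALSE]
  out$t_start <- (events$first_td[keep] + events$last_lo[keep - 1]) / 2
  out$t_end <- (events$first_td[keep + 1] + events$last_lo[keep]) / 2
  out$step_id <- seq_len(nrow(out))
  out$single_support_fraction <- vapply(seq_len(nrow(out)), function(i) {
    opp <- setdiff(c("A", "B"), out$tripod[i])
    legs <- if (opp == "A") TRIPOD_A else TRIPOD_B
    s <- f[f$leg %in% legs, ]
    occ <- interval_union_length(pmax(s$t_down, out$t_start[i]),
                                 pmin(s$t_up, out$t_end[i]))
    1 - occ / (out$t_end[i] - out$t_start[i])
  }, numeric(1))
  rownames(out) <- NULL
  out[, c("step_id", "tripod", "t_start", "t_end", "first_td", "last_lo",
          "single_support_fraction", "x_front", "y_front", "x_mid",
          "y_mid", "x_hind", "y_hind")]
}

# match each front-leg stance with the nearest middle and hind stances
collect_tripod_events <- function(f, legs, label) {
  front <- f[f$leg == legs[1], ]; mid <- f[f$leg == legs[2], ]
  hind <- f[f$leg == legs[3], ]
  if (!nrow(front) || !nrow(mid) || !nrow(hind)) return(NULL)
  period <- median(diff(sort(front$t_down)))
  if (!is.finite(period)) period <- diff(range(f$t_down, f$t_up))
  rows <- lapply(seq_len(nrow(front)), function(i) {
    td <- front$t_down[i]
    jm <- which.min(abs(mid$t_down - td))
    jh <- which.min(abs(hind$t_down - td))
    if (abs(mid$t_down[jm] - td) > period / 2 ||
        abs(hind$t_down[jh] - td) > period / 2) return(NULL)
    data.frame(
      tripod = label,
      first_td = min(td, mid$t_down[jm], hind$t_down[jh]),
      last_lo = max(front$t_up[i], mid$t_up[jm], hind$t_up[jh]),
      x_front = null_na(front$x_foot[i]), y_front = null_na(front$y_foot[i]),
      x_mid = null_na(mid$x_foot[jm]), y_mid = null_na(mid$y_foot[jm]),
      x_hind = null_na(hind$x_foot[jh]), y_hind = null_na(hind$y_foot[jh]))
  })
  do.call(rbind, rows)
}

null_na <- function(x) if (is.null(x) || !length(x)) NA_real_ else x

# total length of the union of intervals [lo_i, hi_i] (empty ones ignored)
interval_union_length <- function(lo, hi) {
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]
  if (!length(lo)) return(0)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  tot <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] > cur_hi) {
      tot <- tot + cur_hi - cur_lo
      cur_lo <- lo[i]; cur_hi <- hi[i]
    } else cur_hi <- max(cur_hi, hi[i])
  }
  tot + cur_hi - cur_lo
}

# unit vector of the walking direction in the ground plane, from the
# principal axis of the CoM horizontal displacement, oriented forwards
walking_direction <- function(com) {
  if (is.null(com$y) || all(!is.finite(com$y)) || sd(com$y) == 0) {
    return(c(1, 0))
  }
  xy <- cbind(com$x, com$y)
  xy <- sweep(xy, 2, colMeans(xy))
  u <- svd(xy, nu = 0, nv = 1)$v[, 1]
  disp <- c(com$x[nrow(com)] - com$x[1], com$y[nrow(com)] - com$y[1])
  if (sum(u * disp) < 0) u <- -u
  u
}

#' Per-step tripod geometry from footholds and the CoM track
#'
#' The tripod spread is measured along the walking direction:
#' `2L = |x_front - x_hind|` projected onto the direction of travel.
#' The effective foothold is the midpoint of the front and hind
#' footholds.  Mid-stance is the time at which the CoM passes over the
#' effective foothold (`theta = 0`), and `r_m` is the CoM height there.
#' If the CoM never crosses the foothold inside the window the time of
#' maximum height is used instead and the record is flagged.
#'
#' @param step One row of [tripod_step_windows()].
#' @param com CoM trajectory data.frame with `t`, `x`, `z` (and
#'   optionally `y`).
#' @return A list: `L`, `r_m`, `foothold` (projected position along the
#'   walking direction), `foothold_xy`, `t_mid`, `direction`, `flagged`.
#' @export
step_geometry <- function(step, com) {
  sel <- com$t >= step$t_start & com$t <= step$t_end
  if (sum(sel) < 3)
    stop("step_geometry: CoM does not cover the step window", call. = FALSE)
  u <- walking_direction(com)
  proj <- function(x, y) x * u[1] + ifelse(is.na(y), 0, y) * u[2]
  if (anyNA(c(step$x_front, step$x_hind)))
    stop("step_geometry: tripod foothold coordinates missing", call. = FALSE)
  p_front <- proj(step$x_front, step$y_front)
  p_hind <- proj(step$x_hind, step$y_hind)
  L <- abs(p_front - p_hind) / 2
  foot_xy <- c((step$x_front + step$x_hind) / 2,
               mean(c(step$y_front, step$y_hind), na.rm = TRUE))
  p_foot <- proj(foot_xy[1], foot_xy[2])
  tt <- com$t[sel]
  pc <- proj(com$x[sel], if (is.null(com$y)) rep(NA, sum(sel)) else com$y[sel])
  zz <- com$z[sel]
  rel <- pc - p_foot
  flagged <- FALSE
  cross <- which(rel[-length(rel)] <= 0 & rel[-1] > 0)
  if (length(cross)) {
    i <- cross[1]
    frac <- -rel[i] / (rel[i + 1] - rel[i])
    t_mid <- tt[i] + frac * (tt[i + 1] - tt[i])
    r_m <- zz[i] + frac * (zz[i + 1] - zz[i])
  } else {
    i <- which.max(zz)
    t_mid <- tt[i]
    r_m <- zz[i]
    flagged <- TRUE
  }
  list(L = L, r_m = r_m, foothold = p_foot, foothold_xy = foot_xy,
       t_mid = t_mid, direction = u, flagged = flagged)
}

#' Total excursion of a series about its endpoint-to-endpoint line
#'
#' Detrends the series by the straight line through its first and last
#' samples and returns the total excursion of the residual,
#' `max(residual) - min(residual)`.  (A signed sum of the extrema would
#' cancel for symmetric oscillations; the excursion is what the
#' within-step height and speed changes require.)
#'
#' @param y Numeric series (>= 3 samples).
#' @param t Sample times (default equally spaced).
#' @return The excursion (same units as `y`); 0 for an exactly linear
#'   series.
#' @export
detrended_change <- function(y, t = seq_along(y)) {
  stopifnot(length(y) >= 3, length(t) == length(y))
  n <- length(y)
  line <- y[1] + (y[n] - y[1]) * (t - t[1]) / (t[n] - t[1])
  resid <- y - line
  max(resid) - min(resid)
}

#' Summarise one tripod step
#'
#' Combines the window, geometry and CoM descriptors into a step
#' record: mean and initial horizontal speed, distance travelled,
#' duration, within-step speed and height changes (total excursion
#' about the endpoint line, [detrended_change()]), Froude number, and
#' the geometry ratio.
#'
#' @param step One row of [tripod_step_windows()].
#' @param com CoM trajectory data.frame (`t`, `x`, `z`, optional `y`,
#'   `v`).
#' @param leg_length Length scale for the Froude number
#'   `Fr = v^2 / (g leg_length)` (m); defaults to the measured `r_m`.
#' @param g Gravitational acceleration (m/s^2).
#' @return A one-row data.frame (`step_record`): window, tripod,
#'   geometry, speeds, `distance`, `duration`, `delta_v`, `delta_z`,
#'   `Fr`, `L_over_rm`, `single_support_fraction`, `flagged`.
#' @export
step_summary <- function(step, com, leg_length = NULL, g = 9.807) {
  geom <- step_geometry(step, com)
  sel <- com$t >= step$t_start & com$t <= step$t_end
  tt <- com$t[sel]
  u <- geom$direction
  pc <- com$x[sel] * u[1] + (if (is.null(com$y)) 0 else com$y[sel]) * u[2]
  zz <- com$z[sel]
  v <- if (!is.null(com$v)) com$v[sel] else finite_diff(pc, tt)
  n0 <- min(5, length(v))
  if (is.null(leg_length)) leg_length <- geom$r_m
  v_mean <- mean(v)
  out <- data.frame(
    step_id = step$step_id, tripod = step$tripod,
    t_start = step$t_start, t_end = step$t_end, t_mid = geom$t_mid,
    L = geom$L, r_m = geom$r_m, foothold = geom$foothold,
    v_mean = v_mean, v_init = mean(v[seq_len(n0)]),
    distance = pc[length(pc)] - pc[1],
    duration = step$t_end - step$t_start,
    delta_v = detrended_change(v, tt),
    delta_z = detrended_change(zz, tt),
    Fr = v_mean^2 / (g * leg_length),
    L_over_rm = geom$L / geom$r_m,
    single_support_fraction = step$single_support_fraction,
    flagged = geom$flagged)
  class(out) <- c("step_record", "data.frame")
  out
}

#' Filter step records for model fitting
#'
#' Applies the fitting eligibility criteria: single-support fraction of
#' at least `min_ssf` (so that a one-effective-leg model is a fair
#' description of the window), and, when a `fly` column is present, a
#' minimum number of eligible steps per fly (flies contributing fewer
#' steps are dropped from per-fly fits).
#'
#' @param records A data.frame of step records with a
#'   `single_support_fraction` column.
#' @param min_ssf Minimum single-support fraction (default 0.25).
#' @param min_steps_per_fly Minimum eligible steps per fly (default 6),
#'   applied only if `records$fly` exists.
#' @return The filtered data.frame.
#' @export
filter_steps <- function(records, min_ssf = 0.25, min_steps_per_fly = 6) {
  out <- records[records$single_support_fraction >= min_ssf, , drop = FALSE]
  if (!is.null(out$fly)) {
    counts <- table(out$fly)
    keep <- names(counts)[counts >= min_steps_per_fly]
    out <- out[out$fly %in% keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
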