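#' Measured initial conditions of a step
#'
#' The initial leg length and angle follow from the first frame's CoM
#' position relative to the effective foothold; the initial radial and
#' angular speeds are least-squares slopes of `r(t)` and `theta(t)`
#' over the first five frames (three-frame fallback, flagged, when the
#' window is very short).
#'
#' @param com CoM trajectory data.frame (`t`, `x`, `z`).  `x` must
#'   already be relative to the effective foothold (see
#'   [step_geometry()]).
#' @param window Numeric `c(start, end)` (s).
#' @param n_frames Number of frames for the rate estimate (default 5).
#' @return A list `r0`, `theta0`, `r_dot0`, `theta_dot0`, `flagged`.
#' @export
estimate_initial_conditions <- function(com, window, n_frames = 5) {
  sel <- which(com$t >= window[1] & com$t <= window[2])
  flagged <- FALSE
  if (length(sel) < n_frames) {
    if (length(sel) >= 3) {
      n_frames <- 3; flagged <- TRUE
    } else stop("estimate_initial_conditions: fewer than 3 frames in window",
                call. = FALSE)
  }
  idx <- sel[seq_len(n_frames)]
  r <- sqrt(com$x[idx]^2 + com$z[idx]^2)
  th <- atan2(com$x[idx], com$z[idx])
  tt <- com$t[idx] - com$t[idx[1]]
  # local least squares with curvature and jerk terms: the rate at the
  # first frame is the linear coefficient (a straight-line slope would
  # be biased by the deceleration over the window)
  slope <- function(y) {
    if (length(tt) >= 5) unname(coef(lm(y ~ tt + I(tt^2) + I(tt^3)))[2])
    else if (length(tt) >= 4) unname(coef(lm(y ~ tt + I(tt^2)))[2])
    else unname(coef(lm(y ~ tt))[2])
  }
  list(r0 = r[1], theta0 = th[1],
       r_dot0 = slope(r), theta_dot0 = slope(th), flagged = flagged)
}

# parameter box for the constrained fit, in fitting units.
# k_s in N/m (0, 0.050); k_a in N m (0, 50e-9); R within +-10% of R_real;
# initial rates within +-10% of their measured values.
fit_bounds <- function(model, R_real, ic) {
  rate_box <- function(v) {
    half <- 0.10 * abs(v)
    if (half == 0) half <- 1e-12     # stationary measurement: pin the rate
    c(v - half, v + half)
  }
  b <- list(k_s = c(1e-4, 0.050),
            k_a = c(0, 50e-9),
            R = c(0.90, 1.10) * R_real,
            r_dot0 = rate_box(ic$r_dot0),
            theta_dot0 = rate_box(ic$theta_dot0))
  if (model == "slip") b$k_a <- NULL
  b
}

# map a point in the unit box to named parameters
unbox <- function(u, bounds) {
  stats::setNames(
    mapply(function(ui, b) b[1] + ui * (b[2] - b[1]), u, bounds),
    names(bounds))
}

#' Fit SLIP or ARSLIP to one step's CoM trajectory
#'
#' Constrained multi-start fit of the model to the tracked CoM
#' positions over a step window.  The initial leg length and angle are
#' fixed from the data; the spring constants, natural length (within
#' 10% of the measured leg length `R_real`) and the initial rates
#' (within 10% of their measured values) are optimized.  The objective
#' is the sum of the height and horizontal-position RMSEs between the
#' simulated and measured CoM.  The global search is a Latin-hypercube
#' multi-start (`n_starts` starts over the bounded box) with local
#' refinement by box-constrained quasi-Newton (L-BFGS-B); results are
#' reproducible for a fixed `seed`.
#'
#' @param com CoM trajectory with `t`, `x`, `z`; `x` relative to the
#'   effective foothold.
#' @param window Numeric `c(start, end)` (s).
#' @param model `"arslip"` or `"slip"`.
#' @param R_real Measured natural leg length (m).
#' @param m Body mass (kg).
#' @param g Gravitational acceleration (m/s^2).
#' @param seed Integer seed for the multi-start draw.
#' @param n_starts Number of Latin-hypercube starts (default 32).
#' @param extra_starts Optional matrix of additional unit-box start
#'   points (rows), e.g. a SLIP solution to warm-start ARSLIP.
#' @return A `fit_result` list: fitted `k_s`, `k_a` (0 for SLIP), `R`,
#'   `r_dot0`, `theta_dot0`; fixed `r0`, `theta0`; `rmse_z`, `rmse_x`,
#'   `objective` (their sum, m); `converged`, `n_starts`, `seed`,
#'   `model`, and the best unit-box point `u` (for warm starts).
#' @export
fit_step <- function(com, window, model = c("arslip", "slip"), R_real, m,
                     g = 9.807, seed = 1L, n_starts = 32L,
                     extra_starts = NULL) {
  model <- match.arg(model)
  sel <- com$t >= window[1] & com$t <= window[2]
  if (sum(sel) < 5)
    stop("fit_step: fewer than 5 frames in window", call. = FALSE)
  tt <- com$t[sel]; xx <- com$x[sel]; zz <- com$z[sel]
  ic <- estimate_initial_conditions(com, window)
  bounds <- fit_bounds(model, R_real, ic)
  d <- length(bounds)

  objective <- function(u) {
    p <- unbox(u, bounds)
    k_a <- if (model == "slip") 0 else p[["k_a"]]
    prm <- list(k_s = p[["k_s"]], k_a = k_a, R = p[["R"]], m = m, g = g)
    class(prm) <- "arslip_params"
    y0 <- c(ic$r0, ic$theta0, p[["r_dot0"]], p[["theta_dot0"]])
    # fitting tolerance: position error ~1e-11 m, far below tracking
    # noise; the tight default is reserved for energy-audited runs
    out <- tryCatch(integrate_arslip(y0, tt, prm, rtol = 1e-8,
                                     atol = 1e-10),
                    arslip_fall = function(e) e)
    if (inherits(out, "arslip_fall"))
      return(1 + (tt[length(tt)] - out$time) / (tt[length(tt)] - tt[1]))
    x_sim <- out[, "r"] * sin(out[, "theta"])
    z_sim <- out[, "r"] * cos(out[, "theta"])
    sqrt(mean((z_sim - zz)^2)) + sqrt(mean((x_sim - xx)^2))
  }

  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, d)
  # scatter-and-filter: score a coarse deterministic grid over the
  # spring constants and natural length (rates at their measured
  # centres) and promote the best points to full local searches
  uk <- c(0.08, 0.35, 0.62, 0.9)
  grid_u <- if (model == "slip")
    as.matrix(expand.grid(uk, c(0.1, 0.5, 0.9), 0.5, 0.5))
  else as.matrix(expand.grid(uk, uk, c(0.1, 0.5, 0.9), 0.5, 0.5))
  scores <- apply(grid_u, 1, objective)
  starts <- rbind(starts, grid_u[order(scores)[1:4], , drop = FALSE])
  if (!is.null(extra_starts)) starts <- rbind(starts, extra_starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = rep(0, d), upper = rep(1, d),
            control = list(factr = 1e3, pgtol = 1e-14, maxit = 150,
                           ndeps = rep(1e-6, d))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1)
    return(structure(list(model = model, converged = FALSE,
                          objective = Inf, n_starts = n_starts,
                          seed = seed), class = "fit_result"))
  p <- unbox(best$par, bounds)
  # recompute the two RMSE components at the optimum
  prm <- list(k_s = p[["k_s"]],
              k_a = if (model == "slip") 0 else p[["k_a"]],
              R = p[["R"]], m = m, g = g)
  class(prm) <- "arslip_params"
  out <- integrate_arslip(c(ic$r0, ic$theta0, p[["r_dot0"]],
                            p[["theta_dot0"]]), tt, prm)
  rmse_z <- sqrt(mean((out[, "r"] * cos(out[, "theta"]) - zz)^2))
  rmse_x <- sqrt(mean((out[, "r"] * sin(out[, "theta"]) - xx)^2))
  structure(list(
    model = model,
    k_s = p[["k_s"]],
    k_a = if (model == "slip") 0 else p[["k_a"]],
    R = p[["R"]],
    r_dot0 = p[["r_dot0"]], theta_dot0 = p[["theta_dot0"]],
    r0 = ic$r0, theta0 = ic$theta0,
    rmse_z = rmse_z, rmse_x = rmse_x,
    objective = best$value,
    u = best$par, m = m, g = g,
    converged = TRUE, n_starts = n_starts, seed = seed),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("%s fit: did not converge (%d starts)\n",
                toupper(x$model), x$n_starts))
    return(invisible(x))
  }
  cat(sprintf("%s fit: k_s = %.4g N/m, k_a = %.4g N m, R = %.4g m, objective = %.4g m\n",
              toupper(x$model), x$k_s, x$k_a, x$R, x$objective))
  invisible(x)
}

#' Fit both SLIP and ARSLIP to one step
#'
#' Fits SLIP first, then ARSLIP warm-started from the SLIP solution
#' (with the angular spring at zero) in addition to its own
#' Latin-hypercube starts.  Because SLIP is nested in ARSLIP
#' (`k_a = 0`), this guarantees the ARSLIP objective is never worse.
#'
#' @inheritParams fit_step
#' @return A list with elements `slip` and `arslip` ([fit_step()]
#'   results).
#' @export
fit_step_models <- function(com, window, R_real, m, g = 9.807, seed = 1L,
                            n_starts = 32L) {
  slip <- fit_step(com, window, "slip", R_real, m, g,
                   seed = seed, n_starts = n_starts)
  warm <- NULL
  if (slip$converged) {
    u <- slip$u
    # slip box order: k_s, R, r_dot0, theta_dot0 ->
    # arslip box order: k_s, k_a = 0, R, r_dot0, theta_dot0
    warm <- matrix(c(u[1], 0, u[2], u[3], u[4]), nrow = 1)
  }
  arslip <- fit_step(com, window, "arslip", R_real, m, g,
                     seed = seed, n_starts = n_starts,
                     extra_starts = warm)
  list(slip = slip, arslip = arslip)
}

#' Paired SLIP vs ARSLIP comparison over a dataset
#'
#' @param fits A list of [fit_step_models()] results (one per step).
#' @return A list with `table` (per-step objectives for both models),
#'   `median_slip`, `median_arslip`, and `arslip_win_fraction` (ties
#'   split 50/50).
#' @export
compare_models <- function(fits) {
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    data.frame(step = i,
               objective_slip = fits[[i]]$slip$objective,
               objective_arslip = fits[[i]]$arslip$objective)
  }))
  wins <- ifelse(tab$objective_arslip < tab$objective_slip, 1,
                 ifelse(tab$objective_arslip > tab$objective_slip, 0, 0.5))
  list(table = tab,
       median_slip = median(tab$objective_slip),
       median_arslip = median(tab$objective_arslip),
       arslip_win_fraction = mean(wins))
}

#' Per-fly leg stiffness and natural length from step geometry
#'
#' Assumes a single per-leg spring constant `k` and natural leg length
#' `R_tri` for a fly and finds the pair that best reproduces the
#' per-step fitted ARSLIP spring constants through the springy-tripod
#' reduction evaluated at each step's measured geometry `(L, r_m)`.
#' The residual is relative, so the angular (~1e-8 N m) and radial
#' (~1e-2 N/m) constants contribute comparably:
#' `sum_steps [((ka_pred - ka_fit)/ka_fit)^2 + ((ks_pred - ks_fit)/ks_fit)^2]`.
#'
#' @param steps Data.frame with one row per step: `L`, `r_m`, `k_s_fit`,
#'   `k_a_fit`, and optionally `R_fit`.
#' @param R_real Measured leg length (m); `R_tri` is searched within
#'   `[0.75, 1.5] R_real`.
#' @param m Body mass (kg).
#' @param g Gravitational acceleration (m/s^2).
#' @param seed Integer seed.
#' @param n_starts Latin-hypercube starts (default 16).
#' @param min_steps Minimum number of usable steps (default 6).
#' @return A `fly_tripod_fit` list: `k`, `R_tri`, `objective`,
#'   per-step table `steps` with predicted and fitted constants and
#'   their dimensionless versions, Pearson correlations `cor_gamma_a`,
#'   `cor_gamma_s` and `cor_gamma_pooled` (both constants pooled; the
#'   radial constant alone spans only ~1.4-fold over fly-like
#'   geometries, so its own correlation saturates under measurement
#'   noise), implied `R_pred` diagnostics, and indices of any excluded
#'   steps.
#' @export
fit_fly_tripod <- function(steps, R_real, m, g = 9.807, seed = 1L,
                           n_starts = 16L, min_steps = 6L) {
  need <- c("L", "r_m", "k_s_fit", "k_a_fit")
  miss <- setdiff(need, names(steps))
  if (length(miss))
    stop("fit_fly_tripod: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  # exclude steps whose geometry is degenerate anywhere in the R_tri box
  Rtri_hi <- 1.5 * R_real
  s3 <- (steps$L^2 + steps$r_m^2)^1.5
  degenerate <- 3 - 2 * steps$L^2 * Rtri_hi / s3 <= 0 |
    steps$k_a_fit <= 0 | steps$k_s_fit <= 0
  excluded <- which(degenerate)
  if (length(excluded))
    message("fit_fly_tripod: excluding ", length(excluded),
            " step(s) with degenerate geometry or non-positive constants")
  st <- steps[!degenerate, , drop = FALSE]
  if (nrow(st) < min_steps)
    stop(sprintf("fit_fly_tripod: %d usable steps; need at least %d",
                 nrow(st), min_steps), call. = FALSE)
  bounds <- list(k = c(1e-4, 0.050), R_tri = c(0.75, 1.5) * R_real)
  s3 <- (st$L^2 + st$r_m^2)^1.5
  objective <- function(u) {
    p <- unbox(u, bounds)
    ka_pred <- 2 * p[["k"]] * st$L^2 * st$r_m^2 * p[["R_tri"]] / s3
    ks_pred <- p[["k"]] * (3 - 2 * st$L^2 * p[["R_tri"]] / s3)
    if (any(ks_pred <= 0)) return(1e6)
    sum(((ka_pred - st$k_a_fit) / st$k_a_fit)^2 +
          ((ks_pred - st$k_s_fit) / st$k_s_fit)^2)
  }
  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, 2)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = c(0, 0), upper = c(1, 1),
            control = list(factr = 1e3, pgtol = 1e-14, maxit = 500,
                           ndeps = rep(1e-7, 2))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  p <- unbox(best$par, bounds)
  k <- p[["k"]]; R_tri <- p[["R_tri"]]
  pred <- lapply(seq_len(nrow(st)), function(i)
    tripod_to_arslip(tripod_params(k = k, R_tri = R_tri, L = st$L[i],
                                   r_m = st$r_m[i], m = m, g = g)))
  st$k_a_pred <- vapply(pred, `[[`, numeric(1), "k_a")
  st$k_s_pred <- vapply(pred, `[[`, numeric(1), "k_s")
  st$R_pred <- vapply(pred, `[[`, numeric(1), "R")
  R_fit <- if (!is.null(st$R_fit)) st$R_fit else R_real
  st$gamma_a_fit <- st$k_a_fit / (m * g * R_fit)
  st$gamma_s_fit <- st$k_s_fit * R_fit / (m * g)
  st$gamma_a_pred <- st$k_a_pred / (m * g * st$R_pred)
  st$gamma_s_pred <- st$k_s_pred * st$R_pred / (m * g)
  structure(list(
    k = k, R_tri = R_tri, objective = best$value, steps = st,
    cor_gamma_a = cor(st$gamma_a_pred, st$gamma_a_fit),
    cor_gamma_s = cor(st$gamma_s_pred, st$gamma_s_fit),
    # single-number summary of how close all predicted gamma values sit
    # to the fitted ones (both spring constants pooled)
    cor_gamma_pooled = cor(c(st$gamma_a_pred, st$gamma_s_pred),
                           c(st$gamma_a_fit, st$gamma_s_fit)),
    excluded = excluded, seed = seed, n_starts = n_starts),
    class = "fly_tripod_fit")
}

#' @export
print.fly_tripod_fit <- function(x, ...) {
  cat(sprintf("Per-fly tripod fit: k = %.4g N/m, R_tri = %.4g m (%d steps)\n",
              x$k, x$R_tri, nrow(x$steps)))
  cat(sprintf("  predicted-vs-fitted correlation: gamma_a %.3f, gamma_s %.3f\n",
              x$cor_gamma_a, x$cor_gamma_s))
  invisible(x)
}
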