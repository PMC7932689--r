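test_that("equations of motion match direct substitution", {
  p <- arslip_params(k_s = 0.009, k_a = 1.1e-8, R = 2e-3, m = 1e-6)
  st <- com_state(r = 1.8e-3, theta = 0.1, r_dot = 0, theta_dot = 10)
  d <- arslip_derivatives(st, p)
  expect_equal(unname(d["r_ddot"]), -7.77801, tolerance = 1e-5)
  expect_equal(unname(d["theta_ddot"]), 204.4196, tolerance = 1e-5)

  # SLIP is exactly the k_a = 0 case
  p_slip <- arslip_params(k_s = 0.009, k_a = 0, R = 2e-3, m = 1e-6)
  d_slip <- arslip_derivatives(st, p_slip)
  expect_equal(unname(d_slip["theta_ddot"]), 543.9257, tolerance = 1e-5)

  # static fixed point: spring supports the weight, no acceleration
  r_star <- p$R - p$m * p$g / p$k_s
  d0 <- arslip_derivatives(com_state(r = r_star, theta = 0), p)
  expect_equal(unname(d0[c("r_ddot", "theta_ddot")]), c(0, 0),
               tolerance = 1e-12)
})

test_that("total energy sums its terms", {
  p <- arslip_params(k_s = 0.009, k_a = 1.1e-8, R = 2e-3, m = 1e-6)
  st <- com_state(r = 1.8e-3, theta = 0.1, r_dot = 0, theta_dot = 10)
  expect_equal(total_energy(st, p), 1.796141e-8, tolerance = 1e-6)

  # at rest at the fixed point: elastic + gravitational only
  r_star <- p$R - p$m * p$g / p$k_s
  expect_equal(total_energy(com_state(r = r_star, theta = 0), p),
               0.5 * p$k_s * (p$R - r_star)^2 + p$m * p$g * r_star,
               tolerance = 1e-15)
})

test_that("integration conserves energy and holds the fixed point", {
  p <- fly_arslip()
  ic <- initial_conditions(alpha = 0.3, r0 = 1.3e-3, r_dot0 = 1e-3,
                           theta_dot0 = 12)
  traj <- simulate_step(p, ic, seq(0, 0.05, by = 1 / 380))
  E <- trajectory_energy(traj, p)
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-8)
  # model-generated tracks satisfy the polar identities
  expect_equal(traj$x, traj$r * sin(traj$theta), tolerance = 1e-12)
  expect_equal(traj$z, traj$r * cos(traj$theta), tolerance = 1e-12)

  r_star <- p$R - p$m * p$g / p$k_s
  still <- simulate_step(p, initial_conditions(alpha = 0, r0 = r_star),
                         seq(0, 0.05, by = 1 / 380))
  expect_equal(still$x, rep(0, nrow(still)), tolerance = 1e-12)
  expect_equal(still$z, rep(r_star, nrow(still)), tolerance = 1e-10)
})

test_that("pure radial oscillation has the linearized spring period", {
  p <- arslip_params(k_s = 0.009, k_a = 0, R = 2e-3, m = 1e-6)
  r_star <- p$R - p$m * p$g / p$k_s
  ic <- initial_conditions(alpha = 0, r0 = 0.99 * r_star)
  traj <- simulate_step(p, ic, seq(0, 0.2, length.out = 4001))
  peaks <- which(diff(sign(diff(traj$z))) < 0) + 1
  expect_equal(mean(diff(traj$t[peaks])), 2 * pi * sqrt(p$m / p$k_s),
               tolerance = 1e-3)
})

test_that("stiff-spring SLIP converges to the rigid inverted pendulum", {
  # gamma_s = 1e4: leg length essentially frozen at R
  m <- 1e-6; g <- 9.807; R <- 2e-3
  p <- arslip_params(k_s = 1e4 * m * g / R, k_a = 0, R = R, m = m, g = g)
  ic <- initial_conditions(alpha = 0.2, r0 = R, theta_dot0 = 8)
  tt <- seq(0, 0.03, by = 1e-4)
  traj <- simulate_step(p, ic, tt)
  # independent oracle: rigid pendulum theta'' = (g/R) sin(theta),
  # integrated by 4th-order Runge-Kutta on a fine grid
  rk4 <- function(th0, om0, tt) {
    f <- function(y) c(y[2], g / R * sin(y[1]))
    n_sub <- 20
    th <- numeric(length(tt)); y <- c(th0, om0); th[1] <- th0
    for (i in seq_along(tt)[-1]) {
      h <- (tt[i] - tt[i - 1]) / n_sub
      for (j in seq_len(n_sub)) {
        k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
        k4 <- f(y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      th[i] <- y[1]
    }
    th
  }
  th_pend <- rk4(-0.2, 8, tt)
  expect_lt(max(abs(traj$theta - th_pend)), 1e-4)
})

test_that("falls are detected with the failure time", {
  p <- fly_arslip()
  err <- tryCatch(
    simulate_step(p, initial_conditions(alpha = 1.2, r0 = 1.9e-3,
                                        theta_dot0 = -30),
                  seq(0, 0.2, by = 1e-3)),
    error = function(e) e)
  expect_s3_class(err, "arslip_fall")
  expect_true(is.finite(err$time) && err$time > 0)
})

test_that("dense output is converged in the sampling grid", {
  p <- fly_arslip()
  ic <- initial_conditions(alpha = 0.3, r0 = 1.3e-3, theta_dot0 = 12)
  t1 <- seq(0, 0.04, length.out = 41)
  t2 <- seq(0, 0.04, length.out = 81)
  a <- simulate_step(p, ic, t1)
  b <- simulate_step(p, ic, t2)
  expect_lt(max(abs(a$x - b$x[seq(1, 81, 2)])), 1e-9)
  expect_lt(max(abs(a$z - b$z[seq(1, 81, 2)])), 1e-9)
})

test_that("dynamics are invariant under nondimensional rescaling", {
  # same (gamma_s, gamma_a, r_bar0, Omega) at two dimensional scales
  gs <- 2.5; ga <- 0.8
  scale <- list(c(m = 1.123e-6, R = 2e-3), c(m = 2.9e-2, R = 0.31))
  nd_traj <- lapply(scale, function(sc) {
    p <- dimensionalize(gs, ga, m = sc[["m"]], R = sc[["R"]])
    tau <- seq(0, 2, length.out = 101)          # dimensionless time
    tt <- tau * sqrt(p$R / p$g)
    ic <- initial_conditions(alpha = 0.25, r0 = 0.65 * p$R,
                             theta_dot0 = 0.4 * sqrt(p$g / p$R))
    traj <- simulate_step(p, ic, tt)
    cbind(traj$r / p$R, traj$theta)
  })
  expect_lt(max(abs(nd_traj[[1]] - nd_traj[[2]])), 1e-9)
})

test_that("symmetric steps are time-even and sign the kinematic regime", {
  # fly-like: angular spring strong enough for a mid-stance speed maximum
  m <- 1e-6; R <- 2e-3; g <- 9.807
  p_fly <- dimensionalize(2, 0.5, m = m, R = R)
  r_m <- 0.6 * R                # measured fly posture (r_m ~ 1.2 mm)
  Omega <- sqrt(0.01) * p_fly$R / r_m
  st <- simulate_symmetric_step(p_fly, r_m, Omega, half_duration = 0.015)
  expect_lt(max(abs(st$z - rev(st$z))), 1e-9 * max(st$z))
  expect_lt(max(abs(st$v - rev(st$v))), 1e-9 * max(abs(st$v)))
  i0 <- which(st$t == 0)
  idt <- which.min(abs(st$t - 0.02 * 0.015))
  expect_lt(st$v[idt], st$v[i0])               # speed maximum at mid-stance

  # stiff SLIP: walking signature is a mid-stance speed minimum
  p_slip <- dimensionalize(20, 0, m = m, R = R)
  r_m2 <- with(p_slip, R - m * g / k_s)
  st2 <- simulate_symmetric_step(p_slip, r_m2, sqrt(0.01) * p_slip$R / r_m2,
                                 half_duration = 0.015)
  expect_gt(st2$v[which.min(abs(st2$t - 0.0003))], st2$v[which(st2$t == 0)])
})
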