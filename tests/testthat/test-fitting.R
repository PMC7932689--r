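test_that("initial conditions from data: polar conversion and rates", {
  # CoM at (-0.5, 1.8) mm relative to the foothold
  com <- data.frame(t = seq(0, 0.02, by = 1 / 380),
                    x = -0.5e-3, z = 1.8e-3)
  ic <- estimate_initial_conditions(com, c(0, 0.02))
  expect_equal(ic$r0, 1.8681e-3, tolerance = 1e-4)
  expect_equal(ic$theta0, atan2(-0.5, 1.8), tolerance = 1e-12)
  expect_equal(ic$theta0, -0.27095, tolerance = 1e-4)
  expect_equal(ic$r_dot0, 0, tolerance = 1e-12)
  expect_equal(ic$theta_dot0, 0, tolerance = 1e-12)
  expect_false(ic$flagged)
  # short windows fall back to three frames, flagged
  com4 <- com[1:4, ]
  expect_true(estimate_initial_conditions(com4, c(0, 0.011))$flagged)
  expect_error(estimate_initial_conditions(com[1:2, ], c(0, 0.005)),
               "fewer than 3")
})

test_that("measured rates track the true touch-down rates", {
  p <- fly_arslip(k_s = 0.012, R = 2e-3)
  ic_true <- initial_conditions(alpha = 0.3, r0 = 1.3e-3, r_dot0 = 2e-3,
                                theta_dot0 = 11)
  g <- generate_step(p, ic_true, noiseless_config(), seed = 1)
  ic <- estimate_initial_conditions(g$com, range(g$com$t))
  expect_equal(ic$r_dot0, 2e-3, tolerance = 0.02)
  expect_equal(ic$theta_dot0, 11, tolerance = 0.02)
})

test_that("noiseless self-fit recovers the generating parameters", {
  p_true <- fly_arslip(k_s = 0.012, k_a = 1.5e-8, R = 2e-3)
  ic <- initial_conditions(alpha = 0.35, r0 = 1.25e-3, r_dot0 = 2e-3,
                           theta_dot0 = 11)
  g <- generate_step(p_true, ic, noiseless_config(), seed = 5)
  fit <- fit_step(g$com, range(g$com$t), "arslip", R_real = p_true$R,
                  m = p_true$m, seed = 2, n_starts = 8)
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-7)
  nd_t <- nondimensionalize(p_true)
  nd_f <- nondimensionalize(arslip_params(fit$k_s, fit$k_a, fit$R,
                                          p_true$m))
  expect_equal(nd_f$gamma_s, nd_t$gamma_s, tolerance = 0.05)
  expect_equal(nd_f$gamma_a, nd_t$gamma_a, tolerance = 0.05)
  # bit-for-bit reproducibility under the same seed
  fit2 <- fit_step(g$com, range(g$com$t), "arslip", R_real = p_true$R,
                   m = p_true$m, seed = 2, n_starts = 8)
  expect_identical(fit[c("k_s", "k_a", "R", "objective")],
                   fit2[c("k_s", "k_a", "R", "objective")])
})

test_that("ARSLIP nests SLIP: its best objective is never worse", {
  p_true <- fly_arslip(k_s = 0.012, k_a = 1.5e-8, R = 2e-3)
  ic <- initial_conditions(alpha = 0.35, r0 = 1.25e-3, theta_dot0 = 11)
  g <- generate_step(p_true, ic, synthetic_config(), seed = 7)
  both <- fit_step_models(g$com, range(g$com$t), R_real = p_true$R,
                          m = p_true$m, seed = 3, n_starts = 6)
  expect_lte(both$arslip$objective, both$slip$objective + 1e-12)
  # a fly-like step is described far better with the angular spring
  expect_lt(both$arslip$objective, 0.5 * both$slip$objective)
})

test_that("SLIP-generated steps are not beaten by the angular spring", {
  # cockroach-like data: stiff SLIP, no angular spring
  p_slip <- fly_arslip(k_s = 0.03, k_a = 0, R = 2e-3)
  ic <- initial_conditions(alpha = 0.25, r0 = 1.75e-3, theta_dot0 = 9)
  g <- generate_step(p_slip, ic, noiseless_config(), seed = 11)
  both <- fit_step_models(g$com, range(g$com$t), R_real = 2e-3,
                          m = p_slip$m, seed = 5, n_starts = 6)
  expect_lte(both$slip$objective, both$arslip$objective + 1e-7)
})

test_that("model comparison table medians and tie convention", {
  mk <- function(o_s, o_a) list(slip = list(objective = o_s),
                                arslip = list(objective = o_a))
  cmp <- compare_models(list(mk(2, 1), mk(3, 3), mk(1, 2)))
  expect_equal(cmp$arslip_win_fraction, (1 + 0.5 + 0) / 3)
  expect_equal(cmp$median_slip, 2)
  expect_equal(cmp$median_arslip, 2)
  cmp_tie <- compare_models(list(mk(1, 1)))
  expect_equal(cmp_tie$arslip_win_fraction, 0.5)
})

test_that("per-fly spring recovery from exactly mapped steps", {
  k_true <- 0.0084; R_tri_true <- 2.4e-3
  m <- 1.123e-6; R_real <- 2.042e-3
  set.seed(77)
  geoms <- data.frame(r_m = runif(12, 1.1e-3, 1.4e-3))
  geoms$L <- runif(12, 1, 2) * geoms$r_m
  mapped <- lapply(seq_len(12), function(i)
    tripod_to_arslip(tripod_params(k_true, R_tri_true, geoms$L[i],
                                   geoms$r_m[i], m)))
  steps <- data.frame(L = geoms$L, r_m = geoms$r_m,
                      k_s_fit = vapply(mapped, `[[`, numeric(1), "k_s"),
                      k_a_fit = vapply(mapped, `[[`, numeric(1), "k_a"),
                      R_fit = vapply(mapped, `[[`, numeric(1), "R"))
  ft <- fit_fly_tripod(steps, R_real = R_real, m = m, seed = 3)
  expect_equal(ft$k, k_true, tolerance = 0.01)
  expect_equal(ft$R_tri, R_tri_true, tolerance = 0.01)
  expect_gt(ft$cor_gamma_a, 0.999)
  expect_gt(ft$cor_gamma_s, 0.999)
  expect_gt(ft$cor_gamma_pooled, 0.999)

  # fewer than six usable steps is a precondition failure
  expect_error(fit_fly_tripod(steps[1, ], R_real = R_real, m = m),
               "at least 6")
})

test_that("per-fly recovery tolerates multiplicative noise on constants", {
  k_true <- 0.0084; R_tri_true <- 2.4e-3
  m <- 1.123e-6; R_real <- 2.042e-3
  cors <- vapply(1:6, function(sd_seed) {
    set.seed(100 + sd_seed)
    geoms <- data.frame(r_m = runif(30, 0.9e-3, 1.6e-3))
    geoms$L <- runif(30, 1, 2) * geoms$r_m
    mapped <- lapply(seq_len(30), function(i)
      tripod_to_arslip(tripod_params(k_true, R_tri_true, geoms$L[i],
                                     geoms$r_m[i], m)))
    steps <- data.frame(
      L = geoms$L, r_m = geoms$r_m,
      k_s_fit = vapply(mapped, `[[`, numeric(1), "k_s") *
        exp(rnorm(30, 0, 0.1)),
      k_a_fit = vapply(mapped, `[[`, numeric(1), "k_a") *
        exp(rnorm(30, 0, 0.1)),
      R_fit = vapply(mapped, `[[`, numeric(1), "R"))
    ft <- fit_fly_tripod(steps, R_real = R_real, m = m, seed = 3)
    min(ft$cor_gamma_a, ft$cor_gamma_pooled)
  }, numeric(1))
  expect_true(all(cors >= 0.9))
})
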