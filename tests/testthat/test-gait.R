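test_that("footfall validation names the offending row", {
  df <- data.frame(leg = c("R1", "R4"), t_down = c(0, 0.1),
                   t_up = c(0.05, 0.15))
  expect_error(footfall_sequence(df), "R4")
  expect_error(footfall_sequence(data.frame(leg = "R1", t_down = 0.2,
                                            t_up = 0.1)),
               "lift-off")
})

test_that("ideal alternating tripod gives 0 / 0.5 normalized delays", {
  f <- make_m_tripod(0, 0, period = 0.1, duty = 0.5, n_cycles = 10)
  d <- normalized_stance_delays(f)
  expect_equal(nrow(d), 9)
  expect_equal(d$L2, rep(0, 9))
  expect_equal(d$R3, rep(0, 9))
  expect_equal(d$L1, rep(0.5, 9))
  expect_equal(d$period, rep(0.1, 9))
  expect_equal(d$duty, rep(0.5, 9))
})

test_that("stance-start delays are signed and nearest-event matched", {
  # L2 lands 10 ms after R1, period 100 ms
  f <- footfall_sequence(data.frame(
    leg = rep(c("R1", "L2"), each = 3),
    t_down = c(0, 0.1, 0.2, 0.01, 0.11, 0.21),
    t_up = c(0, 0.1, 0.2, 0.01, 0.11, 0.21) + 0.05))
  expect_equal(normalized_stance_delays(f)$L2, c(0.1, 0.1))
  # L2 lands 10 ms before R1: negative delay
  f2 <- footfall_sequence(data.frame(
    leg = rep(c("R1", "L2"), each = 3),
    t_down = c(0, 0.1, 0.2, -0.01, 0.09, 0.19),
    t_up = c(0, 0.1, 0.2, -0.01, 0.09, 0.19) + 0.05))
  expect_equal(normalized_stance_delays(f2)$L2, c(-0.1, -0.1))
})

test_that("delay estimation is translation- and scale-invariant", {
  f <- make_m_tripod(0.06, 0.04, period = 0.08, duty = 0.6, n_cycles = 8)
  d <- normalized_stance_delays(f)
  shifted <- f; shifted$t_down <- f$t_down + 3.7; shifted$t_up <- f$t_up + 3.7
  d_sh <- normalized_stance_delays(footfall_sequence(shifted))
  expect_equal(d_sh[LEG_LABELS[-1]], d[LEG_LABELS[-1]])
  scaled <- f; scaled$t_down <- f$t_down * 2.5; scaled$t_up <- f$t_up * 2.5
  d_sc <- normalized_stance_delays(footfall_sequence(scaled))
  expect_equal(d_sc[LEG_LABELS[-1]], d[LEG_LABELS[-1]])
  expect_equal(d_sc$period, 2.5 * d$period)
})

test_that("M-tripod schedule closes the loop with the delay analysis", {
  f <- make_m_tripod(0.05, 0.08, period = 0.1, duty = 0.6, n_cycles = 8)
  d <- normalized_stance_delays(f)
  expect_equal(mean(d$L2), 0.05, tolerance = 1e-10)
  expect_equal(mean(d$R3), 0.13, tolerance = 1e-10)
  expect_equal(m_tripod_deltas(d),
               c(delta_meso_pro = 0.05, delta_meta_meso = 0.08),
               tolerance = 1e-10)
  # every stance lasts duty * period
  expect_equal(unique(round(f$t_up - f$t_down, 12)), 0.06)
  expect_error(make_m_tripod(0.6, 0, period = 0.1, duty = 0.5, n_cycles = 2),
               "0.5")
})

test_that("stance and swing durations follow their speed laws", {
  f <- footfall_sequence(data.frame(leg = "R1", t_down = c(0.10, 0.21),
                                    t_up = c(0.18, 0.29)))
  s <- stance_swing_durations(f)
  expect_equal(s$stance[1], 0.08)
  expect_equal(s$swing[1], 0.03)
  expect_true(is.na(s$swing[2]))

  # regression recovery of the linear swing law on synthetic intervals
  set.seed(11)
  n <- 200
  v <- runif(n, 8, 35)                         # mm/s
  swing_true <- 0.03 - 0.00018 * v
  swing_obs <- swing_true + rnorm(n, 0, 0.002)
  fit <- lm(swing_obs ~ v)
  expect_lt(abs(coef(fit)[2] - (-0.00018)) / 0.00018, 0.30)

  # reciprocal stance law: R^2 of the 1/v fit
  stance_obs <- 1.4 / v + rnorm(n, 0, 0.004)
  fit2 <- lm(stance_obs ~ I(1 / v))
  expect_gt(summary(fit2)$r.squared, 0.95)
})

test_that("dataset stance durations obey the configured speed laws", {
  cfg <- synthetic_config(n_steps = 30, seed = 21)
  ds <- generate_fly_dataset(cfg)
  s <- stance_swing_durations(ds$footfalls, ds$com)
  # join each stance to its cycle speed through the ground truth
  v_cyc <- ds$truth$v[match(ds$footfalls$cycle, ds$truth$cycle)]
  ok <- !is.na(v_cyc)
  expect_equal(s$stance[ok], cfg$stance_coef / v_cyc[ok], tolerance = 1e-9)
  # the reference leg (offset 0) carries the swing law exactly
  r1 <- ok & ds$footfalls$leg == "R1" & !is.na(s$swing)
  expect_equal(s$swing[r1],
               cfg$swing_intercept + cfg$swing_slope_mm * 1000 * v_cyc[r1],
               tolerance = 0.15)
  # measured window speeds track the cycle speeds
  expect_gt(cor(s$speed[ok & !is.na(s$speed)], v_cyc[ok & !is.na(s$speed)]),
            0.9)
})

test_that("analytic-signal phase of a cosine advances linearly", {
  t <- seq(0, 2, by = 1 / 380)
  tr <- data.frame(t = t, leg = "R1", y_body = cos(2 * pi * 10 * t),
                   stance = TRUE)
  ph <- suppressWarnings(leg_phases(tr))
  n <- nrow(ph)
  keep <- round(0.1 * n):round(0.9 * n)
  up <- cumsum(c(ph$phase[1], {
    d <- diff(ph$phase); d - 2 * pi * round(d / (2 * pi))
  }))[keep]
  fit <- lm(up ~ ph$t[keep])
  expect_equal(coef(fit)[[2]], 2 * pi * 10, tolerance = 1e-3)
  expect_lt(max(abs(resid(fit))), 0.05)
})

test_that("phase delays recover offsets between identical waveforms", {
  t <- seq(0, 2, by = 1 / 380)
  f <- 10
  # quarter-period lag between two sinusoidal tracks
  tr <- rbind(
    data.frame(t = t, leg = "R1", y_body = cos(2 * pi * f * t), stance = TRUE),
    data.frame(t = t, leg = "L2", y_body = cos(2 * pi * f * (t - 0.025)),
               stance = TRUE))
  ph <- suppressWarnings(leg_phases(tr))
  ff <- footfall_sequence(data.frame(leg = "R1",
                                     t_down = seq(0.3, 1.5, by = 0.1),
                                     t_up = seq(0.3, 1.5, by = 0.1) + 0.06))
  pd <- phase_delays(ph, ff)
  expect_equal(mean(pd$L2), 0.25, tolerance = 0.01)

  # identical traces: zero delay; antiphase: +-0.5
  tr2 <- rbind(
    data.frame(t = t, leg = "R1", y_body = cos(2 * pi * f * t), stance = TRUE),
    data.frame(t = t, leg = "R2", y_body = cos(2 * pi * f * t), stance = TRUE),
    data.frame(t = t, leg = "L1", y_body = cos(2 * pi * f * t + pi),
               stance = TRUE))
  pd2 <- phase_delays(suppressWarnings(leg_phases(tr2)), ff)
  expect_equal(mean(pd2$R2), 0, tolerance = 1e-6)
  expect_equal(abs(circular_mean_cycles(pd2$L1)), 0.5, tolerance = 1e-6)
})

test_that("triangle-wave tracks obey the stance 0 -> pi convention", {
  f <- make_m_tripod(0, 0, period = 0.1, duty = 0.6, n_cycles = 20)
  lt <- arslip:::make_leg_tracks(f, seq(0, 2, by = 1 / 380), 1e-3)
  ph <- leg_phases(lt)
  pr <- ph[ph$leg == "R1", ]
  up <- arslip:::unwrap_phase(pr$phase)
  at <- function(tt) arslip:::wrap_half(approx(pr$t, up, tt)$y / (2 * pi)) *
    2 * pi
  tds <- f$t_down[f$leg == "R1"]
  ph_td <- at(tds[tds > 0.3 & tds < 1.7])
  expect_true(all(abs(ph_td) <= 0.3))
  # lift-off near pi (end of stance)
  tus <- f$t_up[f$leg == "R1"]
  ph_tu <- at(tus[tus > 0.3 & tus < 1.7])
  expect_true(all(abs(abs(ph_tu) - pi) <= 0.4))
})

test_that("stance-start and phase delays agree on noiseless M-tripod data", {
  f <- make_m_tripod(0.05, 0.08, period = 0.1, duty = 0.6, n_cycles = 20)
  lt <- arslip:::make_leg_tracks(f, seq(0, 2, by = 1 / 380), 1e-3)
  pd <- phase_delays(leg_phases(lt), f)
  sd_ <- normalized_stance_delays(f)
  for (lg in LEG_LABELS[-1]) {
    diff_lg <- arslip:::wrap_half(circular_mean_cycles(pd[[lg]]) -
                                    mean(sd_[[lg]]))
    expect_lt(abs(diff_lg), 0.05)
  }
})

test_that("gait templates classify tripod, tetrapod and random delays", {
  f <- make_m_tripod(0, 0, period = 0.1, duty = 0.5, n_cycles = 4)
  d <- normalized_stance_delays(f)
  expect_equal(classify_step_gait(d[1, ]), "tripod")
  # M-tripods up to 0.1-cycle leads stay tripod
  for (dl in c(0.04, 0.08, 0.1)) {
    fm <- make_m_tripod(dl, dl, period = 0.1, duty = 0.6, n_cycles = 4)
    dm <- normalized_stance_delays(fm)
    expect_equal(classify_step_gait(dm[1, ]), "tripod")
  }
  # canonical tetrapod: pairs at 0, 1/3, 2/3 of the cycle
  tet <- c(L2 = 0, R3 = 1 / 3, L1 = 1 / 3, R2 = 2 / 3, L3 = 2 / 3)
  expect_equal(classify_step_gait(tet), "tetrapod")
  expect_equal(classify_step_gait(c(L2 = NA, R3 = 0, L1 = 0.5, R2 = 0.5,
                                    L3 = 0.5)), "noncanonical")

  # uniform-random delays are overwhelmingly noncanonical
  set.seed(99)
  labels <- replicate(1000, {
    d <- setNames(runif(5, -0.5, 0.5), c("L1", "R2", "L2", "R3", "L3"))
    classify_step_gait(d)
  })
  expect_gte(mean(labels == "noncanonical"), 0.90)
})
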