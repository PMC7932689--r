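# shared fixtures: fly-scale parameters and a quiet noiseless config

fly_arslip <- function(k_s = 0.009, k_a = 1.1e-8, R = 2.042e-3,
                       m = 1.123e-6, g = 9.807)
  arslip_params(k_s = k_s, k_a = k_a, R = R, m = m, g = g)

noiseless_config <- function(...)
  synthetic_config(sigma_z = 0, sigma_x = 0, ...)

# random valid tripod parameters for property sweeps (fly-like scales)
random_tripod <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    r_m <- runif(1, 0.8e-3, 1.6e-3)
    L <- runif(1, 0.5, 2.5) * r_m
    tripod_params(k = runif(1, 0.002, 0.02),
                  R_tri = runif(1, 1.5e-3, 3e-3),
                  L = L, r_m = r_m, m = 1.123e-6)
  })
}

# energy along a trajectory data.frame
trajectory_energy <- function(traj, p) {
  0.5 * p$m * (traj$r_dot^2 + traj$r^2 * traj$theta_dot^2) +
    0.5 * p$k_s * (p$R - traj$r)^2 + 0.5 * p$k_a * traj$theta^2 +
    p$m * p$g * traj$r * cos(traj$theta)
}

circular_mean_cycles <- function(x) Arg(mean(exp(2i * pi * x))) / (2 * pi)
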