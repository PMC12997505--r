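# Published reference estimates used as ground truth / frozen oracles.

# dose-time response posterior means (log-BEC model)
ref_dose_time <- list(
  e0 = -0.2601, e1 = -0.6583, e2 = 0.5128, e3 = 0.5084, emax = -2.6047,
  lned50 = 2.9513, ke = 0.0207, slp = 1.2358, f = 2.3730,
  s2b11 = 0.2096, s2b12 = -0.2058, s2b13 = 0.0550,
  s2b22 = 0.5194, s2b23 = -0.2120, s2b33 = 0.3850, s2y = 0.0804)

# population PK/PD table: theta, SE pairs
ref_pkpd <- list(
  kro = c(theta = -1.73, se = 0.0529),
  kout = c(theta = -4.35, se = 0.0921),
  ic50 = c(theta = -2.34, se = 0.0789),
  imax = c(theta = -1.77, se = 0.0265),
  gama = c(theta = 1.61, se = 0.0559),
  omega2_kro = 0.0853, omega2_imax = 0.294, sigma = 0.350)

# a small, fast truth for fitting tests: published means with published
# random-effect covariance and residual variance
fit_truth <- function() depemokimab_dose_time_params()

# compact Phase-I-like config for fitting tests
fit_config <- function(seed = 1L)
  phase1_config(n_per_arm = 8,
                sampling_days = c(29, 57, 85, 113, 169, 225, 280),
                seed = seed)
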