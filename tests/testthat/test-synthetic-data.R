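test_that("noise-free placebo profile is flat and equals the placebo submodel", {
  truth <- dose_time_params(e0 = -0.26, e1 = -0.66, e2 = 0.51, e3 = 0.51,
                            emax = -2.6, lned50 = 2.95, ke = 0.02, slp = 1.2)
  cfg <- phase1_config(dose_arms = 0, n_per_arm = 4, seed = 42)
  panel <- generate_phase1(cfg, truth)
  for (id in unique(panel$ID)) {
    pi <- panel[panel$ID == id, ]
    expected <- exp(truth$e1 + truth$e3 * log(pi$BASE[1]))
    expect_equal(pi$DV, rep(expected, nrow(pi)), tolerance = 1e-12)
  }
})

test_that("with zero variance components the generator is deterministic in (dose, day, baseline)", {
  truth <- dose_time_params(e0 = -0.26, e1 = -0.66, e2 = 0.51, e3 = 0.51,
                            emax = -2.6, lned50 = 2.95, ke = 0.02, slp = 1.2,
                            f = 2.4)
  cfg <- phase1_config(n_per_arm = 3, baseline_gsd = 1, seed = 1)
  p1 <- generate_phase1(cfg, truth)
  p2 <- generate_phase1(phase1_config(n_per_arm = 3, baseline_gsd = 1, seed = 99),
                        truth)
  expect_equal(p1$DV, p2$DV) # seed-free given all noise off
  mu <- predict_log_bec(truth, p1$DOSE, p1$DAY, log(p1$BASE))
  expect_equal(log(p1$DV), mu, tolerance = 1e-12)
})

test_that("generator mean matches an independent Monte Carlo evaluation of the model formula", {
  truth <- fit_truth()
  n <- 10000
  cfg <- phase1_config(dose_arms = 300, n_per_arm = n,
                       sampling_days = 57, seed = 5)
  panel <- generate_phase1(cfg, truth)
  gen_mean <- mean(log(panel$DV))

  # independent route: direct vectorized evaluation of the formula over
  # freshly drawn baselines, random effects and residuals
  set.seed(1234)
  ch <- chol(truth$s2b)
  sdlog <- log(cfg$baseline_gsd)
  base <- numeric(n)
  for (i in seq_len(n)) {
    repeat { x <- rlnorm(1, log(cfg$baseline_gm), sdlog); if (x >= 0.2) break }
    base[i] <- x
  }
  b <- matrix(rnorm(3 * n), n, 3) %*% ch
  arg <- truth$slp * (b[, 3] + truth$lned50 + truth$ke * (57 - 182) - log(300))
  mu <- b[, 1] + truth$e0 + truth$e2 * log(base) +
    (truth$emax + b[, 2] - truth$e0) / (1 + exp(arg))
  oracle <- mu + rnorm(n, 0, sqrt(truth$s2y))
  mc_se <- sqrt(var(oracle) / n + var(log(panel$DV)) / n)
  expect_lt(abs(gen_mean - mean(oracle)), 3 * mc_se)
})

test_that("default 48-subject panel has the first-in-human record structure", {
  panel <- generate_phase1(phase1_config(seed = 3), fit_truth())
  expect_equal(length(unique(panel$ID)), 48)
  expect_gt(nrow(panel), 550)           # ~620-record panel
  expect_lt(nrow(panel), 700)
  n57 <- sum(panel$DAY >= 57)
  expect_gt(n57, 250)                   # ~290 modelling records
  expect_lt(n57, 340)
  expect_equal(sum(panel$DAY == 29), 48) # one validation visit per subject
  expect_true(all(panel$BASE >= 0.2))    # screening floor
  expect_true(all(panel$DV > 0))
})

test_that("per-subject seed streams are stable when arms are added", {
  truth <- fit_truth()
  p1 <- generate_phase1(phase1_config(dose_arms = c(0, 10), n_per_arm = 4,
                                      seed = 7), truth)
  p2 <- generate_phase1(phase1_config(dose_arms = c(0, 10, 300), n_per_arm = 4,
                                      seed = 7), truth)
  expect_equal(p1$DV, p2$DV[p2$DOSE %in% c(0, 10)])
})

test_that("non-positive-definite covariance is rejected naming the matrix", {
  bad <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, -1), 3, 3)
  expect_error(dose_time_params(e0 = 0, e1 = 0, e2 = 0, e3 = 0, emax = -1,
                                lned50 = 3, ke = 0.02, slp = 1, s2b = bad),
               "s2b")
})

test_that("exacerbation counts follow the NB mean/variance law", {
  design <- trial_design(active_doses = 10, n_per_arm = 100000)
  # Poisson limit: huge dispersion parameter
  pois <- exacerbation_params(lambda0 = 2, emax_frac = 0, k = 1e8)
  d <- generate_exacerbation_counts(design, pois, seed = 1)
  x <- d$COUNT[d$DOSE == 0]
  expect_equal(mean(x), 2, tolerance = 0.02)
  expect_equal(var(x), 2, tolerance = 0.05)
  # NB variance identity: var = mu + mu^2/k = 7 for mu 2, k 0.8
  nb <- exacerbation_params(lambda0 = 2, emax_frac = 0, k = 0.8)
  d2 <- generate_exacerbation_counts(design, nb, seed = 2)
  y <- d2$COUNT[d2$DOSE == 0]
  expect_equal(mean(y), 2, tolerance = 0.03)
  expect_equal(var(y), 7, tolerance = 0.05)
  # annualized rate is exactly count / T
  p3 <- exacerbation_params(lambda0 = 2, emax_frac = 0.5, followup_years = 0.5)
  d3 <- generate_exacerbation_counts(trial_design(100, 50), p3, seed = 3)
  expect_true(all(d3$COUNT >= 0 & d3$COUNT == round(d3$COUNT)))
  expect_equal(d3$RATE, d3$COUNT / 0.5)
})

test_that("invalid exacerbation parameters are rejected", {
  expect_error(exacerbation_params(k = 0), "dispersion")
  expect_error(exacerbation_params(lambda0 = -1), "lambda0")
  expect_error(exacerbation_params(emax_frac = 1.2), "emax_frac")
})

test_that("disease baseline sampler honors fixed, degenerate and lognormal modes", {
  expect_equal(sample_baseline_bec("EGPA", 5, fixed = TRUE), rep(1.0, 5))
  expect_equal(sample_baseline_bec("HES", 3, gm = 1.4, gsd = 1), rep(1.4, 3))
  x <- sample_baseline_bec("severe_asthma", 50000, gm = 0.3, gsd = 2, seed = 1)
  expect_equal(exp(mean(log(x))), 0.3, tolerance = 0.01)
  expect_error(sample_baseline_bec("psoriasis", 5), "unknown disease")
})
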