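pd <- pd_params()
pk <- pk_params()

test_that("PK closed form starts at zero, is linear in dose and matches an ODE oracle", {
  reg <- regimen(100, n_doses = 1)
  expect_equal(pk_concentration(0, reg, pk), 0)
  tt <- seq(0, 364, by = 1)
  c100 <- pk_concentration(tt, reg, pk)
  c200 <- pk_concentration(tt, regimen(200, n_doses = 1), pk)
  expect_equal(c200, 2 * c100, tolerance = 1e-12)
  # numeric integration of the two-state absorption system
  rhs <- function(t, y, p) list(c(-pk$ka * y[1],
                                  pk$ka * y[1] / pk$v_f - pk$ke * y[2]))
  num <- deSolve::lsoda(c(a = 100, c = 0), tt, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(num[-1, "c"] - c100[-1]) / num[-1, "c"]), 1e-6)
  expect_error(pk_concentration(-1, reg, pk), "negative")
})

test_that("multi-dose superposition adds Bateman terms at each administration", {
  reg2 <- regimen(100, interval_weeks = 26, n_doses = 2)
  t_post <- 7 * 26 + 35
  expect_equal(pk_concentration(t_post, reg2, pk),
               pk_concentration(t_post, regimen(100, n_doses = 1), pk) +
                 pk_concentration(35, regimen(100, n_doses = 1), pk),
               tolerance = 1e-12)
})

test_that("individual parameters follow the covariate equations exactly", {
  s_ref <- realize_subject(pd, 0.26, "none")
  expect_equal(s_ref$kro, exp(-1.73), tolerance = 1e-10)   # printed 0.177
  expect_equal(s_ref$imax, exp(-1.77), tolerance = 1e-10)  # printed 0.170
  expect_equal(s_ref$kout, 24 * exp(-4.35), tolerance = 1e-10)
  s_sa <- realize_subject(pd, 0.26, "severe_asthma")
  expect_equal(s_sa$kro, exp(-1.73 + 0.438), tolerance = 1e-10) # 0.2747
  # baseline covariate on both KRO and Imax
  s_hi <- realize_subject(pd, 0.52, "none")
  expect_equal(s_hi$kro, exp(-1.73 + 0.563 * log(2)), tolerance = 1e-10)
  expect_equal(s_hi$imax, exp(-1.77 - 0.380 * log(2)), tolerance = 1e-10)
  # 200622 multiplier and etas
  s6 <- realize_subject(pd, 0.26, "HES", etas = c(0.1, -0.2),
                        study200622 = TRUE)
  expect_equal(s6$kro, exp(-1.73 + 1.27 + 0.1) * 0.5, tolerance = 1e-10)
  expect_error(realize_subject(pd, 0.26, c("HES", "EGPA")), "exactly one")
  expect_error(realize_subject(pd, 0.26, "none", etas = c(0, 3)), "Imax")
})

test_that("reporting transforms reproduce the published footnote arithmetic", {
  expect_equal(ci_backtransform(-1.73, 0.0529), c(0.160, 0.197),
               tolerance = 0.003)
  expect_equal(ci_backtransform(-1.77, 0.0265), c(0.162, 0.179),
               tolerance = 0.003)
  expect_equal(24 * ci_backtransform(-4.35, 0.0921)[2], 0.371,
               tolerance = 0.002)
  expect_equal(ci_linear(1.61, 0.0559)[2], 1.72, tolerance = 0.003)
  expect_equal(rse_pct(abs(-1.73), 0.0529), 3.06, tolerance = 0.005)
  expect_equal(cv_pct(0.0853), 29.8, tolerance = 0.05)
  expect_equal(cv_pct(0.294), 58.5, tolerance = 0.05)
})

test_that("turnover steady states match the analytic closed form", {
  s <- realize_subject(pd, 0.26, "none")
  horizon <- 4000 # ~many turnover half-lives, reach steady state
  for (conc in c(0, s$ic50, 1000 * s$ic50)) {
    sol <- solve_turnover(s, function(t) rep(conc, length(t)), horizon,
                          grid = c(0, horizon), rtol = 1e-10, atol = 1e-12)
    expect_equal(sol$eos[2], turnover_steady_state(s, conc),
                 tolerance = 1e-6)
  }
  # named identities: no drug -> kro; C = IC50 -> half-maximal; C >> IC50 -> floor
  expect_equal(turnover_steady_state(s, 0), s$kro)
  expect_equal(turnover_steady_state(s, s$ic50),
               s$kro * (1 + (s$imax - 1) / 2), tolerance = 1e-12)
  expect_equal(turnover_steady_state(s, 1e9), s$kro * s$imax,
               tolerance = 1e-6)
})

test_that("trajectories are positive and the convolution solution tracks the ODE", {
  s <- realize_subject(pd, 0.26, "severe_asthma")
  reg <- regimen(100)
  cf <- function(t) pk_concentration(t, reg, pk)
  ode <- solve_turnover(s, cf, 364, rtol = 1e-10, atol = 1e-12)
  expect_true(all(ode$eos > 0))
  conv <- turnover_convolution(s, cf, ode$day, dt = 0.25)
  expect_lt(max(abs(ode$eos - conv$eos) / ode$eos), 2e-3)
  expect_equal(conv$eos[1], s$kro) # pre-dose steady state
})

test_that("population percent reduction is monotone in dose and zero without drug", {
  red <- vapply(c(0, 25, 100, 400), function(d)
    simulate_population(pd, pk, regimen(d), "CRSwNP", n = 60,
                        seed = 5)$pct_reduction_end, 1)
  expect_equal(red[1], 0, tolerance = 1e-8)
  expect_true(all(diff(red) > 0))
})

test_that("with variances at zero the reduction matches the analytic typical value", {
  pd0 <- pd_params(omega2_kro = 0, omega2_imax = 0)
  # sustained saturating exposure: floor = imax fraction of baseline
  reg_big <- regimen(1e6, interval_weeks = 8, n_doses = 7, horizon_weeks = 52)
  sim <- simulate_population(pd0, pk, reg_big, "EGPA", n = 20, seed = 1,
                             baseline_fixed = 0.26)
  imax_typ <- exp(pd0$theta_imax) # baseline 0.26 GI/L: covariate term zero
  expect_equal(sim$pct_reduction_end, 100 * (1 - imax_typ), tolerance = 0.5)
})

test_that("EGPA true-baseline scenario: 200 mg dominates 100 mg at every timepoint", {
  s100 <- simulate_population(pd, pk, regimen(100), "EGPA", n = 150, seed = 42,
                              baseline_fixed = 1.0)
  s200 <- simulate_population(pd, pk, regimen(200), "EGPA", n = 150, seed = 42,
                              baseline_fixed = 1.0)
  post <- s100$summary$day > 0
  expect_true(all(s200$summary$gm[post] < s100$summary$gm[post]))
})
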