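test_that("a point-mass posterior reproduces the transcribed log-ratio oracles", {
  pm <- as.data.frame(ref_dose_time)[rep(1, 3), ]
  # frozen independent transcriptions at (100 mg, Day 182)
  expect_equal(unique(simulate_change_from_placebo(pm, 100, 182)),
               -2.07573299669, tolerance = 1e-9)
  expect_equal(unique(simulate_change_from_placebo(pm, 100, 182,
                                                   mode = "arm_contrast")),
               -1.68346012074, tolerance = 1e-9)
})

test_that("null treatment effect gives zero log ratio; saturating dose the full contrast", {
  null <- data.frame(e0 = -0.3, e1 = -0.3, e2 = 0.5, e3 = 0.5, emax = -0.3,
                     lned50 = 3, ke = 0.02, slp = 1.2, f = 1)
  for (d in c(5, 60, 300))
    expect_equal(simulate_change_from_placebo(null, d, 182), 0)
  big <- data.frame(e0 = -0.3, e1 = -0.3, e2 = 0.5, e3 = 0.5, emax = -2.6,
                    lned50 = 3, ke = 0.02, slp = 1.2, f = 1)
  expect_equal(simulate_change_from_placebo(big, 1e9, 182,
                                            mode = "arm_contrast"),
               big$emax - big$e0, tolerance = 1e-6)
  expect_error(simulate_change_from_placebo(null[0, ], 10, 182), "empty")
  expect_error(simulate_change_from_placebo(null, 0, 182), "> 0")
})

test_that("decision rules classify the canonical cases and form a partition", {
  th <- decision_thresholds()
  expect_equal(classify_decision(0.90, 0.20, th), "go")
  expect_equal(classify_decision(0.70, 0.05, th), "no_go")
  expect_equal(classify_decision(0.70, 0.15, th), "consider")
  expect_error(classify_decision(0.5, 0.6, th), "ordering")
  # partition over a lattice of valid pairs
  pm <- runif(500); pt <- pm * runif(500)
  dec <- classify_decision(pm, pt, th)
  expect_true(all(dec %in% c("go", "consider", "no_go")))
  expect_length(dec, 500)
})

test_that("threshold monotonicity: looser go_prob grows the go set, tighter nogo_prob the no-go set", {
  set.seed(5)
  pm <- runif(300); pt <- pm * runif(300)
  strict <- decision_thresholds(go_prob = 0.9, nogo_prob = 0.05)
  loose <- decision_thresholds(go_prob = 0.7, nogo_prob = 0.05)
  expect_true(all(classify_decision(pm, pt, strict) != "go" |
                    classify_decision(pm, pt, loose) == "go"))
  tight_ng <- decision_thresholds(go_prob = 0.8, nogo_prob = 0.2)
  base_ng <- decision_thresholds(go_prob = 0.8, nogo_prob = 0.1)
  expect_true(all(classify_decision(pm, pt, base_ng) != "no_go" |
                    classify_decision(pm, pt, tight_ng) == "no_go"))
})

test_that("invalid thresholds are rejected", {
  expect_error(decision_thresholds(mv_reduction = 0.9, tv_reduction = 0.8),
               "deeper")
  expect_error(decision_thresholds(go_prob = 0.1, nogo_prob = 0.5),
               "nogo_prob")
})

draws <- synthetic_posterior_normal(n = 4000, seed = 77)
grid <- build_qdm_grid(draws)

test_that("the QDM grid respects its structural invariants", {
  expect_equal(nrow(grid), 144) # 12 x 12
  expect_true(all(grid$p_tv <= grid$p_mv + 1e-12))
  expect_true(all(grid$p_mv >= 0 & grid$p_mv <= 1))
  expect_true(all(grid$decision %in% c("go", "consider", "no_go")))
  # dose monotonicity of p_mv at fixed day (2 mg excepted: its effective
  # dose is 2F with F ~ 2.4, so it can exceed the 5 mg cell)
  for (d in unique(grid$day)) {
    sub <- grid[grid$day == d & grid$dose > 2, ]
    sub <- sub[order(sub$dose), ]
    expect_true(all(diff(sub$p_mv) >= -0.02))
  }
})

test_that("grids are reproducible at a fixed seed and degenerate thresholds collapse p_mv = p_tv", {
  g2 <- build_qdm_grid(synthetic_posterior_normal(n = 4000, seed = 77))
  expect_identical(as.data.frame(grid), as.data.frame(g2))
  th_eq <- decision_thresholds(mv_reduction = 0.7999999, tv_reduction = 0.8)
  g3 <- build_qdm_grid(draws, th_eq, doses = c(10, 100), days = c(100, 200))
  expect_equal(g3$p_mv, g3$p_tv, tolerance = 0.005)
  expect_true(all(g3$decision %in% c("go", "consider", "no_go")))
})

test_that("sampled-threshold mode behaves like point mode as the SE shrinks", {
  th_s <- decision_thresholds(threshold_mode = "sampled", mv_se = 1e-9,
                              tv_se = 1e-9)
  g_s <- build_qdm_grid(draws, th_s, doses = c(30, 100), days = 182, seed = 3)
  g_p <- build_qdm_grid(draws, decision_thresholds(), doses = c(30, 100),
                        days = 182)
  expect_equal(g_s$p_mv, g_p$p_mv, tolerance = 1e-6)
})

test_that("the reference posterior classifies all doses >= 60 mg at Day 182 as go and low late doses no-go", {
  g <- build_qdm_grid(draws, doses = qdm_default_grid()$doses, days = 182)
  expect_true(all(g$decision[g$dose >= 60] == "go"))
  expect_true(all(g$p_mv[g$dose >= 60] > 0.8))
  late <- build_qdm_grid(draws, doses = c(2, 5), days = 280)
  expect_true(all(late$decision == "no_go"))
})
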