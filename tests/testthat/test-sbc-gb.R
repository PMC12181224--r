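th <- thresholds(1, 1.3)

test_that("linear SBC rule is weight-independent and region-driven", {
  r <- sbc_rule(th, k_d = -1, k_p = 1, eta = 1)
  expect_equal(sbc_linear_delta(0.5, r), 0)
  expect_equal(sbc_linear_delta(1.1, r), -1)
  r0 <- sbc_rule(th, k_d = -1, k_p = 1, eta = 0)
  expect_equal(sbc_linear_delta(2, r0), 0)
})

test_that("SBC decay rule has fixed points 0, k_D/lambda, k_P/lambda", {
  r <- sbc_rule(th, k_d = -1, k_p = 1, lambda = 0.5, eta = 1)
  expect_equal(sbc_decay_delta(1.1, w = -1 / 0.5, r), 0)  # depressive fp
  expect_equal(sbc_decay_delta(0.5, w = 0, r), 0)         # pre-depressive fp
  expect_equal(sbc_decay_delta(2, w = 2, r), 0)           # k_P / lambda = 2
  # lambda = 0 silently reduces to the linear rule
  rl <- sbc_rule(th, k_d = -1, k_p = 1, lambda = 0, eta = 0.3)
  expect_equal(sbc_decay_delta(1.1, w = 5, rl), sbc_linear_delta(1.1, rl))
})

test_that("calcium-dependent learning rate scales the approach, not the fixed points", {
  eta_fun <- step_fun(c(1, 1.3), values = c(0.01, 0.4, 0.9), sharpness = 80)
  r <- sbc_rule(th, k_d = -1, k_p = 1, lambda = 0.5, eta = eta_fun)
  # at the fixed point, zero change for any eta
  expect_equal(sbc_cadep_delta(1.1, w = -2, r), 0, tolerance = 1e-9)
  # larger eta(ca) within a region -> larger |dw|, same sign
  w <- 1.5
  d_low <- sbc_cadep_delta(1.05, w, r)
  d_high <- sbc_cadep_delta(1.25, w, r)
  expect_lt(d_low, 0)
  expect_lt(d_high, d_low)
  # eta(ca) ~ 0 at very low calcium
  r2 <- sbc_rule(th, k_d = -1, k_p = 1, lambda = 0.5,
                 eta = step_fun(c(1, 1.3), values = c(0, 0.4, 0.9)))
  expect_equal(sbc_cadep_delta(0.2, w = 7, r2), 0)
})

test_that("original GB rule implements the cumulative three-branch sum", {
  r <- gb_rule(th, w_star = 0.5, eta_d = 1, eta_p = 2, tau = 1)
  # roots of the cubic drift in the pre-depressive region
  expect_equal(gb_delta(0.5, c(0, 0.5, 1), r), c(0, 0, 0))
  # direct substitution: -0.25 * 0.75 * 0.25
  expect_equal(gb_delta(0.5, 0.25, r), -0.046875)
  # w = 1 is not a fixed point in the potentiative region: tau*dw = -eta_D
  expect_equal(gb_delta(2, 1, r), -1)
  # tau scales the step
  r2 <- gb_rule(th, w_star = 0.5, eta_d = 1, eta_p = 2, tau = 4)
  expect_equal(gb_delta(2, 1, r2), -0.25)
})

test_that("GB rule with rates zero reduces to the pure cubic drift", {
  r <- gb_rule(th, w_star = 0.3, eta_d = 0, eta_p = 0, tau = 1)
  for (ca in c(0.2, 1.1, 2)) {
    expect_equal(gb_delta(ca, c(0, 0.3, 1), r), c(0, 0, 0))
    w <- c(0.1, 0.2, 0.5, 0.9)
    expect_equal(gb_delta(ca, w, r), -w * (1 - w) * (0.3 - w))
  }
})

test_that("simplified GB rule activates exactly one branch", {
  r <- gb_simplified_rule(th, w_star = 0.5, eta_drift = 0.05, eta_d = 0.1,
                          eta_p = 0.2)
  expect_equal(gb_simplified_delta(0.5, 0.5, r), 0)   # at w*
  expect_equal(gb_simplified_delta(2, 1, r), 0)       # potentiative fp
  expect_equal(gb_simplified_delta(1.1, 0.4, r), -0.04)
  # drift directions around w*
  expect_lt(gb_simplified_delta(0.5, 0.4, r), 0)
  expect_gt(gb_simplified_delta(0.5, 0.6, r), 0)
})

test_that("GB integration converges to the expected states", {
  r <- gb_simplified_rule(th, w_star = 0.5, eta_drift = 0.01, eta_d = 0.05,
                          eta_p = 0.05)
  pot <- integrate_rule(calcium_trace(rep(2, 2000), 1), 0.1, r)
  expect_equal(pot$values[2000], 1, tolerance = 1e-6)
  drift_up <- integrate_rule(calcium_trace(rep(0, 5000), 1), 0.6, r)
  expect_equal(drift_up$values[5000], 1, tolerance = 1e-6)
  drift_down <- integrate_rule(calcium_trace(rep(0, 5000), 1), 0.4, r)
  expect_equal(drift_down$values[5000], 0, tolerance = 1e-6)
  # original rule: drift pushes away from w* in the pre-depressive region
  ro <- gb_rule(th, w_star = 0.5, eta_d = 0.5, eta_p = 1, tau = 10)
  up <- integrate_rule(calcium_trace(rep(0.5, 20000), 1), 0.6, ro)
  expect_equal(up$values[20000], 1, tolerance = 1e-3)
  # efficacy-to-weight mapping
  rw <- gb_rule(th, w_up = 2, w_down = 0.5)
  expect_equal(efficacy_to_weight(c(0, 1, 0.5), rw), c(0.5, 2, 1.25))
})
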