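test_that("isolated low-frequency spikes give small per-spike depression", {
  # at very low frequency each 1.05-high transient dwells
  # tau * log(1.05 / 1) ~ 0.49 ms in the depressive region
  res <- run_frequency_protocol(0.5, w0 = 1)
  expect_equal(res$summary$dwell_potentiative, 0)
  expect_equal(res$summary$dwell_depressive, 5 * 10 * log(1.05 / 1),
               tolerance = 0.1)
  expect_lt(res$summary$dw, 0)
  expect_gt(res$summary$dw, -0.1)
  expect_error(run_frequency_protocol(-1), "positive")
})

test_that("high-frequency stimulation potentiates weak synapses and depresses strong ones", {
  hi_weak <- run_frequency_protocol(100, w0 = 1)
  expect_gt(hi_weak$summary$dw, 0)
  expect_gt(hi_weak$summary$dwell_potentiative, 0)
  hi_strong <- run_frequency_protocol(100, w0 = 2.2)
  expect_lt(hi_strong$summary$dw, 0)
})

test_that("frequency sweep is consistent, weight-monotone, and changes sign with frequency", {
  fg <- c(1, 10, 50, 100)
  wg <- c(0.42, 1, 1.8, 2.25)
  tab <- frequency_sweep(fg, wg)
  # single cell reproduces the single run exactly
  one <- run_frequency_protocol(50, w0 = 1)
  expect_equal(tab$dw[tab$freq == 50 & tab$w0 == 1], one$summary$dw)
  # cannot depress below the depressive fixed point
  expect_true(all(tab$dw[tab$w0 == 0.42] >= -1e-9))
  # dw nonincreasing in w0 at each frequency
  for (f in fg) {
    dws <- tab$dw[tab$freq == f][order(wg)]
    expect_true(all(diff(dws) <= 1e-12))
  }
  # sign reversal along the frequency axis at baseline weight
  at1 <- tab$dw[tab$w0 == 1][order(fg)]
  expect_lt(at1[1], 0)
  expect_gt(at1[length(at1)], 0)
  # potentiative dwell nondecreasing with frequency
  dwellp <- unique(tab[, c("freq", "dwell_potentiative")])
  expect_true(all(diff(dwellp$dwell_potentiative[order(dwellp$freq)]) >= 0))
})

test_that("a lone postsynaptic spike nearly cancels between regions", {
  res <- run_stdp_pair(0, lone = "post")
  expect_equal(res$summary$dwell_potentiative, 7 * log(1.55 / 1.3),
               tolerance = 0.05)
  expect_equal(res$summary$dwell_depressive, 7 * log(1.3 / 1),
               tolerance = 0.05)
  # potentiation on the way up is almost exactly balanced by depression on
  # the way down
  lobe <- abs(run_stdp_pair(10)$summary$dw)
  expect_lt(abs(res$summary$dw), 0.2 * lobe)
})

test_that("STDP pairing gives the classic sign structure", {
  expect_gt(run_stdp_pair(10)$summary$dw, 0)   # pre before post
  expect_lt(run_stdp_pair(-10)$summary$dw, 0)  # post before pre
  # curve decays to ~0 for long intervals
  lobe <- abs(run_stdp_pair(10)$summary$dw)
  expect_lt(abs(run_stdp_pair(60)$summary$dw), 0.25 * lobe)
  # strong weights shift the curve downward
  expect_lt(run_stdp_pair(10, w0 = 2.2)$summary$dw,
            run_stdp_pair(10, w0 = 0.5)$summary$dw)
})

test_that("non-overlapping events compose as sequential closed-form relaxations", {
  # at |delta_t| = 100 ms >> tau_Ca the two transients do not overlap, so the
  # combined effect equals running the lone-pre episode and feeding its final
  # weight into the lone-post episode
  combined <- run_stdp_pair(100, w0 = 1)
  a <- run_stdp_pair(100, w0 = 1, lone = "pre")
  b <- run_stdp_pair(100, w0 = a$summary$w_final, lone = "post")
  expect_equal(combined$summary$w_final, b$summary$w_final, tolerance = 1e-9)
})

test_that("stdp sweep matches single runs and repeats accumulate", {
  tab <- stdp_sweep(c(-20, 10), c(0.8, 1.5))
  one <- run_stdp_pair(10, w0 = 0.8)
  expect_equal(tab$dw[tab$delta_t == 10 & tab$w0 == 0.8], one$summary$dw)
  ten <- run_stdp_pair(10, w0 = 1, n_pairings = 10)
  expect_gt(ten$summary$dw, 5 * run_stdp_pair(10, w0 = 1)$summary$dw)
})

test_that("late-phase endpoints depend on protein synthesis", {
  ltd_p <- run_late_phase_experiment("LTD", "present")
  expect_equal(ltd_p$summary$percent_of_baseline, 61, tolerance = 0.01)
  ltp_p <- run_late_phase_experiment("LTP", "present")
  expect_equal(ltp_p$summary$percent_of_baseline, 142, tolerance = 0.01)
  ltp_a <- run_late_phase_experiment("LTP", "absent")
  expect_equal(ltp_a$summary$percent_of_baseline, 100, tolerance = 0.01)
  expect_error(run_late_phase_experiment("LTX"), "LTP")
  # early phase reaches the early fixed points before the late drift
  tr <- ltd_p$weights
  n_early <- 9  # 9 s at 1-s steps
  expect_equal(tr$values[n_early], 0.42, tolerance = 1e-9)
})

test_that("phase-plane grids expose the weight dependence of each rule", {
  r <- demo_rule1d()
  pp <- phase_plane(r, ca_grid = c(0.5, 1.1, 2), w_grid = c(0, 0.5, 1))
  expect_equal(nrow(pp), 9)
  # dw is nonincreasing in w at fixed calcium
  for (ca in c(0.5, 1.1, 2)) {
    d <- pp$dw[pp$ca == ca]
    expect_true(all(diff(d[order(c(0, 0.5, 1))]) <= 0))
  }
  expect_equal(pp$dw[pp$ca == 2 & pp$w == 0], 0.25)
})
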