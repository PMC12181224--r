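test_that("1D FPLR delta moves toward the fixed point by the eta fraction", {
  r <- demo_rule1d()
  expect_equal(fplr1d_delta(2, 0, r), 0.25)     # F = 1, eta = 0.25, w = 0
  expect_equal(fplr1d_delta(1.1, 0, r), 0)      # at the depressive fp
  # eta = 1 jumps straight to the fixed point
  r1 <- fplr_rule1d(thresholds(1, 1.3), F = c(0.5, 0, 1), eta = c(1, 1, 1))
  for (w in c(-2, 0.3, 5)) expect_equal(w + fplr1d_delta(2, w, r1), 1)
  # learning rates above 1 are rejected at construction
  expect_error(fplr_rule1d(thresholds(1, 1.3), F = c(0.5, 0, 1),
                           eta = c(0, 0.5, 1.2)), "\\[0, 1\\]")
})

test_that("one FPLR step contracts the distance to the fixed point by exactly 1 - eta", {
  set.seed(42)
  for (i in 1:50) {
    r <- random_rule1d()
    ca <- stats::runif(1, 0, 3)
    w <- stats::runif(1, -1, 3)
    fp <- eval_step(r$F, ca)
    eta <- eval_step(r$eta, ca)
    w1 <- w + fplr1d_delta(ca, w, r)
    expect_equal(abs(w1 - fp), (1 - eta) * abs(w - fp), tolerance = 1e-14)
  }
})

test_that("closed-form relaxation matches its definition", {
  r <- demo_rule1d()
  expect_equal(closed_form_weight(0.8, 1.1, 5, 5, r), 0.8)  # zero elapsed
  # half-life identity: depressive region has F = 0
  eta_c <- eta_continuous(0.15, 1)
  t_half <- log(2) / eta_c
  expect_equal(closed_form_weight(1, 1.1, 0, t_half, r), 0.5)
  expect_error(closed_form_weight(1, 1.1, 5, 4, r), "t_end")
})

test_that("discrete integration matches the closed-form oracle under constant calcium", {
  set.seed(7)
  for (i in 1:20) {
    r <- random_rule1d()
    ca <- stats::runif(1, 0, 3)
    w0 <- stats::runif(1, -1, 3)
    n <- 400L
    traj <- integrate_rule(calcium_trace(rep(ca, n), 1), w0, r)
    fp <- eval_step(r$F, ca)
    eta <- eval_step(r$eta, ca)
    # exact geometric relaxation
    expect_equal(traj$values, fp + (w0 - fp) * (1 - eta)^(1:n),
                 tolerance = 1e-12)
    # continuous-rate closed form agrees to < 1e-8 relative
    if (eta < 1) {
      cf <- closed_form_weight(w0, ca, 0, n, r)
      expect_equal(traj$values[n], cf, tolerance = 1e-8)
    }
  }
})

test_that("trajectories stay inside the hull of the start and the fixed points", {
  set.seed(11)
  for (i in 1:20) {
    r <- random_rule1d()
    w0 <- stats::runif(1, -0.5, 2.5)
    ca <- calcium_trace(stats::runif(500, 0, 3), 1)
    w <- integrate_rule(ca, w0, r)$values
    lo <- min(w0, r$F$values) - 1e-12
    hi <- max(w0, r$F$values) + 1e-12
    expect_true(all(w >= lo & w <= hi))
  }
})

test_that("basin validation reports violations instead of raising", {
  expect_length(validate_basins(c(0.2, 0.5, 0.8), c(0, 0.3, 0.7, 1),
                                c(0.1, 0.1, 0.1)), 0)
  v <- validate_basins(c(0.8), c(0, 0.3), c(0.1))
  expect_match(v, "outside its basin")
  v2 <- validate_basins(c(0.2, 0.5, 0.8), c(0, 0.7, 0.3, 1),
                        c(0.1, 0.1, 0.1))
  expect_match(v2, "not strictly increasing", all = FALSE)
  v3 <- validate_basins(c(0.5), c(0, 1), c(1.5))
  expect_match(v3, "outside \\[0, 1\\]")
  expect_error(basin_spec(c(0.8), c(0, 0.3), c(0.1)), "invalid basin")
})

test_that("2D lookup returns the basin of the current weight", {
  r <- tri_stable_rule2d()
  expect_equal(lookup_2d(0.5, 0.25, r)$F, 0.2)
  expect_equal(lookup_2d(0.5, 0.65, r)$F, 0.5)
  expect_equal(lookup_2d(0.5, 0.75, r)$F, 0.8)
  # a boundary is an unstable fixed point
  expect_equal(lookup_2d(0.5, 0.3, r)$F, 0.3)
  expect_equal(fplr2d_delta(0.5, 0.3, r), 0)
  # scalar regions behave like the 1D rule
  expect_equal(fplr2d_delta(2, 0.4, r), 0.2 * (1 - 0.4))
  expect_equal(fplr2d_delta(0.5, 0.5, r), 0)       # MIDDLE state
  expect_gt(fplr2d_delta(0.5, 0.75, r), 0)         # drifts up toward 0.8
  expect_error(lookup_2d(0.5, 1.5, r), "outside basin range")
})

test_that("half-stable boundaries join the requested basin", {
  bs <- basin_spec(c(0.2, 0.8), c(0, 0.5, 1), c(0.1, 0.1),
                   boundary_mode = c("unstable", "right", "unstable"))
  r <- fplr_rule2d(thresholds(1, 1.3),
                   regions = list(bs, c(F = 0, eta = 0.1),
                                  c(F = 1, eta = 0.1)))
  fe <- lookup_2d(0.5, 0.5, r)
  expect_equal(fe$F, 0.8)
  expect_gt(fplr2d_delta(0.5, 0.5, r), 0)
})

test_that("pre-depressive drift converges within its basin and never exits", {
  r <- tri_stable_rule2d()
  pre <- calcium_trace(rep(0.5, 3000), 1)
  cases <- list(c(0.05, 0.2, 0, 0.3), c(0.45, 0.5, 0.3, 0.7),
                c(0.69, 0.5, 0.3, 0.7), c(0.95, 0.8, 0.7, 1))
  for (cs in cases) {
    w <- integrate_rule(pre, cs[1], r)$values
    expect_true(all(w > cs[3] & w < cs[4]))
    expect_equal(w[length(w)], cs[2], tolerance = 1e-9)
  }
})

test_that("protein gating dispatches between the 1D and 2D sub-rules", {
  no_p <- fplr_rule1d(thresholds(1, 1.3), F = c(1, 0, 2),
                      eta = c(0.005, 0.3, 0.3))
  with_p <- tri_stable_rule2d()
  pg <- protein_gated_rule(no_p, with_p)
  for (ca in c(0.4, 1.1, 2)) {
    w <- 0.42
    expect_equal(protein_gated_delta(ca, w, 0, pg),
                 fplr1d_delta(ca, w, no_p))
    expect_equal(protein_gated_delta(ca, w, 1, pg),
                 fplr2d_delta(ca, w, with_p))
  }
  expect_error(protein_gated_delta(1, 0.5, 2, pg), "0 or 1")
  # sub-rules must share thresholds
  other <- fplr_rule1d(thresholds(0.9, 1.3), F = c(1, 0, 2),
                       eta = c(0, 0.3, 0.3))
  expect_error(protein_gated_rule(other, with_p), "share")
})

test_that("a plasticity delay shifts the response without changing it", {
  r <- demo_rule1d(drift = FALSE)
  tr <- calcium_trace(c(rep(2, 50), rep(0, 50)), 1)
  plain <- integrate_rule(tr, 0.3, r)$values
  lag <- integrate_rule(tr, 0.3, r, delay_steps = 10)$values
  expect_equal(lag[1:10], rep(0.3, 10))           # nothing happens yet
  expect_equal(lag[11:100], plain[1:90])          # then the same response
  expect_error(integrate_rule(tr, 0.3, r, delay_steps = -1), "non-negative")
})

test_that("integrate_rule handles constant rules and protein traces", {
  r <- fplr_rule1d(thresholds(1, 1.3), F = c(0.5, 0, 1), eta = c(0, 0, 0))
  tr <- calcium_trace(stats::runif(100, 0, 3), 1)
  expect_equal(integrate_rule(tr, 0.7, r)$values, rep(0.7, 100))
  pg <- protein_gated_rule(
    fplr_rule1d(thresholds(1, 1.3), F = c(1, 0, 2), eta = c(0.01, 0.3, 0.3)),
    tri_stable_rule2d())
  expect_error(integrate_rule(tr, 0.5, pg, protein = c(0, 1)), "length")
  # switching the protein on mid-trace changes the attractor
  tr0 <- calcium_trace(rep(0.5, 4000), 1)
  wA <- integrate_rule(tr0, 0.75, pg, protein = 0)$values
  wB <- integrate_rule(tr0, 0.75, pg, protein = 1)$values
  expect_equal(wA[4000], 1, tolerance = 1e-6)    # baseline without protein
  expect_equal(wB[4000], 0.8, tolerance = 1e-6)  # UP basin with protein
})
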