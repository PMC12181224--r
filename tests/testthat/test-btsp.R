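test_that("receptive fields are Gaussian in circular track distance", {
  cfg <- track_config(T = 10000, N = 1000, r = 400, P_max = 0.02)
  expect_equal(receptive_field_rate(3500, 3500, cfg), 0.02)
  expect_equal(receptive_field_rate(3500, 3500 + 400, cfg), 0.02 / exp(1))
  # wraparound: a field at 0 sees a location just before the seam as nearby
  expect_equal(receptive_field_rate(0, 10000 - 5, cfg),
               0.02 * exp(-(5 / 400)^2))
  expect_equal(synapse_at(3500, cfg), 351)
  expect_equal(synapse_at(9999, cfg), 1)  # nearest center wraps to 0
})

test_that("Bernoulli spike sampling is bounded, concentrated, and reproducible", {
  expect_length(sample_spikes(rep(0, 1000))$times, 0)
  expect_error(sample_spikes(c(0.5, 1.2)), "\\[0, 1\\]")
  n <- 1e5; p <- 0.01
  st <- sample_spikes(rep(p, n), seed = 123)
  expect_lt(abs(length(st$times) - n * p), 4 * sqrt(n * p * (1 - p)))
  st2 <- sample_spikes(rep(p, n), seed = 123)
  expect_identical(st$times, st2$times)
})

test_that("the neuron leaks to rest, clamps during the plateau, and sums spikes", {
  np <- neuron_params()
  expect_equal(neuron_step(-75, 0, FALSE, np), -75)
  expect_equal(neuron_step(-60, 123, TRUE, np), -30)
  # a 1 mV displacement decays e-fold in tau_V
  expect_equal(neuron_step(-74, 0, FALSE, np, dt = 15), -75 + exp(-1))
  # each spike adds syn_scale * w / C_m
  expect_equal(neuron_step(-75, 2.5, FALSE, np), -75 + 0.4 * 2.5)
})

test_that("synapse calcium combines local decay with the broadcast plateau", {
  cp <- btsp_calcium_params()
  s <- synapse_calcium_step(c(0, 0.5), 0, spikes = c(1, 0),
                            plateau_active = TRUE, cp)
  expect_equal(s$ca_plateau, 1.33)
  expect_equal(s$ca_pre, c(0.1, 0.5 * exp(-1 / 2000)))
  expect_equal(s$total, s$ca_pre + 1.33)
  # plateau decays with tau_Ca once the induction ends
  s2 <- synapse_calcium_step(s$ca_pre, s$ca_plateau, c(0, 0), FALSE, cp,
                             dt = 2000)
  expect_equal(s2$ca_plateau, 1.33 * exp(-1))
})

test_that("a silent session leaves voltage, calcium and weights untouched", {
  p <- small_btsp_preset(N = 20, T = 2000, P_max = 0)
  ses <- run_btsp_session(laps = 2, inductions = NULL, preset = p, seed = 1,
                          record = 5)
  expect_true(all(ses$voltage == -75))
  expect_true(all(ses$ca_rec == 0))
  expect_true(all(ses$weights_final == 0.2))
  expect_true(all(ses$dwell_depressive == 0))
})

test_that("the voltage is clamped to V_plateau at every induction step", {
  p <- small_btsp_preset(N = 20, T = 2000)
  ses <- run_btsp_session(laps = 2, inductions = c("2" = 500), preset = p,
                          seed = 4, record = 2)
  on <- which(ses$plateau)
  expect_equal(length(on), 300)
  expect_true(all(ses$voltage[on] == -30))
})

test_that("identical seeds give bit-identical sessions", {
  p <- small_btsp_preset(N = 30, T = 3000)
  a <- run_btsp_session(laps = 2, inductions = c("2" = 1000), preset = p,
                        seed = 99, record = 3)
  b <- run_btsp_session(laps = 2, inductions = c("2" = 1000), preset = p,
                        seed = 99, record = 3)
  expect_identical(a$voltage, b$voltage)
  expect_identical(a$weights_final, b$weights_final)
  c <- run_btsp_session(laps = 2, inductions = c("2" = 1000), preset = p,
                        seed = 100, record = 3)
  expect_false(identical(a$voltage, c$voltage))
})

test_that("the compiled session loop matches a plain R reference", {
  p <- small_btsp_preset(N = 4, T = 1000)
  laps <- 2; n_steps <- 2000
  set.seed(5)
  spikes <- matrix(rbinom(4 * n_steps, 1, 0.01), nrow = 4)
  ses <- run_btsp_session(laps = laps, inductions = c("2" = 300), preset = p,
                          record = 1:4, spikes = spikes)
  # R reference using the exported single-step operations
  np <- p$neuron; cp <- p$calcium; rule <- p$rule
  w <- rep(0.2, 4); ca_pre <- rep(0, 4); ca_plat <- 0; V <- np$V_rest
  Vv <- numeric(n_steps); W <- matrix(0, 4, n_steps); CA <- matrix(0, 4, n_steps)
  for (s in seq_len(n_steps)) {
    plateau <- (s - 1) >= 1300 && (s - 1) < 1600
    sp <- spikes[, s]
    syn_in <- sum(w * sp)
    st <- synapse_calcium_step(ca_pre, ca_plat, sp, plateau, cp)
    ca_pre <- st$ca_pre; ca_plat <- st$ca_plateau
    w <- w + fplr1d_delta(st$total, w, rule)
    V <- neuron_step(V, syn_in, plateau, np)
    Vv[s] <- V; W[, s] <- w; CA[, s] <- st$total
  }
  expect_equal(ses$voltage, Vv, tolerance = 1e-12)
  expect_equal(ses$weights_final, w, tolerance = 1e-12)
  expect_equal(unname(ses$w_rec), W, tolerance = 1e-12)
  expect_equal(unname(ses$ca_rec), CA, tolerance = 1e-12)
})

test_that("the 7-lap schedule forms, overwrites, and coexists place fields", {
  ses <- run_btsp_session(seed = 2, record = c(201, 351, 751))
  # weights stay inside [F_D, F_P]
  expect_true(all(ses$weights_final >= 0.2 - 1e-9))
  expect_true(all(ses$weights_final <= 2.5 + 1e-9))
  # lap 3: a single ramp bracketing the 3.5 s induction location
  r3 <- longest_ramps(ses, 3)
  expect_gte(nrow(r3), 1)
  main3 <- r3[which.max(r3$end - r3$start), ]
  expect_lt(main3$start, 3500)
  expect_gt(main3$end, 3500)
  # lap 5: the field has moved earlier (overwritten toward 2 s)
  r5 <- longest_ramps(ses, 5)
  main5 <- r5[which.max(r5$end - r5$start), ]
  expect_lt(main5$start, main3$start)
  expect_lt(abs(main5$start + main5$end - 2 * 2000), 3500)
  # lap 7: two fields coexist (near 2 s and near 7.5 s)
  r7 <- longest_ramps(ses, 7)
  expect_gte(nrow(r7), 2)
  mids <- (r7$start + r7$end) / 2
  expect_true(any(mids < 5000) && any(mids > 5000))
  # overwrite selectivity: synapses at the depressive fixed point are never
  # pushed below it, even though their calcium visits the depressive region
  i20 <- match(201, ses$record_idx)
  lap2 <- (ses$steps_per_lap + 1):(2 * ses$steps_per_lap)
  expect_gt(ses$dwell_depressive[201, 2], 0)
  expect_true(all(ses$w_rec[i20, lap2] >= 0.2 - 1e-9))
  # S3.5 potentiates during lap 2 and is depressed back by the lap-4
  # induction at 2 s
  i35 <- match(351, ses$record_idx)
  w35 <- ses$w_rec[i35, ]
  expect_gt(max(w35[lap2]), 1.5)
  expect_lt(ses$weights_final[351], 0.6)
  # S7.5 stays potentiated after lap 6
  expect_gt(ses$weights_final[751], 0.6)
})

test_that("the mirror schedule yields the mirror-image outcome", {
  ses <- run_btsp_session(inductions = c("2" = 6500, "4" = 8000,
                                         "6" = 2500),
                          seed = 2, record = c(251, 651, 801))
  r3 <- longest_ramps(ses, 3)
  main3 <- r3[which.max(r3$end - r3$start), ]
  expect_lt(main3$start, 6500)
  expect_gt(main3$end, 6500)
  r7 <- longest_ramps(ses, 7)
  mids <- (r7$start + r7$end) / 2
  expect_true(any(abs(mids - 8000) < 2000) && any(abs(mids - 2500) < 2000))
  expect_true(all(ses$weights_final >= 0.2 - 1e-9))
  # the first field (6.5 s) is overwritten by the nearby 8 s induction;
  # judge by the mean weight of the ~40 synapses around each location
  near <- function(loc) {
    i <- synapse_at(loc, ses$track)
    mean(ses$weights_final[(i - 20):(i + 20)])
  }
  expect_gt(near(8000), 0.5)
  expect_gt(near(2500), 0.5)
  expect_lt(near(6500), near(8000))
  expect_lt(near(6500), near(2500))
})

test_that("the weight-change map shows the BTSP weight dependence", {
  tab <- weight_change_map(w0_grid = c(0.2, 2.4), dist_grid = c(0, 4000),
                           seeds = 1:3)
  near_lo <- tab$dw[tab$distance == 0 & tab$w0 == 0.2]
  near_hi <- tab$dw[tab$distance == 0 & tab$w0 == 2.4]
  far_lo <- tab$dw[tab$distance == 4000 & tab$w0 == 0.2]
  far_hi <- tab$dw[tab$distance == 4000 & tab$w0 == 2.4]
  expect_gt(near_lo, 0.5)          # fields at the induction potentiate
  expect_lt(near_hi, 0)            # strong synapses there depress
  expect_lt(abs(far_lo), 0.05)     # far weak synapses barely change
  expect_lt(far_hi, 0)             # far strong synapses depress slightly
  expect_gt(far_hi, near_hi)
})
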