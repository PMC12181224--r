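# shared rule fixtures, built in code

# the canonical illustrative 1D rule: drift to 0.5, depress to 0, potentiate
# to 1, with rates 0.015 / 0.15 / 0.25 per step
demo_rule1d <- function(dt = 1, drift = TRUE, sharpness = NULL) {
  fplr_rule1d(thresholds(1, 1.3),
              F = c(0.5, 0, 1),
              eta = c(if (drift) 0.015 else 0, 0.15, 0.25),
              dt = dt, sharpness = sharpness)
}

# tri-stable pre-depressive drift: DOWN 0.2 / MIDDLE 0.5 / UP 0.8 with basin
# boundaries [0, 0.3, 0.7, 1]
tri_stable_rule2d <- function(dt = 1) {
  fplr_rule2d(thresholds(1, 1.3),
              regions = list(
                basin_spec(c(0.2, 0.5, 0.8), c(0, 0.3, 0.7, 1),
                           c(0.01, 0.02, 0.01)),
                c(F = 0, eta = 0.1),
                c(F = 1, eta = 0.2)),
              dt = dt)
}

# random 1D rule for property-style tests
random_rule1d <- function() {
  th <- sort(stats::runif(2, 0.5, 2.5))
  fplr_rule1d(thresholds(th[1], th[2]),
              F = stats::runif(3, 0, 2),
              eta = stats::runif(3, 0, 1),
              dt = 1)
}

# BTSP preset with a small, fast track for structural tests
small_btsp_preset <- function(N = 5, T = 2000, P_max = 0.02) {
  p <- load_preset("btsp")
  p$track <- track_config(T = T, N = N, r = 400, P_max = P_max)
  p
}

longest_ramps <- function(session, lap, min_ms = 500) {
  r <- detect_ramps(session, lap)
  r <- r[r$end - r$start >= min_ms, , drop = FALSE]
  r[order(r$start), , drop = FALSE]
}
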