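#' Circular-track configuration for the place-field simulation
#'
#' `N` spatially tuned synapses whose Gaussian receptive fields tile a
#' circular track; the animal runs at constant velocity so track position is
#' measured in milliseconds of running time, `l(t) = t mod T`. Field centers
#' sit every `T / N` ms.
#'
#' @param T lap duration = track length (ms of running time).
#' @param N synapse count (>= 1).
#' @param r receptive-field width parameter (ms of track).
#' @param P_max peak per-step spike probability at the field center, in
#'   `[0, 1]`.
#' @return An object of class `"fplr_track_config"` with precomputed field
#'   `centers`.
#' @export
track_config <- function(T = 10000, N = 1000, r = 400, P_max = 0.02) {
  stopifnot(N >= 1, r > 0, P_max >= 0, P_max <= 1, T > 0)
  structure(list(T = T, N = as.integer(N), r = r, P_max = P_max,
                 centers = (seq_len(N) - 1L) * T / N),
            class = "fplr_track_config")
}

#' Leaky-integrator neuron parameters
#'
#' @param C_m membrane capacitance (nF).
#' @param tau_v voltage leak time constant (ms), > 0.
#' @param V_rest resting potential (mV).
#' @param V_plateau plateau (voltage-clamp) potential (mV), > `V_rest`.
#' @param syn_scale charge delivered per spike per unit weight (pC); each
#'   presynaptic spike at synapse `i` deflects the voltage by
#'   `syn_scale * w_i / C_m` mV.
#' @return An object of class `"fplr_neuron_params"`.
#' @export
neuron_params <- function(C_m = 1, tau_v = 15, V_rest = -75, V_plateau = -30,
                          syn_scale = 0.4) {
  stopifnot(tau_v > 0, V_plateau > V_rest, C_m > 0)
  structure(list(C_m = C_m, tau_v = tau_v, V_rest = V_rest,
                 V_plateau = V_plateau, syn_scale = syn_scale),
            class = "fplr_neuron_params")
}

#' Dual-source calcium parameters for BTSP
#'
#' Per-synapse calcium is the sum of a local presynaptic component (jump
#' `pre_height` per own-synapse spike) and a globally broadcast plateau
#' component (rectangular step of `plateau_height` during the induction).
#' Both decay exponentially with the same long time constant `tau_ca`, the
#' simplification of treating cytosolic plus endoplasmic-reticulum calcium as
#' a single seconds-scale trace.
#'
#' @param pre_height calcium jump per presynaptic spike (a.u.).
#' @param plateau_height plateau calcium level (a.u.).
#' @param plateau_duration induction duration (ms).
#' @param tau_ca calcium decay time constant (ms).
#' @return An object of class `"fplr_btsp_calcium_params"`.
#' @export
btsp_calcium_params <- function(pre_height = 0.1, plateau_height = 1.33,
                                plateau_duration = 300, tau_ca = 2000) {
  stopifnot(pre_height > 0, plateau_height > 0, plateau_duration > 0,
            tau_ca > 0)
  structure(list(pre_height = pre_height, plateau_height = plateau_height,
                 plateau_duration = plateau_duration, tau_ca = tau_ca),
            class = "fplr_btsp_calcium_params")
}

circular_distance <- function(a, b, T) {
  d <- abs(a - b) %% T
  pmin(d, T - d)
}

#' Per-step spike probability of a spatially tuned synapse
#'
#' Gaussian receptive field evaluated at the circular (wraparound) distance
#' between the field center and the current location:
#' `P_max * exp(-(d / r)^2)`.
#'
#' @param l_i field center (ms of track), in `[0, T)`.
#' @param l current location (ms of track), in `[0, T)`.
#' @param cfg a [track_config()].
#' @return spike probability per step, in `(0, P_max]`.
#' @export
receptive_field_rate <- function(l_i, l, cfg) {
  stopifnot(inherits(cfg, "fplr_track_config"))
  d <- circular_distance(l_i, l, cfg$T)
  cfg$P_max * exp(-(d / cfg$r)^2)
}

#' Sample Bernoulli spike trains from rate traces
#'
#' Independent Bernoulli draw per time step per synapse. Identical seeds give
#' identical rasters.
#'
#' @param rates numeric vector (one synapse) or matrix (synapses x steps) of
#'   per-step spike probabilities in `[0, 1]`.
#' @param dt sample step (ms).
#' @param seed optional RNG seed.
#' @return a [spike_train()] (vector input) or list of spike trains (matrix
#'   input).
#' @export
sample_spikes <- function(rates, dt = 1, seed = NULL) {
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function(r) {
    spike_train(((which(stats::runif(length(r)) < r)) - 1L) * dt)
  }
  if (is.matrix(rates)) {
    lapply(seq_len(nrow(rates)), function(i) draw(rates[i, ]))
  } else {
    draw(rates)
  }
}

#' One voltage step of the leaky-integrator neuron
#'
#' Without input the voltage relaxes to `V_rest` with time constant `tau_v`
#' (exact per-step decay factor). While the plateau is active the voltage is
#' clamped to `V_plateau` exactly. Each presynaptic spike at synapse `i`
#' deflects the voltage by `syn_scale * w_i / C_m`.
#'
#' @param V current voltage (mV).
#' @param syn_input summed weight of synapses spiking this step.
#' @param plateau_active logical.
#' @param params a [neuron_params()].
#' @param dt step (ms).
#' @return next voltage (mV).
#' @export
neuron_step <- function(V, syn_input, plateau_active, params, dt = 1) {
  stopifnot(inherits(params, "fplr_neuron_params"), dt > 0)
  if (plateau_active) return(params$V_plateau)
  params$V_rest + (V - params$V_rest) * exp(-dt / params$tau_v) +
    syn_input * params$syn_scale / params$C_m
}

#' One calcium step of a BTSP synapse
#'
#' Local presynaptic calcium decays with `tau_ca` and jumps by `pre_height`
#' at an own-synapse spike (jump lands undecayed); plateau calcium equals
#' `plateau_height` while the induction is active and decays with `tau_ca`
#' afterwards. The plateau component is broadcast identically to all synapses.
#'
#' @param ca_pre current local calcium (vector over synapses allowed).
#' @param ca_plateau current plateau calcium (scalar).
#' @param spikes 0/1 spike indicator per synapse this step.
#' @param plateau_active logical.
#' @param params a [btsp_calcium_params()].
#' @param dt step (ms).
#' @return list with updated `ca_pre`, `ca_plateau` and `total` calcium.
#' @export
synapse_calcium_step <- function(ca_pre, ca_plateau, spikes, plateau_active,
                                 params, dt = 1) {
  stopifnot(inherits(params, "fplr_btsp_calcium_params"), dt > 0)
  d <- exp(-dt / params$tau_ca)
  ca_pre <- ca_pre * d + params$pre_height * spikes
  ca_plateau <- if (plateau_active) params$plateau_height else ca_plateau * d
  list(ca_pre = ca_pre, ca_plateau = ca_plateau,
       total = ca_pre + ca_plateau)
}

#' Index of the synapse whose receptive field is centered nearest a location
#'
#' @param location track location (ms).
#' @param cfg a [track_config()].
#' @export
synapse_at <- function(location, cfg) {
  stopifnot(inherits(cfg, "fplr_track_config"))
  which.min(circular_distance(cfg$centers, location %% cfg$T, cfg$T))
}

#' Run a behavioral-timescale plasticity session
#'
#' Simulates an animal running `laps` laps of a circular track past a leaky
#' integrator neuron with spatially tuned stochastic inputs. Plateau
#' potentials are induced at the scheduled lap times, clamping the voltage to
#' `V_plateau` and broadcasting a rectangular calcium step to all synapses;
#' synaptic weights follow the preset's 1D FPLR rule (pre-depressive drift
#' off). All synapses start at the depressive fixed point unless `w0` is
#' given.
#'
#' @param laps number of laps; default 7.
#' @param inductions named numeric vector mapping lap number to induction
#'   time within the lap (ms), e.g. `c("2" = 3500, "4" = 2000, "6" = 7500)`
#'   (the default schedule). Use `NULL` for no inductions.
#' @param preset a preset from [load_preset()]; default `"btsp"`.
#' @param seed RNG seed for the Bernoulli inputs.
#' @param w0 initial weights: scalar or length-`N` vector; default the
#'   preset's depressive fixed point.
#' @param record synapse indices whose calcium and weight traces are stored
#'   at full resolution, or a single count (that many evenly spaced
#'   synapses); default 40.
#' @param spikes optional precomputed 0/1 spike matrix (`N` x steps),
#'   bypassing the internal Bernoulli draws (used for exact cross-checks).
#' @param dt time step (ms); default 1.
#' @return An object of class `"fplr_btsp_session"`: voltage trace, final
#'   weights, recorded weight/calcium matrices (`record` x steps), per-lap
#'   dwell-time matrices `dwell_depressive` / `dwell_potentiative` (`N` x
#'   laps, ms), spike counts, recorded spike times, the induction schedule
#'   and the seed.
#' @export
run_btsp_session <- function(laps = 7,
                             inductions = c("2" = 3500, "4" = 2000,
                                            "6" = 7500),
                             preset = NULL, seed = NULL, w0 = NULL,
                             record = 40, spikes = NULL, dt = 1) {
  if (is.null(preset)) preset <- load_preset("btsp")
  cfg <- preset$track
  np <- preset$neuron
  cp <- preset$calcium
  rule <- preset$rule
  steps_per_lap <- round(cfg$T / dt)
  if (abs(steps_per_lap * dt - cfg$T) > 1e-9) {
    stop("lap duration must be a multiple of dt", call. = FALSE)
  }
  if (is.null(inductions) || length(inductions) == 0L) {
    ind_lap <- integer(0); ind_time <- numeric(0)
  } else {
    ind_lap <- as.integer(names(inductions))
    ind_time <- as.numeric(inductions)
    if (any(is.na(ind_lap)) || any(ind_lap < 1L) || any(ind_lap > laps)) {
      stop("induction laps must name laps within the session", call. = FALSE)
    }
    if (any(ind_time < 0 | ind_time >= cfg$T)) {
      stop("induction times must lie within [0, T)", call. = FALSE)
    }
  }
  if (is.null(w0)) w0 <- eval_step(rule$F, rule$thresholds$theta_d)
  w0 <- rep_len(w0, cfg$N)
  # scalar `record` is a count of evenly spaced synapses; a vector gives
  # explicit synapse indices
  if (length(record) == 1L) {
    record_idx <- unique(round(seq(1, cfg$N, length.out = record)))
  } else {
    record_idx <- sort(unique(as.integer(record)))
  }
  if (any(record_idx < 1L | record_idx > cfg$N)) {
    stop("record indices out of range", call. = FALSE)
  }
  eta_vals <- rule$eta$values
  f_vals <- rule$F$values
  if (!is.null(seed)) set.seed(seed)
  sim <- btsp_simulate_cpp(
    laps = as.integer(laps), steps_per_lap = as.integer(steps_per_lap),
    dt = dt, ind_lap = ind_lap, ind_time = ind_time,
    N = cfg$N, r = cfg$r, P_max = cfg$P_max, track_T = cfg$T,
    V_rest = np$V_rest, V_plateau = np$V_plateau, tau_V = np$tau_v,
    C_m = np$C_m, syn_scale = np$syn_scale,
    pre_height = cp$pre_height, plateau_height = cp$plateau_height,
    plateau_duration = cp$plateau_duration, tau_Ca = cp$tau_ca,
    theta_d = rule$thresholds$theta_d, theta_p = rule$thresholds$theta_p,
    w0 = w0, F_d = f_vals[2L], F_p = f_vals[3L],
    eta_d = eta_vals[2L], eta_p = eta_vals[3L],
    eta_pre = eta_vals[1L], F_pre = f_vals[1L],
    record_idx = record_idx, spikes_in = spikes)
  structure(list(
    voltage = sim$voltage,
    weights_final = sim$weights_final,
    w_rec = sim$w_rec, ca_rec = sim$ca_rec, record_idx = record_idx,
    dwell_depressive = sim$dwell_depressive,
    dwell_potentiative = sim$dwell_potentiative,
    spike_count = sim$spike_count,
    rec_spikes = sim$rec_spikes,
    plateau = sim$plateau,
    laps = laps, dt = dt, steps_per_lap = steps_per_lap,
    inductions = inductions, seed = seed, w0 = w0,
    track = cfg, neuron = np, calcium_params = cp, rule = rule),
    class = "fplr_btsp_session")
}

#' @export
print.fplr_btsp_session <- function(x, ...) {
  cat("BTSP session:", x$laps, "laps x", x$steps_per_lap * x$dt, "ms,",
      x$track$N, "synapses\n")
  if (length(x$inductions)) {
    cat("  inductions: lap", paste(names(x$inductions), "@",
                                   x$inductions, "ms", collapse = ", "), "\n")
  }
  cat("  final weights: [", signif(min(x$weights_final), 4), ",",
      signif(max(x$weights_final), 4), "]\n")
  invisible(x)
}

#' Extract one lap of the session voltage
#' @param session a [run_btsp_session()] result.
#' @param lap lap number (1-based).
#' @export
lap_voltage <- function(session, lap) {
  stopifnot(inherits(session, "fplr_btsp_session"),
            lap >= 1, lap <= session$laps)
  i0 <- (lap - 1L) * session$steps_per_lap
  session$voltage[(i0 + 1L):(i0 + session$steps_per_lap)]
}

#' Detect voltage ramps (place fields) in a lap
#'
#' Smooths the voltage with a centered moving average and returns the
#' intervals where it exceeds `baseline + threshold_mv`. The baseline
#' defaults to the mean smoothed voltage of a reference lap (lap 1, which has
#' no induction), since ongoing background input keeps the mean voltage above
#' rest even without a place field.
#'
#' @param session a [run_btsp_session()] result.
#' @param lap lap to analyze.
#' @param reference_lap lap supplying the baseline (default 1).
#' @param threshold_mv detection threshold above baseline (mV).
#' @param smooth_ms moving-average window (ms).
#' @return data frame of ramp intervals (`start`, `end` in ms within the lap).
#' @export
detect_ramps <- function(session, lap, reference_lap = 1,
                         threshold_mv = 0.5, smooth_ms = 200) {
  v <- lap_voltage(session, lap)
  ref <- lap_voltage(session, reference_lap)
  k <- max(1L, round(smooth_ms / session$dt))
  kern <- rep(1 / k, k)
  sm <- function(x) {
    y <- stats::filter(x, kern, sides = 2)
    y[is.na(y)] <- x[is.na(y)]
    as.numeric(y)
  }
  vs <- sm(v)
  baseline <- mean(sm(ref))
  above <- vs > baseline + threshold_mv
  if (!any(above)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = (starts[keep] - 1L) * session$dt,
             end = ends[keep] * session$dt)
}

#' Expected weight change versus initial weight and field distance
#'
#' A single lap with one plateau induction in the middle of the track. For
#' each requested receptive-field distance from the induction location, the
#' synapse's calcium trace is recorded and the preset's 1D FPLR rule is
#' integrated from each initial weight (the calcium is input-driven and does
#' not depend on the weights), averaging the weight change over seeds.
#'
#' @param w0_grid numeric vector of initial weights.
#' @param dist_grid numeric vector of field-center distances from the
#'   induction location (ms of track; may be negative for fields earlier on
#'   the track).
#' @param preset a preset from [load_preset()]; default `"btsp"`.
#' @param seeds integer vector of RNG seeds to average over.
#' @param induction_time induction time within the lap (ms); default 5000.
#' @return data frame with columns `distance`, `w0`, `dw` (mean over seeds).
#' @export
weight_change_map <- function(w0_grid, dist_grid, preset = NULL,
                              seeds = 1:5, induction_time = 5000) {
  stopifnot(length(w0_grid) > 0, length(dist_grid) > 0)
  if (is.null(preset)) preset <- load_preset("btsp")
  cfg <- preset$track
  rule <- preset$rule
  idx <- vapply(dist_grid, function(d) {
    synapse_at(induction_time + d, cfg)
  }, integer(1))
  rec <- unique(idx)
  if (length(rec) == 1L) rec <- c(rec, if (rec > 1L) 1L else 2L)
  acc <- matrix(0, nrow = length(dist_grid), ncol = length(w0_grid))
  for (s in seeds) {
    ses <- run_btsp_session(
      laps = 1,
      inductions = stats::setNames(induction_time, "1"),
      preset = preset, seed = s, record = rec)
    for (j in seq_along(idx)) {
      row <- match(idx[j], ses$record_idx)
      tr <- calcium_trace(ses$ca_rec[row, ], dt = ses$dt)
      for (k in seq_along(w0_grid)) {
        traj <- integrate_rule(tr, w0_grid[k], rule)
        acc[j, k] <- acc[j, k] + delta_w(traj)
      }
    }
  }
  acc <- acc / length(seeds)
  data.frame(distance = rep(dist_grid, times = length(w0_grid)),
             w0 = rep(w0_grid, each = length(dist_grid)),
             dw = as.vector(acc))
}
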