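#' Result of a stimulation protocol
#'
#' Bundles the calcium trace, the weight trajectory obtained by integrating a
#' plasticity rule against it, the region bar code and a scalar summary.
#'
#' @param calcium a [calcium_trace()].
#' @param weights a [weight_trajectory()].
#' @param barcode a bar code from [compute_barcode()].
#' @param extra named list merged into the summary.
#' @return An object of class `"fplr_protocol_result"` with elements
#'   `calcium`, `weights`, `barcode` and `summary` (list with `w0`, `w_final`,
#'   `dw` and the dwell durations in ms).
#' @export
protocol_result <- function(calcium, weights, barcode, extra = list()) {
  n <- length(weights$values)
  summary <- c(list(
    w0 = weights$w0,
    w_final = if (n) weights$values[n] else weights$w0,
    dw = delta_w(weights),
    dwell_depressive = barcode$durations[["depressive"]],
    dwell_potentiative = barcode$durations[["potentiative"]]),
    extra)
  structure(list(calcium = calcium, weights = weights, barcode = barcode,
                 summary = summary),
            class = "fplr_protocol_result")
}

#' @export
print.fplr_protocol_result <- function(x, ...) {
  s <- x$summary
  cat("Protocol result: w0 =", s$w0, "-> w_final =", signif(s$w_final, 6),
      "(dw =", signif(s$dw, 6), ")\n")
  cat("  dwell: depressive", s$dwell_depressive, "ms, potentiative",
      s$dwell_potentiative, "ms\n")
  invisible(x)
}

# simulate past the last spike until calcium has decayed below
# theta_d * (1 - 1e-6), so the depressive tail of the decay is captured
trim_to_decay <- function(trace, last_spike, theta_d) {
  cut <- theta_d * (1 - 1e-6)
  i0 <- floor(last_spike / trace$dt) + 2L
  v <- trace$values
  if (i0 > length(v)) return(trace)
  below <- which(v[i0:length(v)] < cut)
  if (length(below) == 0L) return(trace)
  calcium_trace(v[seq_len(i0 + below[1L] - 1L)], dt = trace$dt, t0 = trace$t0)
}

#' Frequency-dependent plasticity protocol
#'
#' A train of presynaptic spikes at a fixed frequency drives spike calcium
#' (jump `c_pre` per spike, decay `tau_ca`); the synapse follows the preset's
#' 1D FPLR rule with pre-depressive drift off. The simulation extends past the
#' last spike until the calcium has decayed below `theta_D`, so the
#' depressive tail of the decay ("what goes up must come down") is part of
#' the result.
#'
#' @param freq stimulation frequency (Hz), > 0.
#' @param w0 initial weight; defaults to the preset's `w0`.
#' @param preset a preset from [load_preset()]; default `"frequency"`.
#' @param n_spikes number of presynaptic spikes in the train.
#' @return a [protocol_result()].
#' @examples
#' \donttest{
#' res <- run_frequency_protocol(100, preset = load_preset("frequency"))
#' res$summary$dw
#' }
#' @export
run_frequency_protocol <- function(freq, w0 = NULL, preset = NULL,
                                   n_spikes = 5) {
  if (!is.numeric(freq) || length(freq) != 1L || freq <= 0) {
    stop("`freq` must be a positive frequency in Hz", call. = FALSE)
  }
  if (is.null(preset)) preset <- load_preset("frequency")
  if (is.null(w0)) w0 <- preset$w0 %||% 1
  cp <- preset$calcium
  rule <- preset$rule
  dt <- preset$dt
  isi <- 1000 / freq
  spikes <- (seq_len(n_spikes) - 1L) * isi
  last <- spikes[n_spikes]
  peak_bound <- max(cp$c_pre * n_spikes, rule$thresholds$theta_d * 1.01)
  tail_ms <- cp$tau_ca * log(peak_bound / (rule$thresholds$theta_d * 1e-6))
  trace <- spike_calcium(spikes, numeric(0), cp,
                         t_total = last + tail_ms + dt, dt = dt)
  trace <- trim_to_decay(trace, last, rule$thresholds$theta_d)
  traj <- integrate_rule(trace, w0, rule)
  bc <- compute_barcode(trace, rule$thresholds)
  protocol_result(trace, traj, bc,
                  extra = list(freq = freq, n_spikes = n_spikes))
}

#' Sweep the frequency protocol over frequencies and initial weights
#'
#' One [run_frequency_protocol()] summary per (frequency, initial weight)
#' cell; the calcium trace is shared across initial weights at each
#' frequency. This is the grid behind the frequency-plasticity heatmap:
#' depression at low frequencies turning into potentiation at high
#' frequencies for weak synapses, and net depression of strong synapses even
#' under high-frequency stimulation.
#'
#' @param freq_grid numeric vector of frequencies (Hz).
#' @param w0_grid numeric vector of initial weights.
#' @inheritParams run_frequency_protocol
#' @return data frame with columns `freq`, `w0`, `w_final`, `dw`,
#'   `dwell_depressive`, `dwell_potentiative` (ms).
#' @export
frequency_sweep <- function(freq_grid, w0_grid, preset = NULL, n_spikes = 5) {
  stopifnot(length(freq_grid) > 0, length(w0_grid) > 0)
  if (is.null(preset)) preset <- load_preset("frequency")
  rule <- preset$rule
  rows <- lapply(freq_grid, function(f) {
    base <- run_frequency_protocol(f, w0 = preset$w0 %||% 1, preset = preset,
                                   n_spikes = n_spikes)
    dd <- base$summary$dwell_depressive
    dp <- base$summary$dwell_potentiative
    do.call(rbind, lapply(w0_grid, function(w0) {
      traj <- integrate_rule(base$calcium, w0, rule)
      data.frame(freq = f, w0 = w0,
                 w_final = traj$values[length(traj$values)],
                 dw = delta_w(traj),
                 dwell_depressive = dd, dwell_potentiative = dp)
    }))
  })
  do.call(rbind, rows)
}

#' Spike-timing-dependent plasticity pairing
#'
#' A single presynaptic spike paired with a single postsynaptic spike at
#' interval `delta_t` (positive = pre before post). The earliest spike sits at
#' 50 ms of the simulation; the trace runs at least 100 ms and extends until
#' the calcium has decayed below `theta_D`. With `n_pairings > 1` the pairing
#' repeats with full calcium decay between repeats.
#'
#' @param delta_t post minus pre spike time (ms); negative = post before pre.
#' @param w0 initial weight; defaults to the preset's `w0`.
#' @param preset a preset from [load_preset()]; default `"stdp"`.
#' @param n_pairings number of pairing repetitions.
#' @param lone optionally drop one spike: `"pre"` keeps only the presynaptic
#'   spike, `"post"` only the postsynaptic one; default `"none"` keeps both.
#' @return a [protocol_result()].
#' @export
run_stdp_pair <- function(delta_t, w0 = NULL, preset = NULL, n_pairings = 1,
                          lone = c("none", "pre", "post")) {
  lone <- match.arg(lone)
  if (is.null(preset)) preset <- load_preset("stdp")
  if (is.null(w0)) w0 <- preset$w0 %||% 1
  cp <- preset$calcium
  rule <- preset$rule
  dt <- preset$dt
  t_pre1 <- 50 + max(0, -delta_t)
  t_post1 <- t_pre1 + delta_t
  peak_bound <- max(cp$c_pre + cp$c_post, rule$thresholds$theta_d * 1.01)
  gap <- cp$tau_ca * log(peak_bound / 1e-12)
  period <- max(100, max(t_pre1, t_post1) + gap)
  reps <- (seq_len(n_pairings) - 1L) * period
  pre <- if (lone == "post") numeric(0) else t_pre1 + reps
  post <- if (lone == "pre") numeric(0) else t_post1 + reps
  last <- max(pre, post, 50)
  tail_ms <- cp$tau_ca * log(peak_bound / (rule$thresholds$theta_d * 1e-6))
  t_total <- max(100, last + tail_ms) + dt
  trace <- spike_calcium(pre, post, cp, t_total = t_total, dt = dt)
  trace <- trim_to_decay(trace, last, rule$thresholds$theta_d)
  traj <- integrate_rule(trace, w0, rule)
  bc <- compute_barcode(trace, rule$thresholds)
  protocol_result(trace, traj, bc,
                  extra = list(delta_t = delta_t, n_pairings = n_pairings))
}

#' Sweep the STDP pairing over intervals and initial weights
#'
#' @param delta_t_grid numeric vector of pairing intervals (ms).
#' @param w0_grid numeric vector of initial weights.
#' @inheritParams run_stdp_pair
#' @return data frame with columns `delta_t`, `w0`, `w_final`, `dw`,
#'   `dwell_depressive`, `dwell_potentiative`.
#' @export
stdp_sweep <- function(delta_t_grid, w0_grid, preset = NULL, n_pairings = 1) {
  stopifnot(length(delta_t_grid) > 0, length(w0_grid) > 0)
  if (is.null(preset)) preset <- load_preset("stdp")
  rule <- preset$rule
  rows <- lapply(delta_t_grid, function(dtv) {
    base <- run_stdp_pair(dtv, w0 = preset$w0 %||% 1, preset = preset,
                          n_pairings = n_pairings)
    dd <- base$summary$dwell_depressive
    dp <- base$summary$dwell_potentiative
    do.call(rbind, lapply(w0_grid, function(w0) {
      traj <- integrate_rule(base$calcium, w0, rule)
      data.frame(delta_t = dtv, w0 = w0,
                 w_final = traj$values[length(traj$values)],
                 dw = delta_w(traj),
                 dwell_depressive = dd, dwell_potentiative = dp)
    }))
  })
  do.call(rbind, rows)
}

#' Protein-gated late-phase LTP/LTD experiment
#'
#' Two phases. Early phase: calcium is held at a depressive (LTD) or
#' potentiative (LTP) level for the protocol duration with a per-second
#' learning rate of 1, driving the weight to the early fixed point. Late
#' phase: calcium drops to 0 for hours while the weight drifts under the
#' protein-gated rule — back toward baseline when the stabilizing protein is
#' absent, or toward the nearest late-phase stable state when it is present.
#'
#' @param direction `"LTP"` or `"LTD"`.
#' @param protein `"present"` or `"absent"`.
#' @param preset a preset from [load_preset()]; default `"late_phase_fig5"`.
#' @param w0 baseline weight (default 1; weights are relative to baseline).
#' @param early_s early-phase duration in seconds; defaults to the preset's
#'   protocol (LTD 9 s, LTP 3 s).
#' @param late_h late-phase duration in hours; defaults to the preset's
#'   protocol (LTD 4.5 h, LTP 10 h).
#' @param hold_ca calcium level held during the early phase; defaults to the
#'   preset's protocol levels (the asymptote only depends on the level's
#'   region, not its exact value).
#' @return a [protocol_result()]; the summary gains `percent_of_baseline`.
#' @export
run_late_phase_experiment <- function(direction, protein = c("present",
                                                             "absent"),
                                      preset = NULL, w0 = 1, early_s = NULL,
                                      late_h = NULL, hold_ca = NULL) {
  if (!is.character(direction) || length(direction) != 1L ||
      !direction %in% c("LTP", "LTD")) {
    stop("`direction` must be \"LTP\" or \"LTD\"", call. = FALSE)
  }
  protein <- match.arg(protein)
  if (is.null(preset)) preset <- load_preset("late_phase_fig5")
  pr <- preset$protocol
  if (is.null(early_s)) {
    early_s <- if (direction == "LTD") pr$ltd_early_s else pr$ltp_early_s
  }
  if (is.null(late_h)) {
    late_h <- if (direction == "LTD") pr$ltd_late_h else pr$ltp_late_h
  }
  if (is.null(hold_ca)) {
    hold_ca <- if (direction == "LTD") pr$ltd_hold_ca else pr$ltp_hold_ca
  }
  dt <- preset$dt                       # ms per step (1 s for this preset)
  n_early <- round(early_s * 1000 / dt)
  n_late <- round(late_h * 3600 * 1000 / dt)
  trace <- calcium_trace(c(rep(hold_ca, n_early), rep(0, n_late)), dt = dt)
  p <- if (protein == "present") 1L else 0L
  traj <- integrate_rule(trace, w0, preset$rule, protein = p)
  bc <- compute_barcode(trace, preset$rule$thresholds)
  res <- protocol_result(trace, traj, bc,
                         extra = list(direction = direction,
                                      protein = protein))
  res$summary$percent_of_baseline <- 100 * res$summary$w_final / w0
  res
}

#' Duration of the early-phase calcium signal of the canonical protocols
#'
#' The canonical induction protocols are a low-frequency stimulation (LFS: 900
#' pulses at 1 Hz) for LTD and a high-frequency stimulation (HFS: 100 pulses
#' at 100 Hz, repeated 3 times) for LTP. Taking each pulse to contribute about
#' 10 ms of calcium signal, the total calcium duration is pulse count times
#' pulse duration: 9 s for LFS and 3 s for HFS.
#'
#' @param protocol `"LFS"` or `"HFS"`.
#' @param pulse_ms calcium signal duration per pulse (ms).
#' @return duration in seconds.
#' @export
early_phase_calcium_duration <- function(protocol = c("LFS", "HFS"),
                                         pulse_ms = 10) {
  protocol <- match.arg(protocol)
  n <- switch(protocol, LFS = 900, HFS = 3 * 100)
  n * pulse_ms / 1000
}

#' Per-step weight change of any rule (dispatcher)
#'
#' @param rule any plasticity rule in the package.
#' @param ca calcium value(s).
#' @param w weight value(s).
#' @param protein protein state for a [protein_gated_rule()].
#' @export
plasticity_delta <- function(rule, ca, w, protein = 0) {
  switch(class(rule)[1L],
         fplr_rule1d = fplr1d_delta(ca, w, rule),
         fplr_rule2d = fplr2d_delta(ca, w, rule),
         fplr_protein_rule = protein_gated_delta(ca, w, protein, rule),
         fplr_sbc_rule = sbc_decay_delta(ca, w, rule),
         fplr_gb_rule = gb_delta(ca, w, rule),
         fplr_gb_simplified_rule = gb_simplified_delta(ca, w, rule),
         stop("unsupported rule class: ", class(rule)[1L], call. = FALSE))
}

#' Phase-plane grid of per-step weight changes
#'
#' Evaluates `Delta w` over a (calcium, weight) grid, the quantity shown in
#' the rule heatmaps.
#'
#' @param rule any plasticity rule in the package.
#' @param ca_grid,w_grid numeric grids.
#' @param protein protein state for a [protein_gated_rule()].
#' @return data frame with columns `ca`, `w`, `dw`.
#' @export
phase_plane <- function(rule, ca_grid, w_grid, protein = 0) {
  g <- expand.grid(ca = ca_grid, w = w_grid, KEEP.OUT.ATTRS = FALSE)
  g$dw <- vapply(seq_len(nrow(g)), function(i) {
    as.numeric(plasticity_delta(rule, g$ca[i], g$w[i], protein = protein))
  }, numeric(1))
  g
}
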