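#' Uniformly sampled calcium trace
#'
#' A calcium concentration time series sampled every `dt` ms; sample `i`
#' corresponds to time `t0 + (i - 1) * dt`.
#'
#' @param values numeric vector of calcium values (a.u.).
#' @param dt sample step (ms), > 0.
#' @param t0 time of the first sample (ms).
#' @return An object of class `"fplr_calcium_trace"`.
#' @export
calcium_trace <- function(values, dt, t0 = 0) {
  stopifnot(is.numeric(values), is.numeric(dt), length(dt) == 1L, dt > 0)
  structure(list(values = as.numeric(values), dt = dt, t0 = t0),
            class = "fplr_calcium_trace")
}

#' Sample times of a trace
#' @param x a calcium trace or weight trajectory.
#' @export
trace_times <- function(x) {
  x$t0 + (seq_along(x$values) - 1L) * x$dt
}

#' @export
print.fplr_calcium_trace <- function(x, ...) {
  cat("Calcium trace:", length(x$values), "samples, dt =", x$dt,
      "ms, range [", min(x$values), ",", max(x$values), "]\n")
  invisible(x)
}

#' @export
as.data.frame.fplr_calcium_trace <- function(x, ...) {
  data.frame(time = trace_times(x), calcium = x$values)
}

#' Presynaptic / postsynaptic spike train
#'
#' Spike times in ms, strictly increasing after snapping to the sampling grid.
#'
#' @param times numeric vector of spike times (ms), within `[0, T]` when used
#'   with a trace of duration `T`.
#' @return An object of class `"fplr_spike_train"`.
#' @export
spike_train <- function(times) {
  times <- sort(as.numeric(times))
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("spike times must be finite and >= 0", call. = FALSE)
  }
  structure(list(times = times), class = "fplr_spike_train")
}

spike_times <- function(x) {
  if (inherits(x, "fplr_spike_train")) x$times else sort(as.numeric(x))
}

#' Rectangular calcium step stimulus
#'
#' Calcium held at `level` on `[t_start, t_end)` and 0 elsewhere; the
#' canonical probe for reading fixed points off a plasticity rule.
#'
#' @param level calcium level during the step (a.u.).
#' @param t_start,t_end step onset and offset (ms), `0 <= t_start < t_end <=
#'   t_total`.
#' @param t_total total trace duration (ms).
#' @param dt sample step (ms).
#' @return a [calcium_trace()].
#' @export
step_stimulus <- function(level, t_start, t_end, t_total, dt) {
  if (!(t_start >= 0 && t_start < t_end && t_end <= t_total)) {
    stop("need 0 <= t_start < t_end <= t_total", call. = FALSE)
  }
  tt <- seq(0, t_total - dt / 2, by = dt)
  calcium_trace(ifelse(tt >= t_start & tt < t_end, level, 0), dt = dt)
}

#' Calcium jump parameters for spike-driven calcium
#'
#' @param c_pre calcium jump per presynaptic spike (a.u., >= 0).
#' @param c_post calcium jump per postsynaptic spike (a.u., >= 0).
#' @param tau_ca calcium decay time constant (ms, > 0).
#' @return An object of class `"fplr_calcium_params"`.
#' @export
calcium_params <- function(c_pre, c_post = 0, tau_ca) {
  if (tau_ca <= 0) stop("tau_ca must be > 0", call. = FALSE)
  if (c_pre < 0 || c_post < 0) stop("jumps must be >= 0", call. = FALSE)
  structure(list(c_pre = c_pre, c_post = c_post, tau_ca = tau_ca),
            class = "fplr_calcium_params")
}

#' Spike-driven exponentially decaying calcium
#'
#' Calcium jumps by `c_pre` at each presynaptic spike and by `c_post` at each
#' postsynaptic spike and decays exponentially with time constant `tau_ca`
#' between spikes (exact per-step decay factor `exp(-dt / tau_ca)`). A spike's
#' jump lands undecayed at the sample containing it; pre and post spikes at
#' the same sample sum both jumps. Superposition holds exactly: the trace of
#' merged trains equals the sum of the separate traces.
#'
#' @param pre,post spike trains ([spike_train()] or numeric vectors of times
#'   in ms) within `[0, t_total]`.
#' @param params a [calcium_params()] object.
#' @param t_total trace duration (ms).
#' @param dt sample step (ms).
#' @return a [calcium_trace()].
#' @export
spike_calcium <- function(pre, post = numeric(0), params, t_total, dt) {
  stopifnot(inherits(params, "fplr_calcium_params"))
  n <- length(seq(0, t_total - dt / 2, by = dt))
  jumps <- numeric(n)
  add_jumps <- function(jumps, times, height) {
    if (length(times) == 0 || height == 0) return(jumps)
    idx <- round(times / dt) + 1L
    if (any(idx < 1L | idx > n)) {
      stop("spike times must lie within [0, t_total]", call. = FALSE)
    }
    for (i in idx) jumps[i] <- jumps[i] + height
    jumps
  }
  jumps <- add_jumps(jumps, spike_times(pre), params$c_pre)
  jumps <- add_jumps(jumps, spike_times(post), params$c_post)
  d <- exp(-dt / params$tau_ca)
  vals <- as.numeric(stats::filter(jumps, d, method = "recursive"))
  calcium_trace(vals, dt = dt)
}

#' Region bar code of a calcium trace
#'
#' Assigns every sample of the trace to a calcium region and records the
#' intervals during which the calcium lies in the depressive region
#' (`theta_D <= Ca < theta_P`) or the potentiative region (`Ca >= theta_P`),
#' together with the total dwell durations.
#'
#' @param trace a [calcium_trace()].
#' @param thresholds an [thresholds()] object.
#' @return An object of class `"fplr_barcode"`: a list with data frames
#'   `depressive` and `potentiative` (columns `start`, `end` in ms) and a
#'   named numeric `durations` (ms) with entries `depressive` and
#'   `potentiative`.
#' @export
compute_barcode <- function(trace, thresholds) {
  stopifnot(inherits(trace, "fplr_calcium_trace"))
  th <- as_thresholds(thresholds)
  idx <- region_index(trace$values, th)
  intervals_for <- function(in_region) {
    if (!any(in_region)) {
      return(data.frame(start = numeric(0), end = numeric(0)))
    }
    r <- rle(in_region)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = trace$t0 + (starts[keep] - 1L) * trace$dt,
               end = trace$t0 + ends[keep] * trace$dt)
  }
  dep <- intervals_for(idx == 1L)
  pot <- intervals_for(idx == 2L)
  structure(list(
    depressive = dep,
    potentiative = pot,
    durations = c(depressive = sum(idx == 1L) * trace$dt,
                  potentiative = sum(idx == 2L) * trace$dt)),
    class = "fplr_barcode")
}

#' @export
print.fplr_barcode <- function(x, ...) {
  cat("Plasticity bar code\n")
  cat("  depressive:  ", nrow(x$depressive), "interval(s),",
      x$durations[["depressive"]], "ms total\n")
  cat("  potentiative:", nrow(x$potentiative), "interval(s),",
      x$durations[["potentiative"]], "ms total\n")
  invisible(x)
}
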