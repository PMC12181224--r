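#' Synaptic weight trajectory
#'
#' Weight time series produced by integrating a plasticity rule against a
#' calcium trace. `values[i]` is the weight after applying the update for
#' calcium sample `i`; the initial weight is kept in `w0`.
#'
#' @param values numeric vector of weights.
#' @param dt sample step (ms).
#' @param w0 initial weight (before the first update).
#' @param t0 time of the first sample (ms).
#' @return An object of class `"fplr_weight_trajectory"`.
#' @export
weight_trajectory <- function(values, dt, w0, t0 = 0) {
  structure(list(values = as.numeric(values), dt = dt, w0 = w0, t0 = t0),
            class = "fplr_weight_trajectory")
}

#' @export
print.fplr_weight_trajectory <- function(x, ...) {
  n <- length(x$values)
  cat("Weight trajectory:", n, "samples, dt =", x$dt, "ms, w0 =", x$w0,
      "-> final", if (n) x$values[n] else x$w0, "\n")
  invisible(x)
}

#' @export
as.data.frame.fplr_weight_trajectory <- function(x, ...) {
  data.frame(time = trace_times(x), weight = x$values)
}

#' Final minus initial weight of a trajectory
#' @param traj a [weight_trajectory()].
#' @export
delta_w <- function(traj) {
  n <- length(traj$values)
  if (n == 0L) return(0)
  traj$values[n] - traj$w0
}

#' Integrate a plasticity rule over a calcium trace
#'
#' Discrete first-order integration `w(t) = w(t - 1) + Delta w` of any rule in
#' the package against a uniformly sampled calcium trace. For the relaxation
#' rules (1D/2D FPLR, SBC with decay) the update is evaluated in compiled
#' code; under constant calcium with per-step rate `eta` the trajectory
#' satisfies the geometric contraction `w_n - F = (1 - eta)^n (w_0 - F)`.
#'
#' @param ca a [calcium_trace()] (or bare numeric vector of calcium values, in
#'   which case the rule's `dt` is assumed).
#' @param w0 initial weight (finite).
#' @param rule one of [fplr_rule1d()], [fplr_rule2d()],
#'   [protein_gated_rule()], [sbc_rule()], [gb_rule()],
#'   [gb_simplified_rule()].
#' @param protein optional 0/1 vector (same length as the trace, or scalar)
#'   for a [protein_gated_rule()]; default 0.
#' @param boundary_tol basin boundary equality tolerance for 2D rules.
#' @param delay_steps optional non-negative integer: the plastic effect
#'   responds to the calcium `delay_steps` samples earlier (calcium before
#'   the trace start is taken as 0). Default 0, no delay.
#' @return a [weight_trajectory()] of the same length as the trace.
#' @export
integrate_rule <- function(ca, w0, rule, protein = NULL,
                           boundary_tol = 1e-12, delay_steps = 0L) {
  if (!inherits(ca, "fplr_calcium_trace")) {
    ca <- calcium_trace(as.numeric(ca), dt = rule$dt %||% 1)
  }
  if (!is.finite(w0)) stop("`w0` must be finite", call. = FALSE)
  v <- ca$values
  if (delay_steps < 0 || delay_steps != round(delay_steps)) {
    stop("`delay_steps` must be a non-negative integer", call. = FALSE)
  }
  if (delay_steps > 0) {
    d <- min(delay_steps, length(v))
    v <- c(rep(0, d), v[seq_len(length(v) - d)])
  }
  w <- switch(
    class(rule)[1L],
    fplr_rule1d = relax_integrate_cpp(eval_step(rule$F, v),
                                      eval_step(rule$eta, v), w0),
    fplr_sbc_rule = {
      eta <- eval_step(rule$eta, v)
      if (length(eta) == 1L) eta <- rep(eta, length(v))
      omega <- eval_step(rule$omega, v)
      if (rule$lambda == 0) {
        w0 + cumsum(eta * omega)
      } else {
        relax_integrate_cpp(omega / rule$lambda, eta * rule$lambda, w0)
      }
    },
    fplr_gb_rule = gb_integrate_cpp(region_index(v, rule$thresholds), w0,
                                    rule$w_star, rule$eta_d, rule$eta_p,
                                    rule$tau),
    fplr_gb_simplified_rule = gb_simplified_integrate_cpp(
      region_index(v, rule$thresholds), w0, rule$w_star, rule$eta_drift,
      rule$eta_d, rule$eta_p),
    fplr_rule2d = fplr2d_integrate_cpp(region_index(v, rule$thresholds), w0,
                                       regions_for_cpp(rule), boundary_tol),
    fplr_protein_rule = {
      if (is.null(protein)) protein <- 0L
      if (length(protein) == 1L) protein <- rep(protein, length(v))
      if (length(protein) != length(v)) {
        stop("`protein` must match the calcium trace length", call. = FALSE)
      }
      if (!all(protein %in% c(0, 1))) {
        stop("`protein` must be 0 or 1", call. = FALSE)
      }
      protein_integrate_cpp(region_index(v, rule$thresholds),
                            as.integer(protein),
                            eval_step(rule$no_protein_rule$F, v),
                            eval_step(rule$no_protein_rule$eta, v),
                            regions_for_cpp(rule$protein_rule),
                            w0, boundary_tol)
    },
    stop("unsupported rule class: ", class(rule)[1L], call. = FALSE)
  )
  weight_trajectory(w, dt = ca$dt, w0 = w0, t0 = ca$t0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
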