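#' Shouval-Bear-Cooper (SBC) calcium-based plasticity rule
#'
#' The classic two-threshold rule family. The per-step weight change is
#' \deqn{\Delta w = \eta(Ca) (\Omega(Ca) - \lambda w)}
#' where `Omega` is the two-threshold step function taking the value 0 below
#' `theta_D`, the signed depression rate `k_D < 0` in the depressive region and
#' the signed potentiation rate `k_P > 0` in the potentiative region.
#'
#' Three variants are covered by one constructor:
#' * `lambda = 0`: the linear rule, weights change linearly and are
#'   weight-independent.
#' * `lambda > 0` with scalar `eta`: the weight-decay rule, with per-region
#'   fixed points `0`, `k_D / lambda`, `k_P / lambda`.
#' * `lambda > 0` with a sigmoidal [step_fun()] `eta`: calcium-dependent
#'   learning rate, slowing the decay to baseline at low calcium.
#'
#' @param thresholds an [thresholds()] object.
#' @param k_d signed depression rate (< 0).
#' @param k_p signed potentiation rate (> 0).
#' @param lambda weight decay rate (>= 0). Zero reduces to the linear rule.
#' @param eta learning rate: a scalar or an [step_fun()] of calcium with
#'   non-decreasing values (sigmoidal calcium-dependent rate).
#' @param sharpness optional sigmoid sharpness for a soft `Omega`; `NULL`
#'   means hard thresholds.
#' @param dt integration step duration (time units of the enclosing protocol).
#' @return An object of class `"fplr_sbc_rule"`.
#' @export
sbc_rule <- function(thresholds, k_d, k_p, lambda = 0, eta = 1,
                     sharpness = NULL, dt = 1) {
  th <- as_thresholds(thresholds)
  if (!(k_d < 0 && k_p > 0)) stop("need k_d < 0 < k_p", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  omega <- step_fun(c(th$theta_d, th$theta_p), c(0, k_d, k_p),
                    sharpness = sharpness)
  if (is.numeric(eta) && length(eta) == 1L) {
    eta <- const_step(eta)
  } else if (!inherits(eta, "fplr_step_fun")) {
    stop("`eta` must be a scalar or a step_fun", call. = FALSE)
  }
  if (any(eta$values < 0)) stop("learning rates must be >= 0", call. = FALSE)
  structure(list(thresholds = th, omega = omega, eta = eta,
                 k_d = k_d, k_p = k_p, lambda = lambda, dt = dt),
            class = "fplr_sbc_rule")
}

#' Per-step weight change under the linear SBC rule
#'
#' `Delta w = eta * Omega(ca)`; independent of the current weight.
#'
#' @param ca calcium value(s), >= 0.
#' @param rule an [sbc_rule()].
#' @return numeric vector of weight increments.
#' @export
sbc_linear_delta <- function(ca, rule) {
  stopifnot(inherits(rule, "fplr_sbc_rule"))
  eval_step(rule$eta, ca) * eval_step(rule$omega, ca)
}

#' Per-step weight change under the SBC rule with weight decay
#'
#' `Delta w = eta * (Omega(ca) - lambda * w)`. With `lambda > 0` the
#' per-region fixed points are `0`, `k_D / lambda` and `k_P / lambda`;
#' `lambda = 0` silently reduces to the linear rule.
#'
#' @inheritParams sbc_linear_delta
#' @param w current weight(s).
#' @export
sbc_decay_delta <- function(ca, w, rule) {
  stopifnot(inherits(rule, "fplr_sbc_rule"))
  eval_step(rule$eta, ca) * (eval_step(rule$omega, ca) - rule$lambda * w)
}

#' Per-step weight change under the SBC rule with calcium-dependent rate
#'
#' Identical functional form to [sbc_decay_delta()]; provided for rules whose
#' `eta` is a sigmoidal [step_fun()] of calcium. Same fixed points; the
#' approach rate scales with `eta(ca)`.
#'
#' @inheritParams sbc_decay_delta
#' @export
sbc_cadep_delta <- function(ca, w, rule) {
  sbc_decay_delta(ca, w, rule)
}

#' Graupner-Brunel (GB) bistable plasticity rule
#'
#' The cubic-drift bistable rule (noise term omitted):
#' \deqn{\tau \Delta w = -w(1-w)(w_* - w) - \eta_D w \, \Theta(Ca - \theta_D)
#'       + \eta_P (1-w) \, \Theta(Ca - \theta_P)}
#' The drift term is always active; the depression term is active in the
#' depressive and potentiative regions; the potentiation term only in the
#' potentiative region. The weight variable is the synaptic efficacy in
#' `[0, 1]`, mapped to physical weights by
#' `w_phys = w_down + w * (w_up - w_down)`.
#'
#' @param thresholds an [thresholds()] object.
#' @param w_star unstable drift fixed point, strictly inside (0, 1).
#' @param eta_d,eta_p depression / potentiation rates (>= 0).
#' @param tau global time constant of the rule (> 0), in steps.
#' @param eta_drift drift rate of the simplified variant (>= 0).
#' @param w_up,w_down efficacy-to-weight mapping endpoints.
#' @param dt integration step duration.
#' @return An object of class `"fplr_gb_rule"`.
#' @export
gb_rule <- function(thresholds, w_star = 0.5, eta_d = 1, eta_p = 1, tau = 1,
                    eta_drift = 0, w_up = 1, w_down = 0, dt = 1) {
  th <- as_thresholds(thresholds)
  if (!(w_star > 0 && w_star < 1)) stop("need 0 < w_star < 1", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (eta_d < 0 || eta_p < 0 || eta_drift < 0) {
    stop("rates must be >= 0", call. = FALSE)
  }
  structure(list(thresholds = th, w_star = w_star, eta_d = eta_d,
                 eta_p = eta_p, tau = tau, eta_drift = eta_drift,
                 w_up = w_up, w_down = w_down, dt = dt),
            class = "fplr_gb_rule")
}

#' Simplified Graupner-Brunel rule
#'
#' Exactly one process is active for any (calcium, weight) pair: exponential
#' drift toward 0 or 1 in the pre-depressive region (direction set by the
#' unstable fixed point `w_star`), asymptotic depression toward 0, or
#' asymptotic potentiation toward 1.
#'
#' @inheritParams gb_rule
#' @return An object of class `"fplr_gb_simplified_rule"`.
#' @export
gb_simplified_rule <- function(thresholds, w_star = 0.5, eta_drift = 0,
                               eta_d = 1, eta_p = 1, w_up = 1, w_down = 0,
                               dt = 1) {
  r <- gb_rule(thresholds, w_star = w_star, eta_d = eta_d, eta_p = eta_p,
               tau = 1, eta_drift = eta_drift, w_up = w_up, w_down = w_down,
               dt = dt)
  class(r) <- "fplr_gb_simplified_rule"
  r
}

#' Per-step efficacy change under the original GB rule
#'
#' Implements the cumulative three-branch sum (drift always on; depression on
#' above `theta_D`; potentiation on above `theta_P`), divided by `tau`.
#'
#' @param ca calcium value(s).
#' @param w current efficacy value(s) (in `[0, 1]` units).
#' @param rule a [gb_rule()].
#' @export
gb_delta <- function(ca, w, rule) {
  stopifnot(inherits(rule, "fplr_gb_rule"))
  reg <- region_index(ca, rule$thresholds)
  d <- -w * (1 - w) * (rule$w_star - w)
  d <- d - rule$eta_d * w * (reg >= 1L)
  d <- d + rule$eta_p * (1 - w) * (reg >= 2L)
  d / rule$tau
}

#' Per-step efficacy change under the simplified GB rule
#'
#' @inheritParams gb_delta
#' @param rule a [gb_simplified_rule()].
#' @export
gb_simplified_delta <- function(ca, w, rule) {
  stopifnot(inherits(rule, "fplr_gb_simplified_rule"))
  reg <- region_index(ca, rule$thresholds)
  n <- max(length(ca), length(w))
  reg <- rep_len(reg, n)
  w <- rep_len(w, n)
  d <- numeric(n)
  pot <- reg >= 2L
  dep <- reg == 1L
  pre <- reg == 0L
  d[pot] <- rule$eta_p * (1 - w[pot])
  d[dep] <- -rule$eta_d * w[dep]
  lo <- pre & w < rule$w_star
  hi <- pre & w > rule$w_star
  d[lo] <- -rule$eta_drift * w[lo]
  d[hi] <- rule$eta_drift * (1 - w[hi])
  d
}

#' Map GB efficacy to physical synaptic weight
#'
#' `w = w_down + rho * (w_up - w_down)`.
#'
#' @param rho efficacy value(s) in `[0, 1]`.
#' @param rule a [gb_rule()] or [gb_simplified_rule()].
#' @export
efficacy_to_weight <- function(rho, rule) {
  rule$w_down + rho * (rule$w_up - rule$w_down)
}
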