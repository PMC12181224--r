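#' One-dimensional fixed point-learning rate (FPLR) rule
#'
#' The per-step weight change is
#' \deqn{\Delta w = \eta(Ca) (F(Ca) - w)}
#' where `F(Ca)` is a step function giving the *fixed point* (where the
#' weight is headed) and `eta(Ca)` a step function giving the *learning rate*
#' (the fraction of the remaining distance traversed per step) in each calcium
#' region. All learning rates must lie in `[0, 1]` to prevent oscillations;
#' `eta = 1` makes the weight jump to the fixed point in a single step.
#'
#' @param thresholds an [thresholds()] object.
#' @param F fixed points: an [step_fun()] of calcium, or a numeric vector of
#'   per-region values (one more than the number of thresholds).
#' @param eta learning rates: an [step_fun()] or numeric vector like `F`;
#'   values in `[0, 1]`, interpreted as fraction per step at step size `dt`.
#' @param dt step duration the learning rates refer to (declared time units,
#'   ms unless stated otherwise by a preset).
#' @param sharpness optional sigmoid sharpness applied when `F`/`eta` are
#'   given as value vectors; `NULL` means hard thresholds.
#' @return An object of class `"fplr_rule1d"`.
#' @examples
#' r <- fplr_rule1d(thresholds(1, 1.3), F = c(0.5, 0, 1),
#'                  eta = c(0.015, 0.15, 0.25))
#' fplr1d_delta(ca = 2, w = 0, r)
#' @export
fplr_rule1d <- function(thresholds, F, eta, dt = 1, sharpness = NULL) {
  th <- as_thresholds(thresholds)
  if (!inherits(F, "fplr_step_fun")) F <- step_fun(th$all, F, sharpness)
  if (!inherits(eta, "fplr_step_fun")) eta <- step_fun(th$all, eta, sharpness)
  if (any(eta$values < 0 | eta$values > 1)) {
    stop("all learning rates must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a positive scalar", call. = FALSE)
  }
  structure(list(thresholds = th, F = F, eta = eta, dt = dt),
            class = "fplr_rule1d")
}

#' @export
print.fplr_rule1d <- function(x, ...) {
  cat("1D FPLR rule (dt =", x$dt, ")\n")
  cat("  thresholds:", paste(x$thresholds$all, collapse = ", "), "\n")
  cat("  F:  ", paste(x$F$values, collapse = ", "), "\n")
  cat("  eta:", paste(x$eta$values, collapse = ", "), "\n")
  invisible(x)
}

#' Per-step weight change under the 1D FPLR rule
#'
#' After one step the distance to the active fixed point shrinks by exactly
#' the factor `1 - eta(ca)`.
#'
#' @param ca calcium value(s), >= 0.
#' @param w current weight(s).
#' @param rule an [fplr_rule1d()].
#' @export
fplr1d_delta <- function(ca, w, rule) {
  stopifnot(inherits(rule, "fplr_rule1d"))
  eval_step(rule$eta, ca) * (eval_step(rule$F, ca) - w)
}

#' Continuous-time learning rate equivalent to a per-step fraction
#'
#' Converts a per-step learning rate (fraction of the remaining distance per
#' step of size `dt`) to the continuous exponential rate that produces the
#' same geometric relaxation at the sample times:
#' `eta_cont = -log(1 - eta_step) / dt`.
#'
#' @param eta_step per-step rate(s) in `[0, 1]`.
#' @param dt step duration.
#' @export
eta_continuous <- function(eta_step, dt) {
  -log(1 - eta_step) / dt
}

#' Closed-form weight after a constant calcium pulse
#'
#' For constant calcium `C` held from `t_start` to `t_end` the 1D FPLR weight
#' relaxes exponentially toward the fixed point:
#' \deqn{w(t_E) = F(C) + (w(t_S) - F(C)) e^{-\eta (t_E - t_S)}}
#' with `eta` the continuous rate implied by the rule's per-step rate (see
#' [eta_continuous()]). A per-step rate of exactly 1 jumps to the fixed point
#' for any positive elapsed time.
#'
#' @param w0 weight at `t_start`.
#' @param ca constant calcium level during the pulse.
#' @param t_start,t_end pulse start and end times (same units as `rule$dt`);
#'   `t_end >= t_start`.
#' @param rule an [fplr_rule1d()].
#' @return the weight at `t_end`.
#' @export
closed_form_weight <- function(w0, ca, t_start, t_end, rule) {
  stopifnot(inherits(rule, "fplr_rule1d"))
  if (t_end < t_start) stop("t_end must be >= t_start", call. = FALSE)
  fp <- eval_step(rule$F, ca)
  eta_step <- eval_step(rule$eta, ca)
  if (t_end == t_start) return(w0)
  if (eta_step >= 1) return(fp)
  fp + (w0 - fp) * exp(-eta_continuous(eta_step, rule$dt) * (t_end - t_start))
}

#' Basins of attraction for weight-dependent drift
#'
#' Describes `N` stable fixed points and the `N + 1` boundaries of their
#' basins of attraction within one calcium region of a 2D FPLR rule. Each
#' fixed point must lie strictly inside its basin and each learning rate in
#' `[0, 1]`. A weight sitting exactly on a boundary (within `tol`) is treated
#' as an unstable fixed point by default; half-stable boundaries can be
#' requested per boundary via `boundary_mode`.
#'
#' @param fixed_points numeric vector of `N` stable weight values.
#' @param boundaries strictly increasing numeric vector of `N + 1` basin
#'   boundaries.
#' @param learning_rates numeric vector of `N` per-step rates in `[0, 1]`.
#' @param boundary_mode character vector (length `N + 1`, recycled if scalar):
#'   `"unstable"` (boundary is an unstable fixed point), `"left"` or
#'   `"right"` (half-stable: the boundary belongs to the adjacent basin).
#' @return An object of class `"fplr_basin_spec"`.
#' @examples
#' basin_spec(c(0.2, 0.5, 0.8), c(0, 0.3, 0.7, 1), c(0.01, 0.02, 0.01))
#' @export
basin_spec <- function(fixed_points, boundaries, learning_rates,
                       boundary_mode = "unstable") {
  v <- validate_basins(fixed_points, boundaries, learning_rates)
  if (length(v) > 0) {
    stop("invalid basin specification:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  }
  if (length(boundary_mode) == 1L) {
    boundary_mode <- rep(boundary_mode, length(boundaries))
  }
  if (length(boundary_mode) != length(boundaries) ||
      !all(boundary_mode %in% c("unstable", "left", "right"))) {
    stop("`boundary_mode` must be 'unstable', 'left' or 'right' per boundary",
         call. = FALSE)
  }
  structure(list(fixed_points = as.numeric(fixed_points),
                 boundaries = as.numeric(boundaries),
                 learning_rates = as.numeric(learning_rates),
                 boundary_mode = boundary_mode),
            class = "fplr_basin_spec")
}

#' Check a basin specification for violations
#'
#' Returns all violated invariants (non-monotone boundaries, fixed point
#' outside its basin, learning rate outside `[0, 1]`, length mismatches)
#' rather than raising an error. A valid specification returns a zero-length
#' character vector.
#'
#' @param fixed_points an [basin_spec()] object, or a numeric vector of fixed
#'   points (then `boundaries` and `learning_rates` must be supplied).
#' @param boundaries,learning_rates numeric vectors, see [basin_spec()].
#' @return character vector of violation messages; `character(0)` when valid.
#' @export
validate_basins <- function(fixed_points, boundaries = NULL,
                            learning_rates = NULL) {
  if (inherits(fixed_points, "fplr_basin_spec")) {
    spec <- fixed_points
    fixed_points <- spec$fixed_points
    boundaries <- spec$boundaries
    learning_rates <- spec$learning_rates
  }
  out <- character(0)
  n <- length(fixed_points)
  if (length(boundaries) != n + 1L) {
    out <- c(out, sprintf(
      "expected %d boundaries for %d fixed points, got %d",
      n + 1L, n, length(boundaries)))
  }
  if (length(learning_rates) != n) {
    out <- c(out, sprintf("expected %d learning rates, got %d",
                          n, length(learning_rates)))
  }
  if (any(diff(boundaries) <= 0)) {
    out <- c(out, "boundaries are not strictly increasing")
  }
  k <- min(n, length(boundaries) - 1L)
  if (k >= 1L && !any(diff(boundaries) <= 0)) {
    for (i in seq_len(k)) {
      if (!(fixed_points[i] > boundaries[i] &&
            fixed_points[i] < boundaries[i + 1L])) {
        out <- c(out, sprintf(
          "fixed point %g lies outside its basin (%g, %g)",
          fixed_points[i], boundaries[i], boundaries[i + 1L]))
      }
    }
  }
  bad <- learning_rates < 0 | learning_rates > 1
  if (any(bad)) {
    out <- c(out, sprintf("learning rate %g outside [0, 1]",
                          learning_rates[bad]))
  }
  out
}

#' Two-dimensional FPLR rule
#'
#' Fixed points and learning rates depend on both the calcium region and the
#' current weight:
#' \deqn{\Delta w = \eta(Ca, w) (F(Ca, w) - w)}
#' Each calcium region holds either a scalar `(F, eta)` pair (weight
#' independent, as in the depressive and potentiative regions of the standard
#' rule) or an [basin_spec()] describing multiple weight-dependent stable
#' states, typically for pre-depressive drift.
#'
#' @param thresholds an [thresholds()] object.
#' @param regions list with one entry per calcium region (length
#'   `length(thresholds$all) + 1`, ordered from the lowest region upward).
#'   Each entry is either a numeric vector `c(F, eta)` (optionally named) or
#'   an [basin_spec()].
#' @param dt step duration the learning rates refer to.
#' @return An object of class `"fplr_rule2d"`.
#' @examples
#' tri <- basin_spec(c(0.2, 0.5, 0.8), c(0, 0.3, 0.7, 1),
#'                   c(0.01, 0.02, 0.01))
#' r <- fplr_rule2d(thresholds(1, 1.3),
#'                  regions = list(tri, c(F = 0, eta = 0.1),
#'                                 c(F = 1, eta = 0.2)))
#' lookup_2d(ca = 0.5, w = 0.25, r)
#' @export
fplr_rule2d <- function(thresholds, regions, dt = 1) {
  th <- as_thresholds(thresholds)
  n_reg <- length(th$all) + 1L
  if (!is.list(regions) || length(regions) != n_reg) {
    stop(sprintf("`regions` must be a list of %d entries (one per region)",
                 n_reg), call. = FALSE)
  }
  regions <- lapply(regions, function(rg) {
    if (inherits(rg, "fplr_basin_spec")) return(rg)
    if (is.numeric(rg) && length(rg) == 2L) {
      rg <- unname(rg)
      if (rg[2L] < 0 || rg[2L] > 1) {
        stop("scalar region learning rate must lie in [0, 1]", call. = FALSE)
      }
      return(list(F = rg[1L], eta = rg[2L]))
    }
    if (is.list(rg) && all(c("F", "eta") %in% names(rg))) {
      return(list(F = rg$F, eta = rg$eta))
    }
    stop("each region must be c(F, eta) or a basin_spec", call. = FALSE)
  })
  structure(list(thresholds = th, regions = regions, dt = dt),
            class = "fplr_rule2d")
}

#' @export
print.fplr_rule2d <- function(x, ...) {
  cat("2D FPLR rule (dt =", x$dt, ")\n")
  cat("  thresholds:", paste(x$thresholds$all, collapse = ", "), "\n")
  for (i in seq_along(x$regions)) {
    rg <- x$regions[[i]]
    if (inherits(rg, "fplr_basin_spec")) {
      cat(sprintf("  region %d: basins at [%s], boundaries [%s]\n", i - 1L,
                  paste(rg$fixed_points, collapse = ", "),
                  paste(rg$boundaries, collapse = ", ")))
    } else {
      cat(sprintf("  region %d: F = %g, eta = %g\n", i - 1L, rg$F, rg$eta))
    }
  }
  invisible(x)
}

#' @export
print.fplr_protein_rule <- function(x, ...) {
  cat("Protein-gated rule\n-- protein absent:\n")
  print(x$no_protein_rule)
  cat("-- protein present:\n")
  print(x$protein_rule)
  invisible(x)
}

# serialize regions for the C++ integrator
regions_for_cpp <- function(rule) {
  lapply(rule$regions, function(rg) {
    if (inherits(rg, "fplr_basin_spec")) {
      list(basin = TRUE,
           boundaries = rg$boundaries,
           fixed_points = rg$fixed_points,
           learning_rates = rg$learning_rates,
           boundary_mode = match(rg$boundary_mode,
                                 c("unstable", "left", "right")) - 1L)
    } else {
      list(basin = FALSE, F = rg$F, eta = rg$eta)
    }
  })
}

#' Look up the active fixed point and learning rate of a 2D rule
#'
#' For a scalar region returns its `(F, eta)` pair; for a basin region returns
#' the fixed point and rate of the basin containing `w`. A weight within
#' `tol` of a basin boundary returns the boundary value itself as fixed point
#' (an unstable fixed point) unless that boundary is declared half-stable.
#'
#' @param ca scalar calcium value.
#' @param w scalar current weight; must lie within the basin range of a basin
#'   region.
#' @param rule an [fplr_rule2d()].
#' @param tol boundary equality tolerance.
#' @return named list with elements `F` and `eta`.
#' @export
lookup_2d <- function(ca, w, rule, tol = 1e-12) {
  stopifnot(inherits(rule, "fplr_rule2d"), length(ca) == 1L, length(w) == 1L)
  rg <- rule$regions[[region_index(ca, rule$thresholds) + 1L]]
  if (!inherits(rg, "fplr_basin_spec")) return(list(F = rg$F, eta = rg$eta))
  b <- rg$boundaries
  if (w < b[1L] - tol || w > b[length(b)] + tol) {
    stop(sprintf("weight %g outside basin range [%g, %g]",
                 w, b[1L], b[length(b)]), call. = FALSE)
  }
  at <- which(abs(w - b) <= tol)
  if (length(at) > 0) {
    j <- at[1L]
    mode <- rg$boundary_mode[j]
    if (mode == "unstable") {
      # at an unstable fixed point: F equals the boundary, so delta is 0
      # whatever the rate; report the adjacent basin's rate
      k <- max(1L, min(j - 1L, length(rg$learning_rates)))
      return(list(F = b[j], eta = rg$learning_rates[k]))
    }
    k <- if (mode == "left") max(1L, j - 1L)
         else min(j, length(rg$fixed_points))
    return(list(F = rg$fixed_points[k], eta = rg$learning_rates[k]))
  }
  k <- findInterval(w, b, rightmost.closed = TRUE)
  k <- max(1L, min(k, length(rg$fixed_points)))
  list(F = rg$fixed_points[k], eta = rg$learning_rates[k])
}

#' Per-step weight change under the 2D FPLR rule
#'
#' `Delta w = eta(ca, w) * (F(ca, w) - w)` with the pair taken from
#' [lookup_2d()]. Because every `eta <= 1` and each basin's fixed point lies
#' inside the basin, a weight never crosses a basin boundary within the
#' pre-depressive region in a single step.
#'
#' @inheritParams lookup_2d
#' @export
fplr2d_delta <- function(ca, w, rule, tol = 1e-12) {
  n <- max(length(ca), length(w))
  ca <- rep_len(ca, n)
  w <- rep_len(w, n)
  vapply(seq_len(n), function(i) {
    fe <- lookup_2d(ca[i], w[i], rule, tol = tol)
    fe$eta * (fe$F - w[i])
  }, numeric(1))
}

#' Protein-synthesis-gated plasticity rule
#'
#' Couples an early/late-phase pair of rules through a binary protein state:
#' when the stabilizing protein is absent (`protein = 0`) the weight follows a
#' 1D FPLR rule (drift back to a single baseline); when present
#' (`protein = 1`) it follows a 2D FPLR rule whose pre-depressive basins
#' stabilize potentiated and depressed weights at distinct late-phase fixed
#' points. Both sub-rules must share the same calcium thresholds.
#'
#' @param no_protein_rule an [fplr_rule1d()].
#' @param protein_rule an [fplr_rule2d()].
#' @return An object of class `"fplr_protein_rule"`.
#' @export
protein_gated_rule <- function(no_protein_rule, protein_rule) {
  stopifnot(inherits(no_protein_rule, "fplr_rule1d"),
            inherits(protein_rule, "fplr_rule2d"))
  if (!isTRUE(all.equal(no_protein_rule$thresholds$all,
                        protein_rule$thresholds$all))) {
    stop("sub-rules must share the same calcium thresholds", call. = FALSE)
  }
  structure(list(no_protein_rule = no_protein_rule,
                 protein_rule = protein_rule,
                 thresholds = no_protein_rule$thresholds,
                 dt = no_protein_rule$dt),
            class = "fplr_protein_rule")
}

#' Per-step weight change under the protein-gated rule
#'
#' Dispatches to the 1D sub-rule when `protein = 0` and to the 2D sub-rule
#' when `protein = 1`.
#'
#' @inheritParams fplr2d_delta
#' @param protein 0 or 1 (vector allowed, recycled against `ca` and `w`).
#' @param rule a [protein_gated_rule()].
#' @export
protein_gated_delta <- function(ca, w, protein, rule, tol = 1e-12) {
  stopifnot(inherits(rule, "fplr_protein_rule"))
  if (!all(protein %in% c(0, 1))) {
    stop("`protein` must be 0 or 1", call. = FALSE)
  }
  n <- max(length(ca), length(w), length(protein))
  ca <- rep_len(ca, n)
  w <- rep_len(w, n)
  protein <- rep_len(protein, n)
  out <- numeric(n)
  if (any(protein == 0)) {
    i <- protein == 0
    out[i] <- fplr1d_delta(ca[i], w[i], rule$no_protein_rule)
  }
  if (any(protein == 1)) {
    i <- protein == 1
    out[i] <- fplr2d_delta(ca[i], w[i], rule$protein_rule, tol = tol)
  }
  out
}
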