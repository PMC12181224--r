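#' Piecewise-constant (or sigmoidally smoothed) function of calcium
#'
#' The basic building block of the fixed point-learning rate (FPLR) rules:
#' a step function of the calcium concentration holding one value per calcium
#' region. With `sharpness = NULL` the thresholds are hard (half-open
#' intervals, lower bound included). Supplying a positive sharpness `b_i` per
#' threshold replaces the hard steps by a sum of sigmoids
#' \deqn{v_0 + \sum_i (v_i - v_{i-1}) / (1 + e^{-b_i (Ca - \theta_i)})}
#' which converges pointwise (off the thresholds) to the hard step function as
#' all `b_i` grow large.
#'
#' @param thresholds ascending numeric vector of calcium thresholds, or an
#'   [thresholds()] object.
#' @param values numeric vector of per-region values; exactly one longer than
#'   the threshold vector.
#' @param sharpness optional positive numeric vector, one entry per threshold
#'   (recycled if scalar). `NULL` means hard thresholds.
#' @return An object of class `"fplr_step_fun"`.
#' @examples
#' F <- step_fun(c(1, 1.3), values = c(0.5, 0, 1))
#' eval_step(F, c(0.2, 1.1, 2))
#' @export
step_fun <- function(thresholds, values, sharpness = NULL) {
  th <- if (inherits(thresholds, "fplr_thresholds")) thresholds$all
        else as.numeric(thresholds)
  if (length(th) < 1L || any(diff(th) <= 0)) {
    stop("thresholds must be a strictly increasing vector", call. = FALSE)
  }
  if (length(values) != length(th) + 1L) {
    stop("`values` must have exactly one more entry than `thresholds`",
         call. = FALSE)
  }
  if (!is.null(sharpness)) {
    if (length(sharpness) == 1L) sharpness <- rep(sharpness, length(th))
    if (length(sharpness) != length(th) || any(sharpness <= 0)) {
      stop("`sharpness` must be positive, one value per threshold",
           call. = FALSE)
    }
  }
  structure(list(thresholds = as.numeric(th), values = as.numeric(values),
                 sharpness = sharpness),
            class = "fplr_step_fun")
}

#' @export
print.fplr_step_fun <- function(x, ...) {
  mode <- if (is.null(x$sharpness)) "hard" else "soft"
  cat("Step function (", mode, " thresholds)\n", sep = "")
  cat("  thresholds:", paste(x$thresholds, collapse = ", "), "\n")
  cat("  values:    ", paste(x$values, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a step function of calcium
#'
#' @param f an [step_fun()] object.
#' @param ca numeric vector of calcium values (>= 0).
#' @return numeric vector of the same length as `ca`.
#' @export
eval_step <- function(f, ca) {
  stopifnot(inherits(f, "fplr_step_fun"))
  if (any(!is.finite(ca)) || any(ca < 0)) {
    stop("calcium values must be finite and non-negative", call. = FALSE)
  }
  if (is.null(f$sharpness)) {
    return(f$values[findInterval(ca, f$thresholds) + 1L])
  }
  out <- rep(f$values[1L], length(ca))
  for (i in seq_along(f$thresholds)) {
    out <- out + (f$values[i + 1L] - f$values[i]) /
      (1 + exp(-f$sharpness[i] * (ca - f$thresholds[i])))
  }
  out
}

# scalar constant as a degenerate step function (used by rule constructors)
const_step <- function(value) {
  structure(list(thresholds = numeric(0), values = as.numeric(value),
                 sharpness = NULL),
            class = "fplr_step_fun")
}
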