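#' Calcium thresholds for plasticity regions
#'
#' A pair of calcium concentration thresholds `theta_d` (depression) and
#' `theta_p` (potentiation), optionally extended with further thresholds for
#' multi-region rules (e.g. a "no man's land" or a post-potentiative neutral
#' zone). The full ordered threshold vector partitions calcium space into
#' `length(thresholds) + 1` regions.
#'
#' @param theta_d depression threshold (calcium, arbitrary concentration
#'   units). Must be strictly positive.
#' @param theta_p potentiation threshold, strictly greater than `theta_d`.
#' @param extra optional numeric vector of additional thresholds; the combined
#'   vector `c(theta_d, theta_p, extra)` must be strictly increasing.
#' @return An object of class `"fplr_thresholds"`.
#' @examples
#' th <- thresholds(1, 1.3)
#' classify_region(c(0.5, 1, 1.3), th)
#' @export
thresholds <- function(theta_d, theta_p, extra = NULL) {
  stopifnot(is.numeric(theta_d), length(theta_d) == 1L,
            is.numeric(theta_p), length(theta_p) == 1L)
  all_th <- c(theta_d, theta_p, extra)
  if (any(!is.finite(all_th)) || any(all_th <= 0)) {
    stop("all thresholds must be finite and strictly positive", call. = FALSE)
  }
  if (any(diff(all_th) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  structure(list(theta_d = theta_d, theta_p = theta_p,
                 all = as.numeric(all_th)),
            class = "fplr_thresholds")
}

as_thresholds <- function(x) {
  if (inherits(x, "fplr_thresholds")) return(x)
  if (is.numeric(x) && length(x) >= 2L) {
    return(thresholds(x[1L], x[2L], if (length(x) > 2L) x[-(1:2)]))
  }
  stop("cannot interpret `x` as thresholds", call. = FALSE)
}

#' @export
print.fplr_thresholds <- function(x, ...) {
  cat("Calcium thresholds: theta_D =", x$theta_d, ", theta_P =", x$theta_p)
  if (length(x$all) > 2L) cat(", extra:", paste(x$all[-(1:2)], collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Integer calcium region index
#'
#' Assigns each calcium value to a region using half-open intervals
#' `[theta_i, theta_(i+1))`: region 0 lies below the first threshold, region
#' `k` is bounded below by the k-th threshold (inclusive).
#'
#' @param ca numeric vector of calcium values (>= 0).
#' @param thresholds an [thresholds()] object (or numeric vector of ordered
#'   thresholds).
#' @return integer vector of region indices in `0:length(thresholds$all)`.
#' @export
region_index <- function(ca, thresholds) {
  th <- as_thresholds(thresholds)
  if (any(!is.finite(ca)) || any(ca < 0)) {
    stop("calcium values must be finite and non-negative", call. = FALSE)
  }
  findInterval(ca, th$all)
}

#' Classify calcium into plasticity regions
#'
#' For the standard two-threshold rule returns `"pre_depressive"`
#' (`ca < theta_D`), `"depressive"` (`theta_D <= ca < theta_P`) or
#' `"potentiative"` (`ca >= theta_P`). Boundaries are half-open with the lower
#' bound included. When extra thresholds are present the regions beyond the
#' first three are labelled `"region_3"`, `"region_4"`, ...
#'
#' @inheritParams region_index
#' @return character vector of region labels.
#' @examples
#' classify_region(c(0.5, 1.0, 1.3), thresholds(1, 1.3))
#' @export
classify_region <- function(ca, thresholds) {
  idx <- region_index(ca, thresholds)
  labs <- c("pre_depressive", "depressive", "potentiative")
  out <- ifelse(idx <= 2L, labs[idx + 1L], paste0("region_", idx))
  as.character(out)
}
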