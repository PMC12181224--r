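#' Write and read time-series traces as CSV
#'
#' Two-column CSV with a header row, times in ms, '.' decimal separator, full
#' double precision. Calcium traces use columns `time, calcium`; weight
#' trajectories `time, weight`.
#'
#' @param x a [calcium_trace()] or [weight_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param what `"calcium"` or `"weight"`: which trace type to reconstruct.
#' @export
read_trace <- function(path, what = c("calcium", "weight")) {
  what <- match.arg(what)
  df <- utils::read.csv(path)
  if (nrow(df) < 1L) stop("empty trace file: ", path, call. = FALSE)
  dt <- if (nrow(df) > 1L) df$time[2L] - df$time[1L] else 1
  if (what == "calcium") {
    calcium_trace(df[[2L]], dt = dt, t0 = df$time[1L])
  } else {
    weight_trajectory(df[[2L]], dt = dt, w0 = df[[2L]][1L], t0 = df$time[1L])
  }
}

#' Write and read spike trains as single-column CSV of times (ms)
#'
#' @param x a [spike_train()] or numeric vector of spike times.
#' @param path file path.
#' @export
write_spike_train <- function(x, path) {
  utils::write.csv(data.frame(time = spike_times(x)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  spike_train(utils::read.csv(path)$time)
}

#' Run manifest
#'
#' Metadata sufficient to reproduce a run: preset name, overrides, seed and
#' package version. Written before any other output file.
#'
#' @param preset_name preset name or path.
#' @param seed RNG seed (or `NA`).
#' @param overrides named list of parameter overrides.
#' @param outputs character vector of output paths.
#' @return a list of class `"fplr_manifest"`.
#' @export
run_manifest <- function(preset_name, seed = NA, overrides = list(),
                         outputs = character(0)) {
  structure(list(
    preset = preset_name,
    overrides = overrides,
    seed = seed,
    package_version = as.character(utils::packageVersion("fplr")),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "fplr_manifest")
}

#' Write a protocol result (or BTSP session) to a directory
#'
#' Writes a `manifest.json` first, then CSV traces and a JSON summary at full
#' double precision. For a protocol result: `calcium.csv`, `weights.csv`,
#' `barcode.json`, `summary.json`. For a BTSP session: `voltage.csv`,
#' `weights_final.csv`, per-lap dwell-duration CSVs and `summary.json`.
#'
#' @param result a [protocol_result()] or [run_btsp_session()] object.
#' @param out_dir output directory (created if needed).
#' @param manifest optional [run_manifest()]; a minimal one is written if
#'   omitted.
#' @return character vector of the files written, invisibly.
#' @export
write_result <- function(result, out_dir, manifest = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (is.null(manifest)) manifest <- run_manifest(preset_name = NA)
  files <- character(0)
  wj <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    p
  }
  files <- c(files, wj(unclass(manifest), "manifest.json"))
  if (inherits(result, "fplr_protocol_result")) {
    p1 <- file.path(out_dir, "calcium.csv")
    write_trace(result$calcium, p1)
    p2 <- file.path(out_dir, "weights.csv")
    write_trace(result$weights, p2)
    files <- c(files, p1, p2,
               wj(list(depressive = result$barcode$depressive,
                       potentiative = result$barcode$potentiative,
                       durations = as.list(result$barcode$durations)),
                  "barcode.json"),
               wj(result$summary, "summary.json"))
  } else if (inherits(result, "fplr_btsp_session")) {
    p1 <- file.path(out_dir, "voltage.csv")
    utils::write.csv(data.frame(
      time = (seq_along(result$voltage) - 1L) * result$dt,
      voltage = result$voltage), p1, row.names = FALSE, quote = FALSE)
    p2 <- file.path(out_dir, "weights_final.csv")
    utils::write.csv(data.frame(synapse = seq_along(result$weights_final),
                                weight = result$weights_final),
                     p2, row.names = FALSE, quote = FALSE)
    p3 <- file.path(out_dir, "dwell_depressive.csv")
    utils::write.csv(as.data.frame(result$dwell_depressive), p3,
                     row.names = FALSE, quote = FALSE)
    p4 <- file.path(out_dir, "dwell_potentiative.csv")
    utils::write.csv(as.data.frame(result$dwell_potentiative), p4,
                     row.names = FALSE, quote = FALSE)
    summary <- list(
      laps = result$laps, dt = result$dt,
      inductions = as.list(result$inductions),
      seed = result$seed,
      w_final_range = range(result$weights_final),
      ramps = lapply(seq_len(result$laps), function(l) {
        detect_ramps(result, l)
      }))
    files <- c(files, p1, p2, p3, p4, wj(summary, "summary.json"))
  } else if (is.data.frame(result)) {
    p1 <- file.path(out_dir, "summary.csv")
    utils::write.csv(result, p1, row.names = FALSE, quote = FALSE)
    files <- c(files, p1)
  } else {
    stop("unsupported result type: ", class(result)[1L], call. = FALSE)
  }
  invisible(files)
}
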