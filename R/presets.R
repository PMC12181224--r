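#' Load a parameter preset
#'
#' Presets bundle a plasticity rule, calcium-generation parameters and (for
#' the place-field simulation) the track and neuron configuration, serialized
#' as JSON. Four presets ship with the package:
#'
#' * `"frequency"` — frequency-dependent plasticity: `theta_D = 1`,
#'   `theta_P = 1.3`, `C_pre = 1.05`, `tau_Ca = 10` ms, `eta_D = 0.04`,
#'   `eta_P = 0.055`, `F_D = 0.42`, `F_P = 2.25`, `dt = 0.01` ms, drift off.
#' * `"stdp"` — spike-timing-dependent plasticity: `C_pre = 0.9`,
#'   `C_post = 1.55`, `tau_Ca = 7` ms, `eta_D = 0.001`, `eta_P = 0.00075`,
#'   same thresholds and fixed points, `dt = 0.01` ms, drift off.
#' * `"btsp"` — behavioral-timescale plasticity: 1000 synapses on a 10 s
#'   circular track, `r = 400`, `P_max = 0.02`, `pre_height = 0.1`,
#'   `plateau_height = 1.33` for 300 ms, `tau_Ca = 2` s, `theta_D = 1.5`,
#'   `theta_P = 2.15`, `eta_D = 0.0017`, `eta_P = 0.15`, `F_D = 0.2`,
#'   `F_P = 2.5`, `dt = 1` ms.
#' * `"late_phase_fig5"` — protein-gated late-phase rule with biologically
#'   calibrated endpoints: early fixed points 0.42 / 2.25 of baseline reached
#'   at rate 1 per second; late-phase drift at 0.0046 per second, either back
#'   to baseline (no protein) or to stable states at 0.61 / 1.0 / 1.42 of
#'   baseline (protein present); `dt = 1` s.
#'
#' All rule invariants are checked at load time; a file with a learning rate
#' above 1 is rejected.
#'
#' @param name one of the shipped preset names, or a path to a preset JSON
#'   file.
#' @return An object of class `"fplr_preset"`: a list with `name`, `dt` (ms),
#'   `rule`, and depending on the preset `calcium`, `track`, `neuron`,
#'   `protocol`, `w0` and `provenance`.
#' @examples
#' p <- load_preset("frequency")
#' p$rule
#' @export
load_preset <- function(name) {
  shipped <- c("frequency", "stdp", "btsp", "late_phase_fig5")
  path <- if (name %in% shipped) {
    system.file("extdata", "presets", paste0(name, ".json"),
                package = "fplr", mustWork = TRUE)
  } else if (file.exists(name)) {
    name
  } else {
    stop(sprintf(
      "unknown preset '%s' (shipped presets: %s) and no such file",
      name, paste(shipped, collapse = ", ")), call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse_preset(raw, path)
}

parse_preset <- function(raw, path) {
  need <- function(field) {
    if (is.null(raw[[field]])) {
      stop(sprintf("preset '%s' is missing field '%s'", path, field),
           call. = FALSE)
    }
    raw[[field]]
  }
  th_raw <- need("thresholds")
  th <- thresholds(th_raw$theta_d, th_raw$theta_p,
                   extra = th_raw$extra %||% NULL)
  dt <- need("dt")
  rule_raw <- need("rule")
  rule <- parse_rule(rule_raw, th, dt, path)
  out <- list(name = raw$name %||% basename(path), dt = dt,
              thresholds = th, rule = rule,
              w0 = raw$w0 %||% NULL, provenance = raw$provenance %||% "",
              protocol = raw$protocol %||% NULL)
  if (!is.null(raw$calcium)) {
    ca <- raw$calcium
    if (!is.null(ca$tau_ca) && !is.null(ca$c_pre)) {
      out$calcium <- calcium_params(ca$c_pre, ca$c_post %||% 0, ca$tau_ca)
    } else if (!is.null(ca$pre_height)) {
      out$calcium <- btsp_calcium_params(ca$pre_height, ca$plateau_height,
                                         ca$plateau_duration, ca$tau_ca)
    }
  }
  if (!is.null(raw$track)) {
    tr <- raw$track
    out$track <- track_config(tr$T, tr$N, tr$r, tr$P_max)
  }
  if (!is.null(raw$neuron)) {
    nn <- raw$neuron
    out$neuron <- neuron_params(nn$C_m, nn$tau_v, nn$V_rest, nn$V_plateau,
                                nn$syn_scale %||% 0.4)
  }
  structure(out, class = "fplr_preset")
}

# Convert learning rates from the units a preset declares to per-step
# fractions at step size dt (ms). Printed parameter sets state continuous
# rates (per ms, or per s for the late-phase calibration) that are integrated
# by forward Euler, so eta_step = eta * dt.
eta_to_step <- function(eta, units, dt_ms) {
  switch(units,
         per_step = eta,
         per_ms = eta * dt_ms,
         per_s = eta * dt_ms / 1000,
         stop("unknown eta_units: ", units, call. = FALSE))
}

parse_rule <- function(rr, th, dt, path) {
  type <- rr$type %||% "fplr1d"
  units <- rr$eta_units %||% "per_step"
  if (type == "fplr1d") {
    return(fplr_rule1d(th, F = rr$F, eta = eta_to_step(rr$eta, units, dt),
                       dt = dt, sharpness = rr$sharpness %||% NULL))
  }
  if (type == "protein_gated") {
    np <- rr$no_protein
    no_protein <- fplr_rule1d(th, F = np$F,
                              eta = eta_to_step(np$eta, units, dt), dt = dt)
    pr <- rr$protein
    regions <- lapply(pr, function(rg) {
      if (!is.null(rg$basins)) {
        b <- rg$basins
        basin_spec(b$fixed_points, b$boundaries,
                   eta_to_step(b$learning_rates, units, dt))
      } else {
        c(F = rg$F, eta = eta_to_step(rg$eta, units, dt))
      }
    })
    protein <- fplr_rule2d(th, regions = unname(regions), dt = dt)
    return(protein_gated_rule(no_protein, protein))
  }
  stop(sprintf("preset '%s': unknown rule type '%s'", path, type),
       call. = FALSE)
}

#' @export
print.fplr_preset <- function(x, ...) {
  cat("Preset '", x$name, "' (dt = ", x$dt, " ms)\n", sep = "")
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  print(x$rule)
  invisible(x)
}
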