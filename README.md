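# fplr

Simulators for calcium-controlled synaptic plasticity built around the
**fixed point–learning rate (FPLR)** idea: the postsynaptic calcium
concentration tells a synaptic weight *where it is going* (a fixed point per
calcium region) and *how fast it goes there* (a learning rate per region).
The package is for computational neuroscientists and experimentalists who
want a small, analytically transparent phenomenological model of long-term
potentiation and depression (LTP/LTD) — the early, calcium-driven phase and
the late, protein-synthesis-dependent phase — without committing to a
mechanistic kinase/phosphatase model.

## The model

With depression and potentiation thresholds `θ_D < θ_P`, a weight update per
time step is

```
Δw = η(Ca) · (F(Ca) − w)
```

where `F(Ca)` and `η(Ca)` are step functions of calcium: e.g. drift toward a
baseline below `θ_D`, depress toward `F_D` on `[θ_D, θ_P)`, potentiate toward
`F_P` at and above `θ_P`. Each step contracts the distance to the active
fixed point by exactly `1 − η`; under constant calcium `C`,

```
w(t_E) = F(C) + (w(t_S) − F(C)) · exp(−η (t_E − t_S)).
```

The same machinery covers the classical two-threshold rules (linear, with
weight decay, with calcium-dependent rate), the bistable cubic-drift rule and
its simplified variant, a two-dimensional rule whose pre-depressive drift has
multiple weight-dependent stable states (basins of attraction), and a
protein-gated combination of the two used for late-phase LTP/LTD. Calcium
itself is generated as step stimuli or spike-driven exponentially decaying
transients, summarized by region "bar codes" (when was calcium depressive /
potentiative, and for how long). A compiled leaky-integrator simulation
reproduces behavioral-timescale plasticity (BTSP): place-field formation,
overwriting by a nearby second induction, and coexistence with a distant one.

## Worked example

```r
library(fplr)

# high-frequency stimulation potentiates a baseline synapse...
run_frequency_protocol(100, w0 = 1)
#> Protocol result: w0 = 1 -> w_final = 1.17166 (dw = 0.171662 )
#>   dwell: depressive 10.98 ms, potentiative 7.61 ms

# ...while low-frequency stimulation depresses it
run_frequency_protocol(2, w0 = 1)
#> Protocol result: w0 = 1 -> w_final = 0.945846 (dw = -0.0541539 )
#>   dwell: depressive 2.45 ms, potentiative 0 ms
```

Five presynaptic spikes at 100 Hz (calcium jump 1.05, decay 10 ms) sum above
`θ_P = 1.3` for 7.6 ms, relaxing the weight toward `F_P = 2.25`; the
depressive dwell — including the unavoidable pass back through
`[θ_D, θ_P)` as calcium decays ("what goes up must come down") — takes part
of that gain back, for a net +0.17. At 2 Hz the transients stay below `θ_P`
and the synapse only depresses (−0.05).

```r
# late-phase LTD with protein synthesis: early depression to 42% of
# baseline, then hours of drift that stabilize at 61%
run_late_phase_experiment("LTD", "present")
#> Protocol result: w0 = 1 -> w_final = 0.61 (dw = -0.39 )
#>   dwell: depressive 9000 ms, potentiative 0 ms

# a 7-lap BTSP session with inductions at 3.5 s, 2 s, and 7.5 s
ses <- run_btsp_session(seed = 1)
detect_ramps(ses, 3)        # place field on the lap after the first induction
#>   start  end
#>    1740 5280              # (longest ramp; brackets the 3.5 s induction)
```

Presets (`load_preset("frequency" | "stdp" | "btsp" | "late_phase_fig5")`)
carry the published parameter tables; `frequency_sweep()`, `stdp_sweep()`,
`weight_change_map()` and `phase_plane()` generate the corresponding heatmap
grids. A command-line interface wrapping these functions ships in
`inst/cli/fplr.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","fplr.R",package="fplr"))')" \
  btsp --laps 7 --inductions 2:3500,4:2000,6:7500 --seed 1 --out out/
```

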