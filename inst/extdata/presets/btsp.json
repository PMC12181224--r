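{
  "name": "btsp",
  "provenance": "behavioral-timescale plasticity parameter set (circular track, plateau inductions)",
  "dt": 1,
  "w0": 0.2,
  "thresholds": {
    "theta_d": 1.5,
    "theta_p": 2.15
  },
  "rule": {
    "type": "fplr1d",
    "F": [
      1.0,
      0.2,
      2.5
    ],
    "eta": [
      0.0,
      0.0017,
      0.15
    ],
    "eta_units": "per_ms"
  },
  "calcium": {
    "pre_height": 0.1,
    "plateau_height": 1.33,
    "plateau_duration": 300,
    "tau_ca": 2000
  },
  "track": {
    "T": 10000,
    "N": 1000,
    "r": 400,
    "P_max": 0.02
  },
  "neuron": {
    "C_m": 1,
    "tau_v": 15,
    "V_rest": -75,
    "V_plateau": -30,
    "syn_scale": 0.4
  }
}
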