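{
  "name": "frequency",
  "provenance": "frequency-dependent plasticity parameter set (early phase, drift off)",
  "dt": 0.01,
  "w0": 1,
  "thresholds": {
    "theta_d": 1.0,
    "theta_p": 1.3
  },
  "rule": {
    "type": "fplr1d",
    "F": [
      1.0,
      0.42,
      2.25
    ],
    "eta": [
      0.0,
      0.04,
      0.055
    ],
    "eta_units": "per_ms"
  },
  "calcium": {
    "c_pre": 1.05,
    "c_post": 0.0,
    "tau_ca": 10
  }
}
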