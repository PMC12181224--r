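{
  "name": "stdp",
  "provenance": "spike-timing-dependent plasticity parameter set (early phase, drift off)",
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
      0.001,
      0.00075
    ],
    "eta_units": "per_ms"
  },
  "calcium": {
    "c_pre": 0.9,
    "c_post": 1.55,
    "tau_ca": 7
  }
}
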