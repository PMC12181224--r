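{
  "name": "late_phase_fig5",
  "provenance": "protein-gated late-phase LTP/LTD calibration (weights relative to baseline; rates per second)",
  "dt": 1000,
  "w0": 1,
  "thresholds": {
    "theta_d": 1.0,
    "theta_p": 1.3
  },
  "rule": {
    "type": "protein_gated",
    "no_protein": {
      "F": [
        1.0,
        0.42,
        2.25
      ],
      "eta": [
        0.0046,
        1.0,
        1.0
      ]
    },
    "protein": {
      "pre_depressive": {
        "basins": {
          "fixed_points": [
            0.61,
            1.0,
            1.42
          ],
          "boundaries": [
            0.0,
            0.8,
            1.2,
            2.5
          ],
          "learning_rates": [
            0.0046,
            0.0046,
            0.0046
          ]
        }
      },
      "depressive": {
        "F": 0.42,
        "eta": 1.0
      },
      "potentiative": {
        "F": 2.25,
        "eta": 1.0
      }
    },
    "eta_units": "per_s"
  },
  "protocol": {
    "ltd_hold_ca": 1.15,
    "ltp_hold_ca": 2.0,
    "ltd_early_s": 9,
    "ltp_early_s": 3,
    "ltd_late_h": 4.5,
    "ltp_late_h": 10
  }
}
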