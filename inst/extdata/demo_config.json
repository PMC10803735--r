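{
  "seed": 20240122,
  "out_dir": "demo_output",
  "simulate": {
    "eeg": {
      "groups": {
        "CC": {"suppression": {"V": 1, "AV_i": 0.5, "AV_c": 0}, "n_participants": 4},
        "MCC": {"suppression": {"V": 1, "AV_i": 1, "AV_c": 1}, "n_participants": 4}
      },
      "trials_per_cell": 40,
      "srate": 250,
      "c1_amplitude": 2,
      "noise_sd": 5,
      "blink_rate": 0.05,
      "saccade_rate": 0.05
    },
    "rt": {
      "groups": {
        "CC": {"model": "coactivation", "coactivation_shift": 40},
        "MCC": {"model": "coactivation", "coactivation_shift": 40}
      },
      "n_trials": 40,
      "n_participants": 8
    }
  },
  "erp": {
    "band": [0.1, 40]
  },
  "infer": {
    "draws": 2000,
    "deprived_group": "CC",
    "control_group": "MCC"
  },
  "rmi": {
    "n_perm": 2001,
    "min_trials": 10
  }
}
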