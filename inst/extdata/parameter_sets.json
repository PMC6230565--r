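{
  "version": "1.0",
  "note": "Rhythmostat model parameter sets. Times are decimal clock hours (t = 0 at midnight, post-midnight bedtimes > 24); SWA quantities are in relative slow-wave-activity units; time constants in hours.",
  "presets": {
    "adult_baseline": {
      "A": 0.50, "phi0": 4.13, "tau": 24.00, "k": 2.00,
      "SWA_l": 0.70, "SWA_b": 0.75, "SWA_d": 2.50, "SWA_u": 4.50,
      "T_d": 1.95, "T_b": 27.04,
      "t2": 23.00, "t1": 7.00, "weekday_risetime": null
    },
    "highschool_survey": {
      "A": 0.50, "phi0": 3.66, "tau": 24.00, "k": 2.00,
      "SWA_l": 0.70, "SWA_b": 0.75, "SWA_d": 2.50, "SWA_u": 4.50,
      "T_d": 2.29, "T_b": 25.22,
      "t2": 24.20, "t1": 8.85, "weekday_risetime": 6.33
    }
  },
  "age_groups": [
    {"label": "<=6", "n": 16,
     "params": {"A": 0.50, "phi0": 3.66, "tau": 24.00, "k": 2.00,
                "SWA_l": 0.70, "SWA_b": 0.765, "SWA_d": 3.25, "SWA_u": 6.00,
                "T_d": 2.36, "T_b": 18.39,
                "t2": 20.84, "t1": 7.79, "weekday_risetime": 7.30},
     "empirical": {"weekend_bedtime": 20.89, "weekend_risetime": 7.88,
                   "weekday_bedtime": 20.42, "weekday_risetime": 7.26}},
    {"label": "6+", "n": 21,
     "params": {"A": 0.50, "phi0": 3.66, "tau": 24.00, "k": 2.00,
                "SWA_l": 0.70, "SWA_b": 0.76, "SWA_d": 3.00, "SWA_u": 5.50,
                "T_d": 2.42, "T_b": 20.40,
                "t2": 22.23, "t1": 8.41, "weekday_risetime": 7.10},
     "empirical": {"weekend_bedtime": 22.32, "weekend_risetime": 8.63,
                   "weekday_bedtime": 21.40, "weekday_risetime": 7.11}},
    {"label": "10+", "n": 24,
     "params": {"A": 0.50, "phi0": 3.66, "tau": 24.00, "k": 2.00,
                "SWA_l": 0.70, "SWA_b": 0.755, "SWA_d": 2.75, "SWA_u": 5.00,
                "T_d": 2.41, "T_b": 21.67,
                "t2": 22.85, "t1": 8.60, "weekday_risetime": 6.90},
     "empirical": {"weekend_bedtime": 22.93, "weekend_risetime": 8.79,
                   "weekday_bedtime": 21.94, "weekday_risetime": 6.90}},
    {"label": "12+", "n": 25,
     "params": {"A": 0.50, "phi0": 3.66, "tau": 24.00, "k": 2.00,
                "SWA_l": 0.70, "SWA_b": 0.755, "SWA_d": 2.75, "SWA_u": 5.00,
                "T_d": 2.56, "T_b": 22.86,
                "t2": 23.45, "t1": 9.05, "weekday_risetime": 6.70},
     "empirical": {"weekend_bedtime": 23.47, "weekend_risetime": 9.25,
                   "weekday_bedtime": 22.23, "weekday_risetime": 6.71}},
    {"label": "14+", "n": 14,
     "params": {"A": 0.50, "phi0": 3.66, "tau": 24.00, "k": 2.00,
                "SWA_l": 0.70, "SWA_b": 0.755, "SWA_d": 2.75, "SWA_u": 5.00,
                "T_d": 2.61, "T_b": 24.80,
                "t2": 24.28, "t1": 9.47, "weekday_risetime": 6.90},
     "empirical": {"weekend_bedtime": 24.31, "weekend_risetime": 9.73,
                   "weekday_bedtime": 23.12, "weekday_risetime": 6.86}},
    {"label": "15+", "n": 21,
     "params": {"A": 0.50, "phi0": 3.66, "tau": 24.00, "k": 2.00,
                "SWA_l": 0.70, "SWA_b": 0.755, "SWA_d": 2.75, "SWA_u": 5.00,
                "T_d": 2.47, "T_b": 25.12,
                "t2": 24.37, "t1": 9.25, "weekday_risetime": 6.70},
     "empirical": {"weekend_bedtime": 24.43, "weekend_risetime": 9.57,
                   "weekday_bedtime": 23.08, "weekday_risetime": 6.66}},
    {"label": "16+", "n": 21,
     "params": {"A": 0.50, "phi0": 3.66, "tau": 24.00, "k": 2.00,
                "SWA_l": 0.70, "SWA_b": 0.755, "SWA_d": 2.75, "SWA_u": 5.00,
                "T_d": 2.55, "T_b": 26.14,
                "t2": 24.78, "t1": 9.53, "weekday_risetime": 6.70},
     "empirical": {"weekend_bedtime": 24.77, "weekend_risetime": 9.81,
                   "weekday_bedtime": 23.44, "weekday_risetime": 6.68}},
    {"label": "18+", "n": 18,
     "params": {"A": 0.50, "phi0": 3.66, "tau": 24.00, "k": 2.00,
                "SWA_l": 0.70, "SWA_b": 0.755, "SWA_d": 2.75, "SWA_u": 5.00,
                "T_d": 2.40, "T_b": 27.81,
                "t2": 25.40, "t1": 9.64, "weekday_risetime": 7.70},
     "empirical": {"weekend_bedtime": 25.42, "weekend_risetime": 9.80,
                   "weekday_bedtime": 24.25, "weekday_risetime": 7.66}}
  ],
  "reference_discrepancies": {
    "note": "Published empirical-minus-simulated discrepancies (hours) for the eight age groups, used only as a cross-check surface by the test suite.",
    "quantities": ["bedtime_weekday", "bedtime_weekend", "risetime_weekday", "risetime_weekend",
                   "tib_weekday", "tib_weekend", "shift_bedtime", "shift_risetime", "shift_tib"],
    "groups": ["<=6", "6+", "10+", "12+", "14+", "15+", "16+", "18+"],
    "values": {
      "bedtime_weekday":  [-0.12, -0.08, -0.05, -0.05, -0.01, -0.07,  0.02, -0.34],
      "bedtime_weekend":  [ 0.05,  0.09,  0.08,  0.02,  0.03,  0.06, -0.01,  0.03],
      "risetime_weekday": [-0.04,  0.01,  0.00,  0.01, -0.04, -0.04, -0.02, -0.04],
      "risetime_weekend": [ 0.08,  0.23,  0.19,  0.20,  0.26,  0.32,  0.28,  0.16],
      "tib_weekday":      [ 0.06,  0.09,  0.05,  0.07, -0.03,  0.02, -0.05,  0.31],
      "tib_weekend":      [ 0.03,  0.13,  0.11,  0.17,  0.23,  0.26,  0.29,  0.13],
      "shift_bedtime":    [-0.14, -0.17, -0.14, -0.08, -0.04, -0.13,  0.03, -0.37],
      "shift_risetime":   [-0.12, -0.21, -0.19, -0.18, -0.31, -0.37, -0.30, -0.20],
      "shift_tib":        [ 0.02, -0.04, -0.06, -0.11, -0.27, -0.24, -0.33,  0.17]
    }
  }
}
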