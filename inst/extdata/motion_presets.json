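{
  "smooth_pursuit": [
    {"delta_deg": 20, "duration_s": 1.5, "pause_s": 1},
    {"delta_deg": 20, "duration_s": 1.5, "pause_s": 1},
    {"delta_deg": -20, "duration_s": 1.5, "pause_s": 1},
    {"delta_deg": 20, "duration_s": 1.5, "pause_s": 0}
  ],
  "smooth_pursuit_programmed": [
    {"delta_deg": 20, "duration_s": 1.8, "pause_s": 0.05},
    {"delta_deg": -20, "duration_s": 1.8, "pause_s": 0.05},
    {"delta_deg": -20, "duration_s": 1.8, "pause_s": 0.05},
    {"delta_deg": 20, "duration_s": 1.8, "pause_s": 0}
  ],
  "scene_saccades": [
    {"delta_deg": 4, "duration_s": 0.05, "pause_s": 0.33},
    {"delta_deg": 4, "duration_s": 0.05, "pause_s": 0.33},
    {"delta_deg": 4, "duration_s": 0.05, "pause_s": 0.33},
    {"delta_deg": -12, "duration_s": 1, "pause_s": 0}
  ],
  "micro_saccades": [
    {"delta_deg": 0.55, "duration_s": 0.014, "pause_s": 1.25},
    {"delta_deg": -0.55, "duration_s": 0.014, "pause_s": 1.25},
    {"delta_deg": 10, "duration_s": 0.5, "pause_s": 1.25},
    {"delta_deg": 0.55, "duration_s": 0.014, "pause_s": 1.25},
    {"delta_deg": -0.55, "duration_s": 0.014, "pause_s": 1.25},
    {"delta_deg": -20, "duration_s": 0.5, "pause_s": 0},
    {"delta_deg": -0.55, "duration_s": 0.014, "pause_s": 1.25},
    {"delta_deg": -0.55, "duration_s": 0.014, "pause_s": 1.25},
    {"delta_deg": 10, "duration_s": 0.5, "pause_s": 1.25}
  ],
  "micro_saccades_programmed": [
    {"delta_deg": 0.4, "duration_s": 0.02, "pause_s": 1.25},
    {"delta_deg": -0.4, "duration_s": 0.02, "pause_s": 1.25}
  ]
}
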