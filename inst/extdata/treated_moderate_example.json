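{
  "patient":   {"weight_kg": 75},
  "infection": {"severity": "Moderate", "mic_mg_L": 16},
  "run":       {"t_end": 24, "macro_step": 0.05},
  "actions": [
    {"time_h": 6, "type": "drug_infusion", "drug": "piperacillin",
     "dose": 4500, "duration_h": 0.5},
    {"time_h": 6, "type": "bolus", "volume_ml": 500, "duration_h": 0.5}
  ]
}
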