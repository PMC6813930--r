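{
  "patient":   {"weight_kg": 75},
  "infection": {"severity": "Severe", "mic_mg_L": 16,
                "location": "example tissue site"},
  "run":       {"t_end": 48, "macro_step": 0.05},
  "actions":   []
}
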