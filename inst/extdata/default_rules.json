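{
  "at_signature_table": {
    "HAFH": {"name": "malonyl", "side_chain_carbons": 0},
    "YASH": {"name": "methylmalonyl", "side_chain_carbons": 1},
    "TAGH": {"name": "alkylmalonyl", "side_chain_carbons": null}
  },
  "kr_fingerprint_table": {
    "A1": {"beta": "R", "alpha": "R"},
    "A2": {"beta": "R", "alpha": "S"},
    "B1": {"beta": "S", "alpha": "R"},
    "B2": {"beta": "S", "alpha": "S"}
  },
  "kr_geometry_table": {"A": "Z", "B": "E"},
  "er_table": {"Y": "S", "V": "R"},
  "enrichment_threshold": 3,
  "allow_unknown_at": false
}
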