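{
  "title": "rltdosim comparison export",
  "description": "Structure of comparison.json written by dosim_compare(); checked by validate_comparison_json().",
  "type": "object",
  "required": ["method", "comparisons"],
  "properties": {
    "method": {"type": "string", "enum": ["SM1", "SM2", "SM3"]},
    "tp_label": {"type": ["string", "null"]},
    "denominator": {"type": "string", "enum": ["rm", "mean"]},
    "comparisons": {
      "type": "object",
      "required": ["method", "tp_label", "group", "cycle", "n", "bias_pct",
                   "sd_pct", "loa_pct", "loa_low_pct", "loa_high_pct", "rmse"],
      "properties": {
        "group": {"type": "array", "items": {"type": "string"}},
        "cycle": {"type": "array", "items": {"type": ["integer", "null"]}},
        "n": {"type": "array", "items": {"type": "integer"}},
        "bias_pct": {"type": "array", "items": {"type": "number"}},
        "sd_pct": {"type": "array", "items": {"type": "number"}},
        "loa_pct": {"type": "array", "items": {"type": "number"}},
        "loa_low_pct": {"type": "array", "items": {"type": "number"}},
        "loa_high_pct": {"type": "array", "items": {"type": "number"}},
        "rmse": {"type": "array", "items": {"type": "number"}}
      }
    }
  }
}
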