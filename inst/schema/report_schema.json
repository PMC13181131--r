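{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "seqssvep pipeline report",
  "type": "object",
  "required": ["provenance", "stimulus_set", "n_distinct_repeat_frequencies",
               "metrics", "ppc_by_repeat_frequency", "units"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["config_hash", "seed", "package_version", "thresholds"],
      "properties": {
        "config_hash": {"type": "string"},
        "seed": {"type": "integer"},
        "package_version": {"type": "string"},
        "thresholds": {"type": "object"}
      }
    },
    "stimulus_set": {"type": "array"},
    "n_distinct_repeat_frequencies": {"type": "integer"},
    "metrics": {"type": "array"},
    "ppc_by_repeat_frequency": {"type": "array"},
    "units": {"type": "array"},
    "statistics": {"type": ["object", "null"]}
  }
}
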