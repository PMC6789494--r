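{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "chiralnet analysis report",
  "type": "object",
  "required": ["schema_version", "network", "order", "verdict", "per_i",
               "confirmed_states", "provenance"],
  "properties": {
    "schema_version": {"type": "string"},
    "network": {"type": "string"},
    "order": {"type": "integer", "minimum": 1},
    "verdict": {"enum": ["accept", "reject", "inconclusive"]},
    "reason": {"type": "string"},
    "n_extreme_currents": {"type": "integer", "minimum": 0},
    "per_i": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["i", "polynomial", "status"],
        "properties": {
          "i": {"type": "integer", "minimum": 1},
          "polynomial": {"type": "string"},
          "status": {"enum": ["certified_empty", "found", "not_found"]},
          "n_samples_found": {"type": "integer"},
          "n_tried": {"type": "integer"}
        }
      }
    },
    "confirmed_states": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["j", "concentrations", "rate_constants"],
        "properties": {
          "j": {"type": "array", "items": {"type": "number"}},
          "concentrations": {"type": "object"},
          "rate_constants": {"type": "object"},
          "lambda": {"type": ["object", "null"]},
          "max_re": {"type": "number"}
        }
      }
    },
    "simulations": {"type": ["array", "null"]},
    "provenance": {
      "type": "object",
      "required": ["config"],
      "properties": {
        "config": {"type": "object", "required": ["seed"]},
        "package_version": {"type": "string"}
      }
    }
  }
}
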