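{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "cryolink validation report",
  "type": "object",
  "required": ["tool", "version", "generated", "config", "counts",
               "pairs", "assessments"],
  "properties": {
    "tool": {"const": "cryolink"},
    "version": {"type": "string"},
    "generated": {"type": "string"},
    "config": {
      "type": "object",
      "required": ["satisfied_max", "reference_observed_max",
                   "theoretical_range", "unresolved_proximity_max"],
      "properties": {
        "satisfied_max": {"type": "number", "exclusiveMinimum": 0},
        "reference_observed_max": {"type": "number", "exclusiveMinimum": 0},
        "theoretical_range": {
          "type": "array", "items": {"type": "number"},
          "minItems": 2, "maxItems": 2
        },
        "unresolved_proximity_max": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "counts": {
      "type": "object",
      "required": ["n", "n_satisfied", "n_violated", "n_unresolved",
                   "n_below_reference", "n_in_theoretical_band",
                   "n_above_satisfied_max"],
      "additionalProperties": {"type": "integer", "minimum": 0}
    },
    "pairs": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["subunit1", "subunit2", "n", "n_satisfied",
                     "n_violated", "n_unresolved"]
      }
    },
    "assessments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["protein1", "site1", "protein2", "site2", "score",
                     "status"],
        "properties": {
          "status": {"enum": ["satisfied", "violated", "unresolved"]}
        }
      }
    },
    "fdr": {
      "type": "object",
      "required": ["fdr", "raw", "counts"]
    }
  }
}
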