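{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "fairness_report",
  "description": "Per-repeat fairness metric distributions from repeated stratified cross-validation. Undefined metric values are explicit nulls with a reason in 'note' (empty-group, zero-denominator, degenerate-fold), never omitted rows.",
  "type": "object",
  "required": ["metrics", "summary", "delta"],
  "properties": {
    "metrics": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["attribute", "modality", "mitigation", "repeat", "metric", "value"],
        "properties": {
          "attribute": {"type": "string"},
          "modality": {"type": "string"},
          "mitigation": {"type": "string"},
          "repeat": {"type": "integer", "minimum": 1},
          "metric": {"enum": ["dpr_overall", "dpr_privileged", "eor_overall", "eor_privileged", "macro_f1", "accuracy"]},
          "value": {"type": ["number", "null"]},
          "note": {"type": ["string", "null"]}
        }
      }
    },
    "summary": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "median": {"type": ["number", "null"]},
          "q1": {"type": ["number", "null"]},
          "q3": {"type": ["number", "null"]},
          "iqr": {"type": ["number", "null"]},
          "n": {"type": "integer"},
          "n_undefined": {"type": "integer"},
          "n_outliers": {"type": ["integer", "null"]}
        }
      }
    },
    "delta": {"type": "number", "exclusiveMinimum": 0},
    "manifest": {"type": ["object", "null"]}
  }
}
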