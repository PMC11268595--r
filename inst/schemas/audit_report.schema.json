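{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "audit_report",
  "description": "Cohort composition audit: per-(attribute, group, label) counts and selection rates, chi-square independence tests, Mann-Whitney covariate comparisons, and the per-attribute exclusion log.",
  "type": "object",
  "required": ["composition", "independence_tests", "covariate_tests", "exclusions", "n_tests", "alpha"],
  "properties": {
    "composition": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["attribute", "label", "group", "n", "n_positive", "selection_rate"],
        "properties": {
          "n": {"type": "integer", "minimum": 0},
          "n_positive": {"type": "integer", "minimum": 0},
          "selection_rate": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    },
    "independence_tests": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "statistic": {"type": ["number", "null"]},
          "df": {"type": ["number", "null"]},
          "p_value": {"type": ["number", "null"]},
          "significant": {"type": ["boolean", "null"]},
          "skipped": {"type": "boolean"},
          "warning_note": {"type": ["string", "null"]}
        }
      }
    },
    "covariate_tests": {"type": "array"},
    "exclusions": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "attribute": {"type": "string"},
          "group": {"type": ["string", "null"]},
          "n": {"type": "integer"},
          "reason": {"type": "string"}
        }
      }
    },
    "n_tests": {"type": "integer", "minimum": 0},
    "alpha": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
    "manifest": {"type": ["object", "null"]}
  }
}
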