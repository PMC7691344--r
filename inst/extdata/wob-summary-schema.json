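{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ripwob cohort summary document",
  "type": "object",
  "required": ["format", "version", "valid_fraction", "summary"],
  "properties": {
    "format": {"const": "ripwob_summary"},
    "version": {"type": "integer"},
    "valid_fraction": {"type": "number", "minimum": 0, "maximum": 1},
    "summary": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variable", "mean", "n"],
        "properties": {
          "variable": {"type": "string"},
          "mean": {"type": ["number", "null"]},
          "sem": {"type": ["number", "null"]},
          "n": {"type": "integer", "minimum": 0}
        }
      }
    },
    "histograms": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["variable", "bin_width", "bin_edges", "counts", "n"],
        "properties": {
          "variable": {"type": "string"},
          "bin_width": {"type": "number", "exclusiveMinimum": 0},
          "bin_edges": {"type": "array", "items": {"type": "number"}},
          "counts": {"type": "array", "items": {"type": "integer", "minimum": 0}},
          "n": {"type": "integer", "minimum": 0},
          "range": {"type": "array", "items": {"type": "number"}},
          "pct_in_range": {"type": "number", "minimum": 0, "maximum": 100}
        }
      }
    }
  }
}
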