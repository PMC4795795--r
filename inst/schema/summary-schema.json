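{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "reachframes experiment summary",
  "description": "Schema of the summary.json written by run_experiment() for the delay-period classification experiments. Dynamics and gradient experiments write their trend/size summaries with the same JSON conventions.",
  "type": "object",
  "properties": {
    "included_total": { "type": "integer", "minimum": 0 },
    "per_node": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "properties": {
          "included": { "type": "integer", "minimum": 0 },
          "counts": {
            "type": "object",
            "properties": {
              "eye": { "type": "number" },
              "hand": { "type": "number" },
              "intermediate": { "type": "number" },
              "indeterminate": { "type": "number" }
            },
            "required": ["eye", "hand", "intermediate", "indeterminate"]
          },
          "percent": {
            "type": "object",
            "properties": {
              "eye": { "type": "number" },
              "hand": { "type": "number" },
              "intermediate": { "type": "number" },
              "indeterminate": { "type": "number" }
            },
            "required": ["eye", "hand", "intermediate", "indeterminate"]
          }
        },
        "required": ["included", "counts", "percent"]
      }
    }
  },
  "required": ["included_total", "per_node"]
}
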