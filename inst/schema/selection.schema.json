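{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "mi2cast/selection/1.0",
  "title": "Feature selection document",
  "description": "Configuration-panel state driving template generation; accepted as JSON or YAML. Each entry of a 'modifications' array is itself an array of subfeature names for that modification.",
  "type": "object",
  "properties": {
    "source": { "$ref": "#/$defs/side" },
    "target": { "$ref": "#/$defs/side" },
    "relation_flags": {
      "type": "array",
      "items": {
        "enum": ["mechanism", "compartment", "cell_line", "cell_type",
                 "tissue", "taxon"]
      }
    },
    "reference_count": { "type": "integer", "minimum": 1, "default": 1 },
    "evidence_count": { "type": "integer", "minimum": 1, "default": 1 }
  },
  "$defs": {
    "side": {
      "type": "object",
      "properties": {
        "modifications": {
          "type": "array",
          "items": {
            "type": "array",
            "items": { "enum": ["residue", "position"] }
          }
        },
        "flags": {
          "type": "array",
          "items": { "enum": ["biological_type", "compartment"] }
        }
      }
    }
  }
}
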