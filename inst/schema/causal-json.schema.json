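{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "mi2cast/causal-json/1.0",
  "title": "causal-JSON",
  "description": "Lossless interchange format for MI2CAST causal statements. Every vocabulary term serializes as an {id, label} object, never a bare string. Readers must tolerate (warn on, then ignore) unknown keys.",
  "type": "object",
  "required": ["format_version", "statements"],
  "properties": {
    "format_version": { "const": "1.0" },
    "statements": {
      "type": "array",
      "items": { "$ref": "#/$defs/statement" }
    }
  },
  "$defs": {
    "term": {
      "type": "object",
      "required": ["id", "label"],
      "properties": {
        "id": { "type": "string", "pattern": "^[A-Za-z][A-Za-z0-9.-]*:.+$" },
        "label": { "type": "string", "minLength": 1 }
      }
    },
    "modification": {
      "type": "object",
      "required": ["term"],
      "properties": {
        "term": { "$ref": "#/$defs/term" },
        "residue": { "$ref": "#/$defs/term" },
        "position": { "type": "integer", "minimum": 1 }
      }
    },
    "entity": {
      "type": "object",
      "required": ["id", "label"],
      "properties": {
        "id": { "type": "string" },
        "label": { "type": "string", "minLength": 1 },
        "biological_type": { "$ref": "#/$defs/term" },
        "modifications": {
          "type": "array",
          "items": { "$ref": "#/$defs/modification" }
        },
        "compartment": { "$ref": "#/$defs/term" }
      }
    },
    "statement": {
      "type": "object",
      "required": ["source", "target", "relation", "references", "evidence"],
      "properties": {
        "source": { "$ref": "#/$defs/entity" },
        "target": { "$ref": "#/$defs/entity" },
        "relation": { "$ref": "#/$defs/term" },
        "references": {
          "type": "array", "minItems": 1,
          "items": {
            "type": "object", "required": ["id"],
            "properties": { "id": { "type": "string" } }
          }
        },
        "evidence": {
          "type": "array", "minItems": 1,
          "items": { "$ref": "#/$defs/term" }
        },
        "mechanism": { "$ref": "#/$defs/term" },
        "compartment": { "$ref": "#/$defs/term" },
        "cell_line": { "$ref": "#/$defs/term" },
        "cell_type": { "$ref": "#/$defs/term" },
        "tissue": { "$ref": "#/$defs/term" },
        "taxon": { "$ref": "#/$defs/term" }
      }
    }
  }
}
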