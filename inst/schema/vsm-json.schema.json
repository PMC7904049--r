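{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "mi2cast/vsm-json/1.0",
  "title": "VSM-JSON (package dialect)",
  "description": "Serialization of a VSM sentence/template: an ordered term array (0-based consecutive positions) plus trident connectors, each a [bearer, relation, argument] triple of term positions; connectors attach only to terms and their endpoints are pairwise distinct. The light form ('format': 'vsm-json-light') is the projection that keeps ids, labels, connectors and the roles of still-empty fields but drops template data (placeholder, lookup, fieldId); it is write-only.",
  "type": "object",
  "required": ["format", "version", "terms", "connectors"],
  "properties": {
    "format": { "enum": ["vsm-json", "vsm-json-light"] },
    "version": { "const": "1.0" },
    "terms": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["position", "variant"],
        "properties": {
          "position": { "type": "integer", "minimum": 0 },
          "variant": { "enum": ["filled", "prefilled", "empty"] },
          "label": { "type": "string" },
          "id": { "type": "string" },
          "fieldId": { "type": "string" },
          "role": { "type": "string" },
          "placeholder": { "type": "string" },
          "lookup": {
            "type": "object",
            "properties": {
              "roles": { "type": "array", "items": { "type": "string" } }
            }
          }
        }
      }
    },
    "connectors": {
      "type": "array",
      "items": {
        "type": "array",
        "items": { "type": "integer", "minimum": 0 },
        "minItems": 3,
        "maxItems": 3
      }
    }
  }
}
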