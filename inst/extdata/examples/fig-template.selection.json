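{
  "source": { "modifications": [[]], "flags": [] },
  "target": { "modifications": [], "flags": [] },
  "relation_flags": ["compartment"],
  "reference_count": 1,
  "evidence_count": 1
}
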