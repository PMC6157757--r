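{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "aomontage transforms output",
  "type": "object",
  "required": ["components", "pairwise", "parameters"],
  "properties": {
    "components": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["reference", "transforms"],
        "properties": {
          "reference": {"type": "string"},
          "transforms": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["tile_id", "tx", "ty"],
              "properties": {
                "tile_id": {"type": "string"},
                "tx": {"type": "number"},
                "ty": {"type": "number"}
              }
            }
          }
        }
      }
    },
    "pairwise": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["src", "dst", "tx", "ty", "inliers"]
      }
    },
    "parameters": {"type": "object"}
  }
}
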