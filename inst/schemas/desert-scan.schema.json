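{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "kmersketch desert-scan report",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["id", "length", "n_selected", "n_deserts",
                 "cumulative_desert", "min_length"],
    "properties": {
      "id": {"type": "string"},
      "length": {"type": "integer", "minimum": 0},
      "n_selected": {"type": "integer", "minimum": 0},
      "n_deserts": {"type": "integer", "minimum": 0},
      "deserts": {
        "type": ["array", "object"],
        "description": "start/end 0-based half-open, length in bases, all_ambiguous flag"
      },
      "cumulative_desert": {"type": "integer", "minimum": 0},
      "min_length": {"type": "integer", "minimum": 1}
    }
  }
}
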