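{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "kmersketch ilp result record",
  "type": "object",
  "required": ["sigma", "k", "cardinality", "max_path", "status",
               "wall_time", "nodes_explored"],
  "properties": {
    "sigma": {"type": "integer", "minimum": 2},
    "k": {"type": "integer", "minimum": 2},
    "cardinality": {"type": "integer", "minimum": 0},
    "max_path": {"type": "integer", "minimum": 0,
                 "description": "edges on the longest remaining path"},
    "expected_absorption": {"type": ["number", "null"]},
    "status": {"enum": ["optimal"]},
    "wall_time": {"type": "number", "minimum": 0},
    "nodes_explored": {"type": "integer", "minimum": 1}
  }
}
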