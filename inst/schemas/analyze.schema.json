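{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "kmersketch analyze report",
  "type": "object",
  "required": ["sigma", "k", "cardinality", "relative_size", "n_scc",
               "scc_cumulative_size", "scc_cumulative_fraction",
               "window_guarantee", "symmetric"],
  "properties": {
    "sigma": {"type": "integer", "minimum": 2},
    "k": {"type": "integer", "minimum": 1},
    "cardinality": {"type": "integer", "minimum": 0},
    "relative_size": {"type": "number", "minimum": 0, "maximum": 1},
    "n_scc": {"type": "integer", "minimum": 0},
    "scc_sizes": {"type": "array", "items": {"type": "integer"}},
    "scc_cumulative_size": {"type": "integer", "minimum": 0},
    "scc_cumulative_fraction": {"type": "number", "minimum": 0, "maximum": 1},
    "window_guarantee": {"enum": ["strong", "relaxed", "none"]},
    "symmetric": {"type": "boolean"},
    "longest_path": {"type": "integer", "minimum": 0},
    "window": {"type": "integer", "minimum": 1}
  }
}
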