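{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tssmap analysis report",
  "type": "object",
  "required": ["tool", "version", "seed", "config_hash", "simulate", "peaks",
               "profiles", "expression", "qpcr"],
  "properties": {
    "tool": {"type": "string"},
    "version": {"type": "string"},
    "seed": {"type": "number"},
    "config_hash": {"type": "string"},
    "simulate": {
      "type": "object",
      "required": ["n_genes", "n_canonical_peaks", "de_core"]
    },
    "peaks": {
      "type": "object",
      "required": ["concordance", "consensus_peak_count", "tss_proximity",
                   "element_enrichment", "size_bins", "accessible_cooccupancy",
                   "occupancy_classes"],
      "properties": {
        "consensus_peak_count": {"type": "number"},
        "tss_proximity": {
          "type": "object",
          "required": ["proximal_count", "total", "percent"]
        }
      }
    },
    "profiles": {
      "type": "object",
      "required": ["tss_profile_argmax_bp"]
    },
    "expression": {
      "type": "object",
      "required": ["group_occupancy", "meta_de", "venn"]
    },
    "qpcr": {
      "type": "object",
      "required": ["summary", "ref_condition"]
    },
    "generated_at": {"type": "string"}
  }
}
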