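{
  "title": "tfcobind pipeline report",
  "description": "Required sections and fields of report.json produced by run_pipeline(). Values are JSON numbers, strings or booleans; enrichment holds one object per tested gene set plus permutation metadata.",
  "required": {
    "meta": ["config_hash", "seed", "analysis_seed"],
    "peaks": ["n_peaks_a_input", "n_peaks_b_input", "n_peaks_a_filtered", "n_peaks_b_filtered", "q_threshold"],
    "assignment": ["upstream_bp", "n_targets_a", "n_targets_b", "fraction_assigned_a", "fraction_assigned_b"],
    "cobinding": ["n_common", "pct_of_a", "pct_of_b", "universe_size", "hypergeom_p", "window_bp", "n_within_window", "fraction_within"],
    "motif": ["threshold_fraction", "fraction_per_motif", "fraction_per_factor", "de_novo_consensus"],
    "expression": ["fold_threshold", "min_rpkm", "n_de", "n_up_in_a", "n_up_in_b"],
    "enrichment": ["permutation_mode", "n_permutations"]
  }
}
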