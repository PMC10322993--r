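{
  "seed": 20260922,
  "output_dir": "morphogene_demo",
  "stages": ["simulate", "effects", "convergence", "genebrain", "behavior"],
  "n_perm": 500,
  "n_rot": 200,
  "n_gene_draws": 1000,
  "gene_subset": "all",
  "sided": "directional",
  "adjust_global": true,
  "target_r": 0.6
}
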