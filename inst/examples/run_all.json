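{
  "seed": 1,
  "simulate": {
    "n_genes_total": 2000,
    "n_genes_per_stage": {"immediate": 100, "early": 100,
                          "intermediate-1": 100, "intermediate-2": 100,
                          "late": 100}
  },
  "thresholds": {"fdr_max": 0.05, "min_abs_fold": 2},
  "stringent": "none",
  "projection": {
    "enabled": true,
    "atlas_synthetic": {"n_cells": 1500, "cluster_separation": 10,
                        "within_cluster_sd": 0.5},
    "bulk": "cluster_bulks",
    "n_samples": 4,
    "bulk_depth": 1000000
  }
}
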