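{
  "mismatch_model": {
    "terminal_match": true,
    "window": 4,
    "max_mm_window": 1,
    "max_mm_total": 3
  },
  "gel_models": {
    "agarose_2.5": {
      "id": "agarose_2.5",
      "min_resolvable_gap": 25,
      "max_product": 3000
    },
    "agarose_4": {
      "id": "agarose_4",
      "min_resolvable_gap": 8,
      "max_product": 300
    },
    "page_8": {
      "id": "page_8",
      "min_resolvable_gap": 3,
      "max_product": 1000
    },
    "capillary": {
      "id": "capillary",
      "min_resolvable_gap": 2,
      "max_product": 6000
    }
  },
  "design_constraints": {
    "max_product_small_indel": 120,
    "tetra_outer_max": 600,
    "min_allele_size_gap": 25,
    "tri_primer_target_gap": 150,
    "tm_range": [55, 62],
    "primer_length_range": [18, 28],
    "product_range_tetra": [120, 350]
  },
  "efficiency_lambda": 0.002,
  "imbalance_ratio": 3,
  "display_floor": 0.05,
  "seed": 1
}
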