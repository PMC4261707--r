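{
  "physiology": {
    "renal_cortex_volume_l": 0.216,
    "pt_fraction_of_cortex": 0.3,
    "pct_fraction_of_pt": 0.7,
    "bladder_volume_l": 0.2,
    "gfr_l_per_h": 6.5,
    "urine_outflow_l_per_h": 0.6,
    "flow_decrement": 0.074,
    "gfr_ranges_l_per_h": {
      "healthy_baseline": [5.66, 7.38],
      "healthy_drug": [5.19, 7.41],
      "t2dm_baseline": [6.52, 7.62],
      "t2dm_drug": [5.07, 7.53]
    },
    "urine_outflow_ranges_l_per_h": {
      "healthy_baseline": [0.63, 1.2],
      "healthy_drug": [0.78, 1.4],
      "t2dm_baseline": [0.54, 1.24],
      "t2dm_drug": [0.8, 1.2]
    }
  },
  "transporters": {
    "healthy": {
      "vmax1_mmol_h": 20.0,
      "vmax2_mmol_h": 93.5,
      "km1_mm": 0.5,
      "km2_mm": 4.0
    },
    "t2dm": {
      "vmax1_mmol_h": 20.0,
      "vmax2_mmol_h": 110.0,
      "km1_mm": 0.5,
      "km2_mm": 4.0
    }
  },
  "inhibitors": {
    "dapagliflozin": {
      "molecular_weight": 409,
      "free_fraction": 0.07,
      "ki1_nm": 400,
      "ki2_nm": 0.3
    },
    "canagliflozin": {
      "molecular_weight": 454,
      "free_fraction": 0.01,
      "ki1_nm": 200,
      "ki2_nm": 0.6
    }
  }
}
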