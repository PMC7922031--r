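{
  "name": "erythromycin_synthetic",
  "molecular_weight": 733.93,
  "lipophilicity": 3.06,
  "solubility": 2000,
  "fraction_unbound": 0.3,
  "intestinal_permeability": 0.0003,
  "partition_method": "rodgers_rowland",
  "processes": [
    {
      "kind": "mm",
      "enzyme": "CYP3A4",
      "K_m": 88,
      "k_cat": 1,
      "product": null,
      "stoichiometry": 1,
      "label": "CYP3A4"
    },
    {
      "kind": "hepatic_cl",
      "CL_hep": 0.01,
      "label": "CL_hep"
    },
    {
      "kind": "gfr",
      "gfr_fraction": 0.1,
      "label": "GFR"
    }
  ],
  "interactions": [
    {
      "mode": "mechanism-based",
      "target_enzyme": "CYP3A4",
      "K_I": 10,
      "k_inact": 0.05
    }
  ],
  "formulations": [
    {
      "name": "solution",
      "kind": "dissolved",
      "food_state": "fasted"
    }
  ]
}
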