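{
  "name": "alprazolam_synthetic",
  "molecular_weight": 308.77,
  "lipophilicity": 2.12,
  "solubility": 40,
  "fraction_unbound": 0.29,
  "intestinal_permeability": 0.0004,
  "partition_method": "rodgers_rowland",
  "processes": [
    {
      "kind": "mm",
      "enzyme": "CYP3A4",
      "K_m": 300,
      "k_cat": 1.5,
      "product": null,
      "stoichiometry": 1,
      "label": "CYP3A4"
    },
    {
      "kind": "gfr",
      "gfr_fraction": 0.02,
      "label": "GFR"
    }
  ],
  "interactions": [],
  "formulations": [
    {
      "name": "solution",
      "kind": "dissolved",
      "food_state": "fasted"
    }
  ]
}
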