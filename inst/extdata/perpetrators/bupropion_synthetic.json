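{
  "name": "bupropion_synthetic",
  "molecular_weight": 239.74,
  "lipophilicity": 3.27,
  "solubility": 300,
  "fraction_unbound": 0.16,
  "intestinal_permeability": 0.0004,
  "partition_method": "rodgers_rowland",
  "processes": [
    {
      "kind": "mm",
      "enzyme": "CYP2B6",
      "K_m": 130,
      "k_cat": 1.5,
      "product": null,
      "stoichiometry": 1,
      "label": "CYP2B6"
    },
    {
      "kind": "gfr",
      "gfr_fraction": 0.1,
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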