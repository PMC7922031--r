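{
  "name": "simvastatin_synthetic",
  "molecular_weight": 418.57,
  "lipophilicity": 4.68,
  "solubility": 30,
  "fraction_unbound": 0.06,
  "intestinal_permeability": 0.0002,
  "partition_method": "rodgers_rowland",
  "processes": [
    {
      "kind": "mm",
      "enzyme": "CYP3A4",
      "K_m": 35,
      "k_cat": 2,
      "product": null,
      "stoichiometry": 1,
      "label": "CYP3A4"
    },
    {
      "kind": "hepatic_cl",
      "CL_hep": 0.05,
      "label": "CL_hep"
    }
  ],
  "interactions": [
    {
      "mode": "competitive",
      "target_enzyme": "CYP3A4",
      "K_i": 10
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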