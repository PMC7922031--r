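{
  "name": "efavirenz_synthetic",
  "molecular_weight": 315.68,
  "lipophilicity": 4.6,
  "solubility": 9,
  "fraction_unbound": 0.015,
  "intestinal_permeability": 0.0003,
  "partition_method": "rodgers_rowland",
  "processes": [
    {
      "kind": "mm",
      "enzyme": "CYP2B6",
      "K_m": 10,
      "k_cat": 0.4,
      "product": null,
      "stoichiometry": 1,
      "label": "CYP2B6"
    },
    {
      "kind": "mm",
      "enzyme": "CYP3A4",
      "K_m": 20,
      "k_cat": 0.05,
      "product": null,
      "stoichiometry": 1,
      "label": "CYP3A4"
    },
    {
      "kind": "hepatic_cl",
      "CL_hep": 0.002,
      "label": "CL_hep"
    }
  ],
  "interactions": [
    {
      "mode": "induction",
      "target_enzyme": "CYP3A4",
      "EC_50": 12,
      "E_max": 3
    },
    {
      "mode": "induction",
      "target_enzyme": "CYP2B6",
      "EC_50": 12,
      "E_max": 4
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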