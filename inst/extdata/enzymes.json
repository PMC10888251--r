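{
  "_comment": "Curated microscopic rate constants and reference conditions for ten uni-uni enzymes. Values are stored exactly as printed in the source kinetic tables; second-order constants are in 1/(M s), first-order constants in 1/s, concentrations in M. 'printed_first_order' holds pseudo-first-order values as printed (k_i = k_i* x [ligand]); these define the default reference rate set. 'keq_convention' records which overall equilibrium constant the source table prints: 'chem' = concentration-independent (second-order constants in binding steps), 'app' = apparent (pseudo-first-order constants, equal to exp(Xtot/RT)). 'reference' holds the printed derived parameters used as cross-checks.",
  "tpi": {
    "full_name": "rabbit muscle triosephosphate isomerase",
    "n_states": 4,
    "scheme_variant": "standard",
    "keq_convention": "chem",
    "second_order": {
      "k1": {"value": 1e7, "ligand": "S"},
      "k8": {"value": 4e8, "ligand": "P"}
    },
    "first_order": {"k2": 7000, "k3": 2000, "k4": 6000, "k5": 60000, "k6": 90000, "k7": 4000},
    "printed_first_order": {"k1": 400, "k8": 25.60},
    "environment": {"substrate": 4e-5, "product": 6.4e-8, "enzyme": 5e-8, "temperature": "about 20 C"},
    "reference": {"kcat": 432, "km": 5.5e-4, "specificity": 7.86e5, "keqtot": 3.2e-3, "xtot": 0.685, "p": 9.9}
  },
  "ksi": {
    "full_name": "Commamonas testosteroni 3-oxo-Delta5-ketosteroid isomerase",
    "n_states": 4,
    "scheme_variant": "standard",
    "keq_convention": "chem",
    "second_order": {
      "k1": {"value": 8.3e8, "ligand": "S"},
      "k8": {"value": 1e9, "ligand": "P"}
    },
    "first_order": {"k2": 8.6e4, "k3": 1.8e5, "k4": 1.7e6, "k5": 6.4e5, "k6": 43, "k7": 1.5e5},
    "printed_first_order": {"k1": 8.3e4, "k8": 5e4},
    "environment": {"substrate": 1e-4, "product": 5e-5, "enzyme": 5e-6, "temperature": "25 C"},
    "reference": {"kcat": 3.5e4, "km": 1.16e-4, "specificity": 3e8, "keqtot": 2281, "xtot": 8.426, "p": 1.16e5},
    "variants": {
      "ref89": {
        "_comment": "earlier literature column; k4 and k5 are lower bounds in the source",
        "second_order": {
          "k1": {"value": 8.6e8, "ligand": "S"},
          "k8": {"value": 8.6e8, "ligand": "P"}
        },
        "first_order": {"k2": 8.6e4, "k3": 1.7e5, "k4": 3e5, "k5": 1e5, "k6": 40, "k7": 1.3e5}
      }
    }
  },
  "ca1": {
    "full_name": "human carbonic anhydrase I",
    "n_states": 4,
    "scheme_variant": "ca_buffer",
    "keq_convention": "app",
    "second_order": {
      "k1": {"value": 3.4e7, "ligand": "S"},
      "k4": {"value": 2.6e7, "ligand": "P"},
      "k7": {"value": 1.1e8, "ligand": "B"},
      "k8": {"value": 9.0e5, "ligand": "B"}
    },
    "first_order": {"k2": 3.8e4, "k3": 2.9e5, "k5": 9.0e5, "k6": 9.0e6},
    "printed_first_order": {"k1": 4.08e4, "k4": 6.24e5, "k7": 5.50e6, "k8": 4.50e4},
    "environment": {"substrate": 1.2e-3, "product": 2.4e-2, "buffer": 5.0e-2, "enzyme": 1.0e-4, "temperature": "25 C"},
    "reference": {"kcat": 7.77e4, "km": 3.13e-3, "specificity": 2.48e7, "keqtot": 6.10, "xtot": 1.81, "p": 2.84e4}
  },
  "ca2": {
    "full_name": "human carbonic anhydrase II",
    "n_states": 4,
    "scheme_variant": "ca_buffer",
    "keq_convention": "app",
    "second_order": {
      "k1": {"value": 1.3e8, "ligand": "S"},
      "k4": {"value": 2.0e8, "ligand": "P"},
      "k7": {"value": 4.0e8, "ligand": "B"},
      "k8": {"value": 2.0e7, "ligand": "B"}
    },
    "first_order": {"k2": 1.8e6, "k3": 1.7e7, "k5": 1.2e6, "k6": 1.2e6},
    "printed_first_order": {"k1": 1.56e5, "k4": 4.80e6, "k7": 2.00e7, "k8": 1.00e6},
    "environment": {"substrate": 1.2e-3, "product": 2.4e-2, "buffer": 5.0e-2, "enzyme": 1.0e-4, "temperature": "25 C"},
    "reference": {"kcat": 8.05e5, "km": 9.63e-3, "specificity": 8.36e7, "keqtot": 6.14, "xtot": 1.81, "p": 1.25e5}
  },
  "ca2_t200h": {
    "full_name": "human carbonic anhydrase II, Thr200His mutant",
    "n_states": 4,
    "scheme_variant": "ca_buffer",
    "keq_convention": "app",
    "second_order": {
      "k1": {"value": 8.2e7, "ligand": "S"},
      "k4": {"value": 9.0e6, "ligand": "P"},
      "k7": {"value": 3.6e8, "ligand": "B"},
      "k8": {"value": 1.8e7, "ligand": "B"}
    },
    "first_order": {"k2": 5.4e4, "k3": 3.0e5, "k5": 2.7e6, "k6": 2.1e7},
    "printed_first_order": {"k1": 9.84e4, "k4": 2.16e5, "k7": 1.80e7, "k8": 9.00e5},
    "environment": {"substrate": 1.2e-3, "product": 2.4e-2, "buffer": 5.0e-2, "enzyme": 1.0e-4, "temperature": "25 C"},
    "reference": {"kcat": 2.10e5, "km": 3.10e-3, "specificity": 6.77e7, "keqtot": 6.51, "xtot": 1.87, "p": 6.29e4}
  },
  "pc1": {
    "full_name": "Staphylococcus aureus PC1 beta-lactamase",
    "n_states": 3,
    "scheme_variant": "standard",
    "keq_convention": "app",
    "second_order": {
      "k1": {"value": 2.2e7, "ligand": "S"},
      "k6": {"value": 1.0e6, "ligand": "P"}
    },
    "first_order": {"k2": 196, "k3": 173, "k4": 4.0, "k5": 96},
    "printed_first_order": {"k1": 3.28e4, "k6": 8.0},
    "environment": {"substrate": 1.492e-3, "product": 8.0e-6, "enzyme": 1e-5, "temperature": "20 C"},
    "reference": {"kcat": 61, "km": 6.0e-6, "specificity": 1.01e7, "keqtot": 8.69e4, "xtot": 11.4, "p": 689}
  },
  "rtem": {
    "full_name": "Escherichia coli RTEM beta-lactamase",
    "n_states": 3,
    "scheme_variant": "standard",
    "keq_convention": "app",
    "second_order": {
      "k1": {"value": 1.23e8, "ligand": "S"},
      "k6": {"value": 4.0e7, "ligand": "P"}
    },
    "first_order": {"k2": 1.18e4, "k3": 2.8e3, "k4": 6.0, "k5": 1.5e3},
    "printed_first_order": {"k1": 1.71e5, "k6": 4.4e3},
    "environment": {"substrate": 1.390e-3, "product": 1.1e-4, "enzyme": 1e-5, "temperature": "20 C"},
    "reference": {"kcat": 9.75e2, "km": 4.15e-5, "specificity": 2.35e7, "keqtot": 2.3e3, "xtot": 7.74, "p": 6757}
  },
  "lac1": {
    "full_name": "Bacillus cereus Lac-1 beta-lactamase",
    "n_states": 3,
    "scheme_variant": "standard",
    "keq_convention": "app",
    "second_order": {
      "k1": {"value": 4.1e7, "ligand": "S"},
      "k6": {"value": 8.0e6, "ligand": "P"}
    },
    "first_order": {"k2": 2.32e3, "k3": 4.09e3, "k4": 50, "k5": 3.61e3},
    "printed_first_order": {"k1": 5.27e4, "k6": 1.72e3},
    "environment": {"substrate": 1.285e-3, "product": 2.15e-4, "enzyme": 1e-5, "temperature": "20 C"},
    "reference": {"kcat": 1.91e3, "km": 7.32e-5, "specificity": 2.60e7, "keqtot": 3.9e3, "xtot": 8.3, "p": 14526}
  },
  "beta_gal": {
    "full_name": "Escherichia coli beta-galactosidase",
    "n_states": 2,
    "scheme_variant": "standard",
    "keq_convention": "app",
    "second_order": {
      "k1": {"value": 5.0e7, "ligand": "S"},
      "k4": {"value": 10, "ligand": "P"}
    },
    "first_order": {"k2": 1.83e4, "k3": 7.3e2},
    "printed_first_order": {"k1": 5.0e3, "k4": 1e-5},
    "_note": "printed k4 corresponds to an effective product concentration of 1e-6 M, not the listed 1e-7 M; the printed value is kept because the table's own Keqtot, Xtot/RT and dissipation derive from it",
    "environment": {"substrate": 1e-4, "product": 1e-7, "enzyme": 1e-6, "temperature": "25 C"},
    "reference": {"kcat": 730, "km": 3.81e-4, "specificity": 1.92e6, "keqtot": 2.0e7, "xtot": 16.81, "p": 2.55e3}
  },
  "glucose_isomerase": {
    "full_name": "Streptomyces murinus glucose (xylose) isomerase",
    "n_states": 2,
    "scheme_variant": "standard",
    "keq_convention": "app",
    "second_order": {
      "k1": {"value": 0.063, "ligand": "S"},
      "k4": {"value": 0.082, "ligand": "P"}
    },
    "first_order": {"k2": 0.021, "k3": 0.029},
    "printed_first_order": {"k1": 0.126, "k4": 0.0164},
    "environment": {"substrate": 2.0, "product": 0.2, "enzyme": 0.01, "temperature": "65 C"},
    "reference": {"kcat": 0.029, "km": 0.794, "specificity": 0.0365, "keqtot": 10.61, "xtot": 2.36, "p": 0.0406}
  }
}
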