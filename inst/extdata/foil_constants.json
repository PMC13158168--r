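{
  "schema_version": 1,
  "provenance": "half-lives, line intensities and abundances from standard evaluated decay data; detector efficiencies are representative HPGe full-energy-peak values and are measurement inputs",
  "foils": {
    "Au": {
      "reaction": "Au-197(n,g)Au-198",
      "half_life_s": 232822,
      "gamma_line_keV": 412,
      "gamma_intensity": 0.9562,
      "abundance": 1.0,
      "atomic_mass_g_mol": 196.967,
      "element_mass_fraction": 1.0,
      "diameter_mm": 10,
      "thickness_mm": 0.05,
      "efficiency": 0.012,
      "xs_file": "xs_au197_ng.csv"
    },
    "Mn": {
      "reaction": "Mn-55(n,g)Mn-56",
      "half_life_s": 9284,
      "gamma_line_keV": 847,
      "gamma_intensity": 0.9885,
      "abundance": 1.0,
      "atomic_mass_g_mol": 54.938,
      "element_mass_fraction": 0.13,
      "diameter_mm": 10,
      "thickness_mm": 0.2,
      "efficiency": 0.0065,
      "xs_file": "xs_mn55_ng.csv"
    },
    "Al": {
      "reaction": "Al-27(n,a)Na-24",
      "half_life_s": 53989,
      "gamma_line_keV": 1369,
      "gamma_intensity": 0.99994,
      "abundance": 1.0,
      "atomic_mass_g_mol": 26.982,
      "element_mass_fraction": 1.0,
      "diameter_mm": 20,
      "thickness_mm": 2.5,
      "efficiency": 0.0042,
      "xs_file": "xs_al27_na.csv"
    }
  },
  "biology": {
    "CBE_skin": 2.5,
    "RBE_N": 2.9,
    "RBE_H": 2.4,
    "reference_boron_ppm": 25,
    "tumor_blood_ratio": 2.5,
    "CBE_tumor": 3.8,
    "alpha_beta_tumor_Gy": 10,
    "alpha_beta_normal_Gy": 2,
    "gamma_Sv_per_Gy": 1
  },
  "tissue": {
    "H": 0.101,
    "C": 0.111,
    "N": 0.026,
    "O": 0.762
  }
}
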