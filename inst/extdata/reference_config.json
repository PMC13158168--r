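{
  "schema_version": 1,
  "_comment": "Parametric out-of-field reference model. Spectrum per location = thermal Maxwellian (kT) + 1/E epithermal + exponential fast tail, each amplitude decaying exponentially with lateral distance from the field center with a component-specific attenuation length (thermal shortest). Users with genuine Monte Carlo room output should serialize it in the ReferenceLibrary JSON schema instead.",
  "charge_per_treatment_C": 0.05,
  "kT_MeV": 2.53e-8,
  "fast_E0_MeV": 0.5,
  "amplitude_per_C": {
    "thermal": 1.0e13,
    "epithermal": 5.3e12,
    "fast": 2.4e11
  },
  "attenuation_cm": {
    "thermal": 15,
    "epithermal": 19,
    "fast": 23
  },
  "field_edge_offset_cm": 7.5,
  "_distances_comment": "PLACEHOLDERS except the waist: only the waist lateral offset (~65 cm from the irradiation center) is established; edit per installation. Gamma doses and primary fractions are calibrated to the reported per-location out-of-field magnitudes.",
  "locations": [
    { "id": "neck",    "distance_cm": 15,  "gamma_Gy": 0.65,  "gamma_primary_fraction": 0.35 },
    { "id": "chest",   "distance_cm": 40,  "gamma_Gy": 0.36,  "gamma_primary_fraction": 0.55 },
    { "id": "abdomen", "distance_cm": 55,  "gamma_Gy": 0.15,  "gamma_primary_fraction": 0.70 },
    { "id": "waist",   "distance_cm": 65,  "gamma_Gy": 0.07,  "gamma_primary_fraction": 0.80 },
    { "id": "knee",    "distance_cm": 95,  "gamma_Gy": 0.03,  "gamma_primary_fraction": 0.916 },
    { "id": "ankle",   "distance_cm": 125, "gamma_Gy": 0.013, "gamma_primary_fraction": 0.272 }
  ]
}
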