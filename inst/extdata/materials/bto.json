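{
  "material_id": "bto",
  "description": "Pristine BaTiO3 (BTO) sextic Landau-Devonshire coefficient set. NOTE: standard literature parameterization (Bell & Cross-type single-crystal set widely used in BaTiO3 phase-field work), not a fitted-in-house set. Each coefficient is slope*(T - T_ref) + offset with T in kelvin.",
  "units": {
    "alpha1": "C^-2 m^2 N",
    "alpha11": "C^-4 m^6 N",
    "alpha12": "C^-4 m^6 N",
    "alpha111": "C^-6 m^10 N",
    "alpha112": "C^-6 m^10 N",
    "alpha123": "C^-6 m^10 N"
  },
  "coefficients": {
    "alpha1":   {"slope": 3.34e5,  "T_ref": 381, "offset": 0},
    "alpha11":  {"slope": 4.69e6,  "T_ref": 393, "offset": -2.02e8},
    "alpha12":  {"slope": 0,       "T_ref": 0,   "offset": 3.23e8},
    "alpha111": {"slope": -5.52e7, "T_ref": 393, "offset": 2.76e9},
    "alpha112": {"slope": 0,       "T_ref": 0,   "offset": 4.47e9},
    "alpha123": {"slope": 0,       "T_ref": 0,   "offset": 4.91e9}
  }
}
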