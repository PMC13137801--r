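{
  "material_id": "btz",
  "description": "BaTi0.85Zr0.15O3 (BTZ) sextic Landau-Devonshire coefficient set. Each coefficient is slope*(T - T_ref) + offset with T in kelvin.",
  "units": {
    "alpha1": "C^-2 m^2 N",
    "alpha11": "C^-4 m^6 N",
    "alpha12": "C^-4 m^6 N",
    "alpha111": "C^-6 m^10 N",
    "alpha112": "C^-6 m^10 N",
    "alpha123": "C^-6 m^10 N"
  },
  "coefficients": {
    "alpha1":   {"slope": 3.11e5,  "T_ref": 293, "offset": 0},
    "alpha11":  {"slope": 4.43e6,  "T_ref": 333, "offset": 0},
    "alpha12":  {"slope": 0,       "T_ref": 0,   "offset": -2.15e8},
    "alpha111": {"slope": -5.16e7, "T_ref": 333, "offset": 2.61e9},
    "alpha112": {"slope": 0,       "T_ref": 0,   "offset": 2.95e9},
    "alpha123": {"slope": 0,       "T_ref": 0,   "offset": 5.65e9}
  }
}
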