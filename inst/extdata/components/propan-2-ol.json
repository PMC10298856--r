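{
  "name": "2-propanol",
  "molar_mass": 60.096,
  "Tc": 508.3,
  "Pc": 4.76,
  "omega": 0.665,
  "Tb": 355.4,
  "molar_volume_table": [
    {
      "T_K": 278.15,
      "V0_m3mol": 7.535e-05
    },
    {
      "T_K": 283.15,
      "V0_m3mol": 7.57e-05
    },
    {
      "T_K": 288.15,
      "V0_m3mol": 7.612e-05
    },
    {
      "T_K": 293.15,
      "V0_m3mol": 7.652e-05
    },
    {
      "T_K": 298.15,
      "V0_m3mol": 7.693e-05
    },
    {
      "T_K": 303.15,
      "V0_m3mol": 7.735e-05
    },
    {
      "T_K": 308.15,
      "V0_m3mol": 7.778e-05
    },
    {
      "T_K": 313.15,
      "V0_m3mol": 7.823e-05
    },
    {
      "T_K": 318.15,
      "V0_m3mol": 7.866e-05
    },
    {
      "T_K": 323.15,
      "V0_m3mol": 7.915e-05
    }
  ],
  "antoine": {
    "A": 17.6939,
    "B": 4114.55,
    "C": 39.969,
    "pressure_unit": "kPa",
    "form": "ln",
    "source": "study fit"
  },
  "B_ref": -0.00181,
  "T_ref": 325,
  "cubic_params": {
    "PRM": {
      "p1": -0.256223,
      "c_over_b": 0.039731
    },
    "PRSV": {
      "kappa1": 0.166735,
      "c_over_b": 0.039468
    }
  },
  "saft_params": {
    "m": 3.249,
    "v00": 0.012,
    "u0_over_k": 202.94,
    "e_over_k": 10,
    "kappa_AB": 0.021,
    "eps_AB_over_k": 2670,
    "scheme": "2B"
  }
}
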