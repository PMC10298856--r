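{
  "name": "1,8-cineole",
  "molar_mass": 154.25,
  "Tc": 661.12,
  "Pc": 3.019,
  "omega": 0.338,
  "Tb": 449.6,
  "molar_volume_table": [
    {
      "T_K": 278.15,
      "V0_m3mol": 0.0001646
    },
    {
      "T_K": 283.15,
      "V0_m3mol": 0.0001653
    },
    {
      "T_K": 288.15,
      "V0_m3mol": 0.0001661
    },
    {
      "T_K": 293.15,
      "V0_m3mol": 0.0001669
    },
    {
      "T_K": 298.15,
      "V0_m3mol": 0.0001677
    },
    {
      "T_K": 303.15,
      "V0_m3mol": 0.0001685
    },
    {
      "T_K": 308.15,
      "V0_m3mol": 0.0001692
    },
    {
      "T_K": 313.15,
      "V0_m3mol": 0.00017
    },
    {
      "T_K": 318.15,
      "V0_m3mol": 0.0001709
    },
    {
      "T_K": 323.15,
      "V0_m3mol": 0.0001717
    }
  ],
  "antoine": {
    "A": 18.578153147329,
    "B": 6287.27353603314,
    "C": -16.9963701663924,
    "pressure_unit": "kPa",
    "form": "ln",
    "source": "refit from bundled pure-pressure table"
  },
  "B_ref": -0.00549,
  "T_ref": 325,
  "cubic_params": {
    "PRM": {
      "p1": -0.003518,
      "c_over_b": -0.086491
    },
    "PRSV": {
      "kappa1": 0.007355,
      "c_over_b": -0.086427
    }
  },
  "saft_params": {
    "m": 4.842,
    "v00": 0.0178,
    "u0_over_k": 263.43,
    "e_over_k": 10,
    "kappa_AB": 0,
    "eps_AB_over_k": 0,
    "scheme": "none"
  }
}
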