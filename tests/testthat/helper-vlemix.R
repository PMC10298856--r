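## shared fixtures for the test suite (everything built in code or from the
## bundled plain-text tables)

ipa <- component("2-propanol")
cin <- component("1,8-cineole")

propanol_pressures <- function() {
  pd <- pure_liquid_data()
  data.frame(T_K = pd$T_K, P_Pa = pd$P0_Pa_1)
}

cineole_pressures <- function() {
  pd <- pure_liquid_data()
  data.frame(T_K = pd$T_K, P_Pa = pd$P0_Pa_2)
}

# pure inputs + virials for a given tabulated temperature
study_pure_inputs <- function(T_K) {
  pd <- pure_liquid_data()
  i <- which(pd$T_K == T_K)
  list(P1 = pd$P0_Pa_1[i], P2 = pd$P0_Pa_2[i],
       V1 = pd$V0_cm3mol_1[i] * 1e-6, V2 = pd$V0_cm3mol_2[i] * 1e-6)
}

study_virials <- function() {
  vc <- virial_cross(ipa$B_ref, cin$B_ref)
  list(B11 = ipa$B_ref, B22 = cin$B_ref, B12 = vc$B12)
}

isotherm <- function(T) dplyr::filter(vle_data(), T_K == T)
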