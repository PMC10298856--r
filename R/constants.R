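# Physical constants and universal model constants (SI units internally:
# Pa, K, m^3/mol, J/mol).

R_GAS <- 8.314462618 # J mol^-1 K^-1

# Peng-Robinson family
PR_OMEGA_A <- 0.457235
PR_OMEGA_B <- 0.077796

# SAFT close-packing / reduced-density constant
SAFT_TAU <- 0.74048

# Chen-Kreglewski universal dispersion constants D_ij, as tabulated for the
# square-well segment dispersion series of the original (Huang-Radosz form)
# SAFT: a_disp/RT = m * sum_ij D_ij (u/kT)^i (eta/tau)^j.
SAFT_DISPERSION <- local({
  D <- matrix(0, 4, 9)
  D[1, 1:6] <- c(-8.8043, 4.164627, -48.203555, 140.4362, -195.23339, 113.515)
  D[2, 1:9] <- c(2.9396, -6.0865383, 40.137956, -76.230797, -133.70055,
                 860.25349, -1535.3224, 1221.4261, -409.10539)
  D[3, 1:5] <- c(-2.8225, 4.7600148, 11.257177, -66.382743, 69.248785)
  D[4, 1:4] <- c(0.34, -3.1875014, 12.231796, -12.110681)
  D
})
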