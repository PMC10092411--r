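# Physical constants and unit conversions, centralized so that every
# module uses one consistent bookkeeping. Internal units: wavelengths in
# nm, distances in nm, molar absorptivity in M^-1 cm^-1, times in ps
# (trajectories) or ns (fluorescence decays).

#' @keywords internal
.AVOGADRO <- 6.02214076e23

# Prefactor of the sixth power of the Forster radius,
#   R0^6 = C * kappa2 * PhiD0 * J / n^4,
# with J in nm^4 M^-1 cm^-1 and R0 in nm. Derived from
# 9000 ln(10) / (128 pi^5 N_A) together with the unit conversion
# M^-1 cm^-1 nm^4 -> nm^6 mol^-1; equals the familiar closed form
# R0^6[A^6] = 8.79e-5 kappa2 n^-4 Phi J up to the A^6/nm^6 factor.
.FORSTER_PREFACTOR_NM6 <- 9000 * log(10) / (128 * pi^5 * .AVOGADRO) * 1e14
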