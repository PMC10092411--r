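# Shared test utilities.

# Plain Rand index between two labelings (fraction of point pairs on
# which the clusterings agree).
rand_index <- function(a, b) {
  ta <- table(a, b)
  n <- length(a)
  (choose(n, 2) + 2 * sum(choose(ta, 2)) -
      sum(choose(rowSums(ta), 2)) - sum(choose(colSums(ta), 2))) /
    choose(n, 2)
}

# Random unit vectors (isotropic), n x 3.
random_unit_vectors <- function(n) {
  z <- stats::runif(n, -1, 1)
  a <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(a), s * sin(a), z)
}

# The documented photokinetic reference parameter set used across the
# photoswitching tests (DCM-like E band, UV-shifted Z band).
reference_kinetics <- function(p_homo = 0.5, p_hetero = 0.6) {
  grid <- seq(300, 600, 1)
  kinetic_params(
    eps_E = gaussian_spectrum(457, 90, 48700, grid),
    eps_Z = gaussian_spectrum(390, 100, 20000, grid),
    Phi_EZ = 0.03, Phi_ZE = 0.50,
    p_homo = p_homo, p_hetero = p_hetero)
}
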