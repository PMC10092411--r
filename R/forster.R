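# Forster-theory core: overlap integral, Forster radius, transfer
# efficiency, orientation factor, steady-state anisotropy relations, and
# reconstruction of the Z-isomer absorptivity from photostationary data.

#' Spectral overlap integral J
#'
#' Computes the donor-acceptor spectral overlap
#' \deqn{J = \int \bar F_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\, d\lambda}
#' with the donor emission area-normalized
#' (\eqn{\int \bar F_D d\lambda = 1}). Quadrature is trapezoidal on the
#' union of both wavelength grids with linear interpolation; spectra are
#' taken as zero outside their measured window, so disjoint spectra give
#' J = 0.
#'
#' @param donor_em donor emission [spectrum()].
#' @param acceptor_abs acceptor absorption [spectrum()] in M^-1 cm^-1.
#' @return J in nm^4 M^-1 cm^-1 (scalar, >= 0).
#' @export
overlap_integral <- function(donor_em, acceptor_abs) {
  if (!inherits(donor_em, "spectrum") || !inherits(acceptor_abs, "spectrum"))
    stop("inputs must be spectrum objects")
  area <- trapz(donor_em$wavelength_nm, donor_em$value)
  if (area <= 0) stop("donor emission spectrum has zero area")
  grid <- sort(unique(c(donor_em$wavelength_nm, acceptor_abs$wavelength_nm)))
  fd <- interp_spectrum(donor_em, grid) / area
  ea <- interp_spectrum(acceptor_abs, grid)
  trapz(grid, fd * ea * grid^4)
}

#' Forster radius from photophysical parameters
#'
#' \deqn{R_0^6 = \frac{9000 \ln 10\, \kappa^2 \Phi_D^0}{128 \pi^5 N_A n^4} J}
#' with unit bookkeeping such that J in nm^4 M^-1 cm^-1 gives R0 in nm
#' (equivalently R0^6 in Angstrom^6 = 8.79e-5 kappa2 n^-4 PhiD0 J).
#'
#' @param J overlap integral, nm^4 M^-1 cm^-1.
#' @param kappa2 orientation factor in \[0, 4\] (2/3 for the isotropic
#'   dynamic average).
#' @param phiD0 donor fluorescence quantum yield in absence of transfer.
#' @param n refractive index of the medium.
#' @return R0 in nm.
#' @examples
#' forster_radius(1.03e13, 2 / 3, 0.25, 1.407) # ~1.84 nm
#' @export
forster_radius <- function(J, kappa2, phiD0, n) {
  if (any(c(J, kappa2, phiD0) < 0)) stop("J, kappa2 and phiD0 must be >= 0")
  if (n <= 0) stop("refractive index must be > 0")
  (.FORSTER_PREFACTOR_NM6 * kappa2 * phiD0 * J / n^4)^(1 / 6)
}

#' FRET efficiency at a given donor-acceptor distance
#'
#' \deqn{E = \frac{1}{1 + (R_{DA}/R_0)^6}}
#'
#' Vectorized over `R_DA` (and `R0`). `R_DA = 0` with `R0 > 0` returns
#' the limit 1; `R0 = 0` returns 0.
#'
#' @param R_DA donor-acceptor distance, nm.
#' @param R0 Forster radius, nm.
#' @return efficiency in \[0, 1\].
#' @export
fret_efficiency <- function(R_DA, R0) {
  if (any(R_DA < 0) || any(R0 < 0)) stop("distances must be >= 0")
  n <- max(length(R_DA), length(R0))
  R_DA <- rep_len(R_DA, n)
  R0 <- rep_len(R0, n)
  out <- numeric(n)
  pos <- R0 > 0
  out[pos] <- 1 / (1 + (R_DA[pos] / R0[pos])^6)
  out[pos & R_DA == 0] <- 1
  out
}

#' Orientation factor from the three Forster angles
#'
#' \deqn{\kappa^2 = (\sin\theta_D \sin\theta_A \cos\phi
#'   - 2 \cos\theta_D \cos\theta_A)^2}
#' where theta_D and theta_A are the angles between each transition
#' dipole and the separation vector, and phi the dihedral between the
#' two dipole-separation planes.
#'
#' @param theta_D,theta_A angles in radians.
#' @param phi dihedral angle in radians.
#' @return kappa^2 in \[0, 4\]; vectorized.
#' @export
kappa_squared_angles <- function(theta_D, theta_A, phi) {
  (sin(theta_D) * sin(theta_A) * cos(phi) -
     2 * cos(theta_D) * cos(theta_A))^2
}

#' Orientation factor from dipole and separation vectors
#'
#' \eqn{\kappa = \hat\mu_D\cdot\hat\mu_A -
#' 3(\hat\mu_D\cdot\hat R)(\hat\mu_A\cdot\hat R)}. Also extracts the
#' geometric angles (theta_D, theta_A, phi); the angle route reproduces
#' the vector route to machine precision. When a dipole is parallel to
#' the separation vector the dihedral is undefined and reported as 0 by
#' convention (kappa^2 is unaffected).
#'
#' @param mu_D,mu_A donor / acceptor transition dipole vectors (any
#'   nonzero length; normalized internally).
#' @param R_vec separation vector from donor to acceptor (nonzero).
#' @return list with `kappa2` and `geometry` (a one-row data frame with
#'   `R_DA`, `theta_D`, `theta_A`, `phi`, `kappa2`).
#' @export
kappa_squared_vectors <- function(mu_D, mu_A, R_vec) {
  d <- unit_vector(mu_D)
  a <- unit_vector(mu_A)
  R <- unit_vector(R_vec)
  kap <- sum(d * a) - 3 * sum(d * R) * sum(a * R)
  theta_D <- acos(pmin(1, pmax(-1, sum(d * R))))
  theta_A <- acos(pmin(1, pmax(-1, sum(a * R))))
  # dihedral between the (R, mu_D) and (R, mu_A) planes, right-handed
  # about R; kappa^2 depends on phi only through cos(phi)
  dp <- d - sum(d * R) * R
  ap <- a - sum(a * R) * R
  if (vec_norm(dp) < 1e-12 || vec_norm(ap) < 1e-12) {
    phi <- 0
  } else {
    dp <- unit_vector(dp)
    ap <- unit_vector(ap)
    cr <- c(dp[2] * ap[3] - dp[3] * ap[2],
            dp[3] * ap[1] - dp[1] * ap[3],
            dp[1] * ap[2] - dp[2] * ap[1])
    phi <- atan2(sum(cr * R), sum(dp * ap))
  }
  geom <- data.frame(R_DA = vec_norm(R_vec), theta_D = theta_D,
                     theta_A = theta_A, phi = phi, kappa2 = kap^2)
  list(kappa2 = kap^2, geometry = geom)
}

#' Fundamental (limiting) fluorescence anisotropy
#'
#' For one-photon excitation, \eqn{r_0 = 0.4\,(3\cos^2\beta - 1)/2}
#' where beta is the angle between the absorption and emission
#' transition dipole moments. beta = 0 gives the theoretical maximum
#' 0.4; beta ~ 15 deg (near-collinear dipoles of a DCM-type push-pull
#' dye) gives 0.36; the magic angle 54.7 deg gives 0.
#'
#' @param beta angle in degrees, in \[0, 90\].
#' @return r0, dimensionless.
#' @export
fundamental_anisotropy <- function(beta) {
  if (any(beta < 0) || any(beta > 90)) stop("beta must be in [0, 90] degrees")
  0.4 * (3 * cos(beta * pi / 180)^2 - 1) / 2
}

#' Anisotropy of a mixture of direct and post-transfer emission
#'
#' Homo-FRET hops depolarize: photons emitted after at least one
#' transfer carry a low residual anisotropy `r_et` (near-random
#' orientation after a hop), so the observed steady-state anisotropy is
#' the probability mixture
#' \deqn{\bar r = (1 - p)\, r_0 + p\, r_{et}.}
#'
#' @param r0 anisotropy of directly emitted photons.
#' @param p_transfer probability in \[0, 1\] that the detected photon
#'   followed at least one homo-transfer hop.
#' @param r_et post-transfer anisotropy (default 0.016).
#' @return mixture anisotropy.
#' @export
mixed_anisotropy <- function(r0, p_transfer, r_et = 0.016) {
  if (any(p_transfer < 0) || any(p_transfer > 1))
    stop("p_transfer must be in [0, 1]")
  (1 - p_transfer) * r0 + p_transfer * r_et
}

#' Z-isomer absorptivity from a photostationary-state spectrum
#'
#' Given the pure E-isomer absorptivity, the absorbance spectrum of a
#' photostationary mixture with known Z fraction `alpha_Z`, and the
#' Beer-Lambert parameters, inverts the two-component mixture:
#' \deqn{\varepsilon_Z(\lambda) = \frac{A_{PSS}(\lambda)/(c\,l) -
#'   (1-\alpha_Z)\,\varepsilon_E(\lambda)}{\alpha_Z}.}
#' Negative values (measurement noise) are clipped to 0 with a warning.
#'
#' @param eps_E E-isomer absorptivity [spectrum()].
#' @param A_pss photostationary absorbance [spectrum()] (same grid or
#'   overlapping; interpolated onto the `eps_E` grid).
#' @param alpha_Z Z-isomer mole fraction at the PSS, in (0, 1].
#' @param c_mol total chromophore concentration, mol L^-1.
#' @param l path length, cm.
#' @return Z-isomer absorptivity [spectrum()] on the `eps_E` grid.
#' @export
z_epsilon_from_pss <- function(eps_E, A_pss, alpha_Z, c_mol, l) {
  if (alpha_Z <= 0 || alpha_Z > 1) stop("alpha_Z must be in (0, 1]")
  if (c_mol <= 0 || l <= 0) stop("concentration and path length must be > 0")
  grid <- eps_E$wavelength_nm
  a <- interp_spectrum(A_pss, grid)
  ez <- (a / (c_mol * l) - (1 - alpha_Z) * eps_E$value) / alpha_Z
  if (any(ez < 0)) {
    warning("negative reconstructed absorptivity clipped to 0 (",
            sum(ez < 0), " grid points)")
    ez <- pmax(ez, 0)
  }
  spectrum(grid, ez, kind = "absorption")
}

#' Bundle the photophysical parameters of a FRET pair
#'
#' @param J overlap integral, nm^4 M^-1 cm^-1.
#' @param kappa2 fixed orientation factor, or the string `"dynamic"` to
#'   use the per-frame instantaneous kappa^2 in trajectory analyses.
#' @param phiD0 donor quantum yield without transfer.
#' @param n refractive index.
#' @return object of class `forster_pair_params`; for fixed kappa2 the
#'   derived `R0` (nm) is included.
#' @export
forster_pair_params <- function(J, kappa2 = "dynamic", phiD0, n) {
  dynamic <- identical(kappa2, "dynamic")
  if (!dynamic) {
    stopifnot_scalar(kappa2)
    if (kappa2 < 0 || kappa2 > 4) stop("kappa2 must be in [0, 4]")
  }
  out <- list(J = J, kappa2 = if (dynamic) "dynamic" else kappa2,
              phiD0 = phiD0, n = n,
              R0 = if (dynamic) NA_real_ else
                forster_radius(J, kappa2, phiD0, n))
  class(out) <- "forster_pair_params"
  out
}

#' @export
print.forster_pair_params <- function(x, ...) {
  cat(sprintf(
    "<forster_pair_params: J = %.4g nm^4/(M cm), kappa2 = %s, PhiD0 = %.3g, n = %.4g%s>\n",
    x$J, if (identical(x$kappa2, "dynamic")) "dynamic" else
      sprintf("%.4g", x$kappa2),
    x$phiD0, x$n,
    if (is.na(x$R0)) "" else sprintf(", R0 = %.3f nm", x$R0)
  ))
  invisible(x)
}
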