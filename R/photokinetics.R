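# Mechanistic model of competitive E/Z photoisomerization coupled to
# intramolecular FRET in systems of 1-3 identical chromophore units.
#
# Two layers:
#   (i)  per absorbed photon, the excitation wanders between units as
#        an absorbing Markov chain (homo/hetero-FRET hops) until it is
#        lost to isomerization or photophysical decay;
#   (ii) at the species level (one species per isomer configuration,
#        e.g. EE, EZ, ZZ), excitation events arrive proportionally to
#        the unit absorptivities, and each photon's fate from (i)
#        flips at most one unit, giving linear first-order kinetics in
#        the species concentrations.

#' Photokinetic parameters
#'
#' @param eps_E,eps_Z absorptivity [spectrum()] of the E and Z isomer
#'   of one chromophore unit, M^-1 cm^-1.
#' @param Phi_EZ,Phi_ZE isomerization quantum yields (excited E -> Z,
#'   excited Z -> E) in the absence of transfer.
#' @param p_homo per-excitation transfer probability from an excited E
#'   unit to another E unit (homo-FRET hop).
#' @param p_hetero per-excitation transfer probability from an excited
#'   E unit to a Z unit (hetero-FRET quench path).
#' @param flux photon flux scale (excitation events per second per
#'   unit absorptivity; sets the overall time unit).
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(eps_E, eps_Z, Phi_EZ, Phi_ZE,
                           p_homo = 0, p_hetero = 0, flux = 1e-6) {
  for (q in c(Phi_EZ, Phi_ZE, p_homo, p_hetero))
    if (q < 0 || q > 1) stop("quantum yields and transfer probabilities must be in [0, 1]")
  structure(list(eps_E = eps_E, eps_Z = eps_Z, Phi_EZ = Phi_EZ,
                 Phi_ZE = Phi_ZE, p_homo = p_homo, p_hetero = p_hetero,
                 flux = flux),
            class = "kinetic_params")
}

eps_at <- function(sp, lambda) interp_spectrum(sp, lambda)

# Per-pair transfer probability matrix for a configuration (vector of
# "E"/"Z"): excited Z units do not transfer (dark, no donor emission);
# excited E units hop to E with pairwise probability p_homo and to Z
# with p_hetero. Pairwise probabilities are defined against the local
# outcomes of a lone donor-acceptor pair; with several acceptors the
# channels compete as rates, i.e. per-pair odds o = p/(1-p) renormalized
# to E_uj = o_j / (1 + sum_k o_k). A single acceptor recovers E = p
# exactly, and the total transfer probability is always < 1 so the
# excitation chain is absorbing.
config_fret_matrix <- function(config, params) {
  n <- length(config)
  M <- matrix(0, n, n)
  if (n == 1L) return(M)
  for (u in seq_len(n)) {
    if (config[u] != "E") next
    p <- vapply(seq_len(n), function(v) {
      if (v == u) 0 else if (config[v] == "E") params$p_homo
      else params$p_hetero
    }, numeric(1))
    if (any(p >= 1)) stop("pairwise transfer probabilities must be < 1")
    odds <- p / (1 - p)
    M[u, ] <- odds / (1 + sum(odds))
  }
  M
}

#' Fate of one excitation in a multichromophoric configuration
#'
#' Solves the absorbing Markov chain of the wandering excitation
#' exactly via the fundamental matrix (I - Q)^-1 R. At each visited
#' unit the outcomes compete as probabilities summing to one: transfer
#' to neighbour j with probability E_uj, and with the residual
#' probability the excitation stays local and either isomerizes (with
#' the resident isomer's quantum yield) or decays.
#'
#' @param config character vector over {"E", "Z"}, length 1-3.
#' @param params [kinetic_params()].
#' @param excited_unit index of the initially excited unit.
#' @param fret_matrix optional explicit per-pair transfer probability
#'   matrix overriding the `p_homo`/`p_hetero` construction.
#' @return named numeric vector: `isomerize_1..n` (probability that
#'   unit u flips) and `decay`; sums to 1.
#' @export
excitation_fate <- function(config, params, excited_unit,
                            fret_matrix = NULL) {
  n <- length(config)
  if (excited_unit < 1L || excited_unit > n) stop("invalid excited unit")
  Q <- fret_matrix %||% config_fret_matrix(config, params)
  if (any(rowSums(Q) > 1 + 1e-12)) stop("transfer probabilities exceed 1")
  phi <- ifelse(config == "E", params$Phi_EZ, params$Phi_ZE)
  local <- 1 - rowSums(Q)
  R <- cbind(diag(local * phi, n), decay = local * (1 - phi))
  fate <- solve(diag(n) - Q, R)[excited_unit, ]
  names(fate) <- c(paste0("isomerize_", seq_len(n)), "decay")
  if (abs(sum(fate) - 1) > 1e-12)
    stop("excitation fate probabilities do not sum to 1")
  fate
}

all_configs <- function(n) {
  grid <- do.call(expand.grid,
                  c(rep(list(c("E", "Z")), n), stringsAsFactors = FALSE))
  lapply(seq_len(nrow(grid)), function(i) as.character(unlist(grid[i, ])))
}

#' Species-level kinetics generator under irradiation
#'
#' Builds the 2^n-species first-order generator G (columns sum to
#' zero) such that dc/dt = G c: each species is excited at each unit
#' at a rate proportional to that unit's isomer absorptivity at the
#' irradiation wavelength, and the excitation's fate
#' ([excitation_fate()]) flips at most one unit.
#'
#' @param n_units 1, 2 or 3.
#' @param params [kinetic_params()].
#' @param lambda_irr irradiation wavelength, nm.
#' @return object of class `photo_system`: `generator` (2^n x 2^n),
#'   `configs` (list of configuration vectors), `labels` (collapsed
#'   strings such as "EZ"), `params`, `lambda_irr`.
#' @export
build_rate_matrix <- function(n_units, params, lambda_irr) {
  if (!n_units %in% 1:3) stop("n_units must be 1, 2 or 3")
  cfgs <- all_configs(n_units)
  labels <- vapply(cfgs, paste0, "", collapse = "")
  ns <- length(cfgs)
  epsE <- eps_at(params$eps_E, lambda_irr)
  epsZ <- eps_at(params$eps_Z, lambda_irr)
  G <- matrix(0, ns, ns, dimnames = list(labels, labels))
  for (s in seq_len(ns)) {
    cfg <- cfgs[[s]]
    for (u in seq_len(n_units)) {
      k_exc <- params$flux * if (cfg[u] == "E") epsE else epsZ
      if (k_exc == 0) next
      fate <- excitation_fate(cfg, params, u)
      for (v in seq_len(n_units)) {
        p_flip <- fate[[paste0("isomerize_", v)]]
        if (p_flip <= 0) next
        cfg2 <- cfg
        cfg2[v] <- if (cfg2[v] == "E") "Z" else "E"
        s2 <- match(paste0(cfg2, collapse = ""), labels)
        G[s2, s] <- G[s2, s] + k_exc * p_flip
        G[s, s] <- G[s, s] - k_exc * p_flip
      }
    }
  }
  structure(list(generator = G, configs = cfgs, labels = labels,
                 params = params, lambda_irr = lambda_irr,
                 n_units = n_units),
            class = "photo_system")
}

# Species absorptivity at a wavelength: weak-coupling additivity over
# units.
species_epsilon <- function(system, lambda) {
  epsE <- eps_at(system$params$eps_E, lambda)
  epsZ <- eps_at(system$params$eps_Z, lambda)
  vapply(system$configs,
         function(cfg) sum(ifelse(cfg == "E", epsE, epsZ)), numeric(1))
}

#' Simulate an irradiation schedule
#'
#' Integrates the linear species kinetics dc/dt = G c through a
#' sequence of irradiation segments (wavelength, flux scale, duration)
#' by matrix exponentials, and reports the probe-wavelength absorbance
#' trace via Beer-Lambert additivity.
#'
#' @param initial named concentrations (mol L^-1) over the species
#'   labels of `n_units` (missing species = 0), or a single number
#'   interpreted as the all-E species concentration.
#' @param params [kinetic_params()].
#' @param schedule data frame with columns `lambda_nm`, `flux_scale`
#'   (multiplier on `params$flux`; 0 = dark), `duration_s`.
#' @param n_units number of chromophore units.
#' @param probe_nm probe wavelength for the absorbance trace.
#' @param path_cm optical path length.
#' @param n_out output samples per segment.
#' @return object of class `absorbance_trace`: data frame `time_s`,
#'   `absorbance`, plus attributes `species` (concentration matrix) and
#'   `labels`.
#' @export
simulate_irradiation <- function(initial, params, schedule, n_units,
                                 probe_nm = 457, path_cm = 1,
                                 n_out = 200L) {
  sys0 <- build_rate_matrix(n_units, params, schedule$lambda_nm[1])
  labels <- sys0$labels
  c0 <- numeric(length(labels))
  names(c0) <- labels
  if (length(initial) == 1L && is.null(names(initial))) {
    c0[paste(rep("E", n_units), collapse = "")] <- initial
  } else {
    c0[names(initial)] <- unlist(initial)
  }
  total0 <- sum(c0)
  times <- numeric(0)
  conc <- NULL
  t0 <- 0
  cc <- c0
  for (seg in seq_len(nrow(schedule))) {
    sys <- build_rate_matrix(n_units, params, schedule$lambda_nm[seg])
    G <- sys$generator * schedule$flux_scale[seg]
    tt <- seq(0, schedule$duration_s[seg], length.out = n_out + 1L)[-1]
    # eigen-decomposition once per segment; G is small (<= 8 x 8)
    for (ti in tt) {
      ci <- as.numeric(Matrix::expm(G * ti) %*% cc)
      times <- c(times, t0 + ti)
      conc <- rbind(conc, ci)
    }
    cc <- conc[nrow(conc), ]
    if (min(cc) < -1e-9 * total0)
      stop("integrator produced negative concentrations")
    cc <- pmax(cc, 0)
    t0 <- t0 + schedule$duration_s[seg]
  }
  if (abs(sum(cc) - total0) > 1e-9 * max(total0, 1))
    stop("chromophore mass not conserved")
  eps_probe <- species_epsilon(sys0, probe_nm)
  A <- as.numeric(conc %*% eps_probe) * path_cm
  out <- data.frame(time_s = times, absorbance = A)
  attr(out, "species") <- conc
  attr(out, "labels") <- labels
  attr(out, "probe_nm") <- probe_nm
  class(out) <- c("absorbance_trace", "data.frame")
  out
}

#' Photostationary composition
#'
#' Stationary species distribution of a kinetics generator (null-space
#' solve), normalized to the supplied total concentration.
#'
#' @param system `photo_system` from [build_rate_matrix()].
#' @param total total species concentration (default 1).
#' @return named concentration vector at the PSS.
#' @export
pss_composition <- function(system, total = 1) {
  G <- system$generator
  ns <- nrow(G)
  # solve G x = 0 with sum(x) = total via a bordered system
  A <- rbind(G, rep(1, ns))
  b <- c(numeric(ns), total)
  x <- qr.solve(A, b)
  x[abs(x) < 1e-14] <- 0
  if (any(x < -1e-10)) stop("non-physical stationary state")
  stats::setNames(pmax(x, 0), system$labels)
}

#' Ratio of probe absorbances at two photostationary states
#'
#' Drives the system to the PSS under irradiation at `lambda_1` and at
#' `lambda_2` and returns A_PSS(lambda_1)/A_PSS(lambda_2) measured at
#' the probe wavelength. For a single photoswitch this is the familiar
#' photochromic conversion ratio; FRET coupling in multichromophoric
#' systems pushes it toward 1.
#'
#' @param params [kinetic_params()].
#' @param n_units number of units.
#' @param lambda_1,lambda_2 irradiation wavelengths, nm.
#' @param probe_nm probe wavelength, nm.
#' @return scalar ratio.
#' @export
pss_ratio <- function(params, n_units, lambda_1 = 485, lambda_2 = 335,
                      probe_nm = 457) {
  one <- function(lam) {
    sys <- build_rate_matrix(n_units, params, lam)
    cs <- pss_composition(sys)
    sum(cs * species_epsilon(sys, probe_nm))
  }
  one(lambda_1) / one(lambda_2)
}

#' Time to reach the photostationary state
#'
#' First time after which the absorbance stays within
#' `tolerance * |A(0) - A(inf)|` of its final value.
#'
#' @param trace `absorbance_trace`.
#' @param tolerance relative tolerance (default 0.05).
#' @return time in s, or `NA` if the trace never settles.
#' @export
time_to_pss <- function(trace, tolerance = 0.05) {
  A <- trace$absorbance
  Ainf <- A[length(A)]
  span <- abs(A[1] - Ainf)
  if (span == 0) return(NA_real_)
  ok <- abs(A - Ainf) <= tolerance * span
  # require the condition to hold from some index onwards
  idx <- which(rev(cumprod(rev(ok))) == 1)
  if (length(idx) == 0) return(NA_real_)
  trace$time_s[idx[1]]
}
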