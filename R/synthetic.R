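# Ground-truth generator for metastable conformational dynamics of a
# two-chromophore tether. A hidden Markov chain visits conformational
# states; each state emits an interchromophoric distance (log-normal)
# and dipole orientations (mean Forster angles with Gaussian angular
# spread), from which full geometry frames are constructed. All
# planted quantities (state path, relaxation timescales, per-state
# efficiency expectations) are retained so downstream analyses can be
# validated against known truth.

#' Define a conformational state of the tether
#'
#' @param name state label.
#' @param R_median median interchromophoric distance, nm (log-normal
#'   emission).
#' @param R_sdlog log-scale standard deviation of the distance.
#' @param theta_D,theta_A,phi mean Forster angles, radians.
#' @param angle_sd angular spread (Gaussian s.d., radians) around the
#'   mean angles; large values approach isotropic orientations.
#' @return a `tether_state` list.
#' @export
tether_state <- function(name, R_median, R_sdlog = 0.1,
                         theta_D = pi / 2, theta_A = pi / 2, phi = 0,
                         angle_sd = 0.3) {
  if (R_median <= 0 || R_sdlog < 0) stop("invalid distance distribution")
  structure(list(name = name, R_median = R_median, R_sdlog = R_sdlog,
                 theta_D = theta_D, theta_A = theta_A, phi = phi,
                 angle_sd = angle_sd),
            class = "tether_state")
}

#' Scenario specification for the synthetic dynamics
#'
#' @param states list of [tether_state()].
#' @param P per-step jump-probability matrix between states (rows sum
#'   to 1).
#' @param dt_ps frame spacing, ps (default 5, a typical trajectory
#'   write-out cadence).
#' @param seed RNG seed recorded with the scenario.
#' @return object of class `scenario_spec`; includes the stationary
#'   occupancy of `P` and the planted relaxation timescales
#'   `-dt/log(lambda_i)` (ps).
#' @export
scenario_spec <- function(states, P, dt_ps = 5, seed = 1L) {
  P <- as.matrix(P)
  ns <- length(states)
  if (!all(dim(P) == c(ns, ns))) stop("P must be n_states x n_states")
  if (any(abs(rowSums(P) - 1) > 1e-10)) stop("rows of P must sum to 1")
  if (any(P < 0)) stop("jump probabilities must be >= 0")
  lambda <- sort(abs(eigen(P)$values), decreasing = TRUE)
  ts <- -dt_ps / log(pmin(lambda[-1], 1 - 1e-15))
  occ <- stationary_distribution(P)
  structure(list(states = states, P = P, dt_ps = dt_ps, seed = seed,
                 occupancy = occ, relaxation_ps = ts),
            class = "scenario_spec")
}

# Sample a hidden Markov state path of length n from jump matrix P.
sample_state_path <- function(P, n, init = NULL) {
  ns <- nrow(P)
  path <- integer(n)
  prob0 <- init %||% stationary_distribution(P)
  path[1] <- sample.int(ns, 1L, prob = prob0)
  cum <- t(apply(P, 1, cumsum))
  u <- stats::runif(n)
  for (t in 2:n)
    path[t] <- findInterval(u[t], cum[path[t - 1L], ]) + 1L
  path
}

# Build dipoles realizing (theta_D, theta_A, phi) about separation
# direction u: mu = cos(theta) u + sin(theta)(cos(psi) e1 + sin(psi) e2)
# with psi_A - psi_D = phi.
dipoles_from_angles <- function(u, theta_D, theta_A, phi, psi_D) {
  b <- perp_basis(u)
  mk <- function(theta, psi)
    cos(theta) * u + sin(theta) * (cos(psi) * b$e1 + sin(psi) * b$e2)
  list(mu_D = mk(theta_D, psi_D), mu_A = mk(theta_A, psi_D + phi))
}

#' Simulate a synthetic two-chromophore trajectory
#'
#' @param spec [scenario_spec()].
#' @param n_frames number of frames (default 40000, i.e. 200 ns at the
#'   5 ps default cadence).
#' @return list with `frames` ([geometry_frames()]) and `truth`: the
#'   hidden `state_path`, the scenario `occupancy`, planted
#'   `relaxation_ps`, and the per-frame sampled angles.
#' @export
simulate_scenario <- function(spec, n_frames = 40000L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  set.seed(spec$seed)
  path <- sample_state_path(spec$P, n_frames)
  ns <- length(spec$states)
  Rmed <- vapply(spec$states, `[[`, 1, "R_median")
  Rsd <- vapply(spec$states, `[[`, 1, "R_sdlog")
  thD <- vapply(spec$states, `[[`, 1, "theta_D")
  thA <- vapply(spec$states, `[[`, 1, "theta_A")
  ph <- vapply(spec$states, `[[`, 1, "phi")
  asd <- vapply(spec$states, `[[`, 1, "angle_sd")
  R <- stats::rlnorm(n_frames, meanlog = log(Rmed[path]), sdlog = Rsd[path])
  theta_D <- clamp_angle(stats::rnorm(n_frames, thD[path], asd[path]))
  theta_A <- clamp_angle(stats::rnorm(n_frames, thA[path], asd[path]))
  phi <- wrap_angle(stats::rnorm(n_frames, ph[path], asd[path]))
  # random separation direction and donor azimuth per frame
  z <- stats::runif(n_frames, -1, 1)
  az <- stats::runif(n_frames, 0, 2 * pi)
  psi_D <- stats::runif(n_frames, 0, 2 * pi)
  refD <- matrix(0, n_frames, 3)
  refA <- matrix(0, n_frames, 3)
  muD <- matrix(0, n_frames, 3)
  muA <- matrix(0, n_frames, 3)
  s <- sqrt(1 - z^2)
  for (t in seq_len(n_frames)) {
    u <- c(s[t] * cos(az[t]), s[t] * sin(az[t]), z[t])
    refA[t, ] <- R[t] * u
    dp <- dipoles_from_angles(u, theta_D[t], theta_A[t], phi[t], psi_D[t])
    muD[t, ] <- dp$mu_D
    muA[t, ] <- dp$mu_A
  }
  frames <- geometry_frames((seq_len(n_frames) - 1L) * spec$dt_ps,
                            refD, refA, muD, muA)
  truth <- list(state_path = path, occupancy = spec$occupancy,
                relaxation_ps = spec$relaxation_ps,
                angles = data.frame(theta_D = theta_D, theta_A = theta_A,
                                    phi = phi),
                R_DA = R)
  list(frames = frames, truth = truth)
}

clamp_angle <- function(x) pmin(pmax(x, 0), pi)
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Theoretical per-state and mixture mean FRET efficiency
#'
#' Monte-Carlo expectation of the instantaneous efficiency under each
#' state's emission distribution (and the dynamic-kappa2 policy),
#' reported with its standard error, plus the occupancy-weighted
#' mixture expectation. Serves as the independent oracle for
#' trajectory-level mean efficiencies.
#'
#' @param spec [scenario_spec()].
#' @param params [forster_pair_params()].
#' @param n_draws Monte-Carlo draws per state.
#' @param seed RNG seed.
#' @return list: `per_state` (data frame with `mean`, `se`),
#'   `mixture_mean`, `mixture_se`.
#' @export
theoretical_mean_efficiency <- function(spec, params, n_draws = 1e6,
                                        seed = 7L) {
  set.seed(seed)
  per <- lapply(spec$states, function(st) {
    R <- stats::rlnorm(n_draws, log(st$R_median), st$R_sdlog)
    thD <- clamp_angle(stats::rnorm(n_draws, st$theta_D, st$angle_sd))
    thA <- clamp_angle(stats::rnorm(n_draws, st$theta_A, st$angle_sd))
    ph <- wrap_angle(stats::rnorm(n_draws, st$phi, st$angle_sd))
    k2 <- if (identical(params$kappa2, "dynamic"))
      kappa_squared_angles(thD, thA, ph) else params$kappa2
    R0 <- (.FORSTER_PREFACTOR_NM6 * k2 * params$phiD0 * params$J /
             params$n^4)^(1 / 6)
    e <- fret_efficiency(R, R0)
    c(mean = mean(e), se = stats::sd(e) / sqrt(n_draws))
  })
  tab <- as.data.frame(do.call(rbind, per))
  tab$state <- vapply(spec$states, `[[`, "", "name")
  occ <- spec$occupancy
  list(per_state = tab,
       mixture_mean = sum(occ * tab$mean),
       mixture_se = sqrt(sum((occ * tab$se)^2)))
}

#' Built-in scenario presets
#'
#' - `"two-state-minimal"`: folded (0.9 nm) / unfolded (2.5 nm) with
#'   occupancies near 0.7 / 0.3 and slow symmetric-rate exchange — the
#'   smallest scenario with a closed-form mixture oracle.
#' - `"EZ-like"`: four states emulating a hetero-pair tether with an
#'   unfolded, two folded and a compact rolled conformation (folded
#'   medians 0.8-1.0 nm, unfolded 2.5 nm).
#' - `"EE-like"`: as `"EZ-like"` but with higher folded occupancy.
#' - `"six-well"`: six well-separated states on a two-branch chain
#'   topology with one dominant source-to-sink pathway; used to
#'   validate the full MSM pipeline.
#'
#' @param preset preset name.
#' @param seed RNG seed stored in the scenario.
#' @return [scenario_spec()].
#' @export
scenario_preset <- function(preset = c("two-state-minimal", "EZ-like",
                                       "EE-like", "six-well"),
                            seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "two-state-minimal" = {
      # escape probabilities 0.006/0.014 give occupancy 0.7/0.3
      P <- matrix(c(0.994, 0.006,
                    0.014, 0.986), 2, 2, byrow = TRUE)
      scenario_spec(
        list(tether_state("folded", 0.9, 0.10, theta_D = 1.2,
                          theta_A = 1.0, phi = 0.5, angle_sd = 0.4),
             tether_state("unfolded", 2.5, 0.08, theta_D = 1.6,
                          theta_A = 1.6, phi = 1.5, angle_sd = 0.6)),
        P, seed = seed)
    },
    "EZ-like" = {
      P <- rbind(c(0.985, 0.007, 0.005, 0.003),
                 c(0.010, 0.980, 0.007, 0.003),
                 c(0.006, 0.006, 0.982, 0.006),
                 c(0.004, 0.003, 0.008, 0.985))
      scenario_spec(
        list(tether_state("unfolded-A", 2.5, 0.10, 1.6, 1.6, 1.5, 0.7),
             tether_state("folded-3", 1.0, 0.12, 1.1, 1.2, 0.4, 0.4),
             tether_state("folded-4", 0.8, 0.12, 0.9, 1.0, 0.3, 0.4),
             tether_state("rolled-B", 0.9, 0.10, 0.6, 0.7, 0.2, 0.3)),
        P, seed = seed)
    },
    "EE-like" = {
      P <- rbind(c(0.970, 0.012, 0.012, 0.006),
                 c(0.006, 0.985, 0.006, 0.003),
                 c(0.005, 0.005, 0.985, 0.005),
                 c(0.003, 0.003, 0.006, 0.988))
      scenario_spec(
        list(tether_state("unfolded-3", 2.4, 0.10, 1.6, 1.6, 1.5, 0.7),
             tether_state("single-folded-2", 1.0, 0.12, 1.1, 1.1, 0.4, 0.4),
             tether_state("single-folded-4", 0.9, 0.12, 1.0, 1.0, 0.3, 0.4),
             tether_state("rolled-B", 0.8, 0.10, 0.6, 0.6, 0.2, 0.3)),
        P, seed = seed)
    },
    "six-well" = {
      # chain topology 1 -> {2 (dominant), 3} -> {4, 5} -> 6 with a
      # strong main branch 1-2-4-6
      ns <- 6
      P <- diag(0.97, ns)
      hop <- function(i, j, p) P[i, j] <<- P[i, j] + p
      P[1, 1] <- 0.960; hop(1, 2, 0.030); hop(1, 3, 0.010)
      P[2, 2] <- 0.955; hop(2, 1, 0.015); hop(2, 4, 0.030)
      P[3, 3] <- 0.960; hop(3, 1, 0.025); hop(3, 5, 0.015)
      P[4, 4] <- 0.955; hop(4, 2, 0.015); hop(4, 6, 0.030)
      P[5, 5] <- 0.970; hop(5, 3, 0.020); hop(5, 6, 0.010)
      P[6, 6] <- 0.960; hop(6, 4, 0.030); hop(6, 5, 0.010)
      states <- list(
        tether_state("well-1", 2.8, 0.05, 1.60, 1.60, 1.5, 0.10),
        tether_state("well-2", 2.0, 0.05, 0.40, 1.60, 0.5, 0.10),
        tether_state("well-3", 2.0, 0.05, 2.70, 0.40, 2.5, 0.10),
        tether_state("well-4", 1.3, 0.05, 1.60, 0.40, 1.0, 0.10),
        tether_state("well-5", 1.3, 0.05, 0.40, 2.70, 2.0, 0.10),
        tether_state("well-6", 0.8, 0.05, 0.90, 0.90, 0.3, 0.10))
      scenario_spec(states, P, seed = seed)
    })
}

#' Write a reproducible synthetic fixture bundle
#'
#' Emits, under `outdir`: the geometry-table trajectory
#' (`trajectory.dat`), DCM-like donor-emission and acceptor-absorption
#' Gaussian spectra (`donor_em.csv`, `acceptor_abs.csv`; absorption max
#' 457 nm, emission max 590 nm), the ground truth (`truth.json`) and a
#' config (`config.json`) from which the bundle regenerates
#' bit-identically.
#'
#' @param outdir output directory (created if needed).
#' @param preset preset name, see [scenario_preset()].
#' @param n_frames trajectory length.
#' @param seed RNG seed.
#' @return invisible character vector of the written paths.
#' @export
write_fixture_bundle <- function(outdir, preset = "two-state-minimal",
                                 n_frames = 5000L, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- scenario_preset(preset, seed = seed)
  sim <- simulate_scenario(spec, n_frames)
  grid <- seq(350, 750, by = 1)
  don <- gaussian_spectrum(590, 70, 1, grid, kind = "emission")
  acc <- gaussian_spectrum(457, 90, 48700, grid, kind = "absorption")
  paths <- file.path(outdir, c("trajectory.dat", "donor_em.csv",
                               "acceptor_abs.csv", "truth.json",
                               "config.json"))
  write_geometry_table(sim$frames, paths[1])
  write_spectrum(don, paths[2])
  write_spectrum(acc, paths[3])
  jsonlite::write_json(
    list(state_path = sim$truth$state_path,
         occupancy = sim$truth$occupancy,
         relaxation_ps = sim$truth$relaxation_ps,
         state_names = vapply(spec$states, `[[`, "", "name")),
    paths[4], digits = NA)
  jsonlite::write_json(
    list(preset = preset, n_frames = n_frames, seed = seed),
    paths[5], auto_unbox = TRUE)
  invisible(paths)
}
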