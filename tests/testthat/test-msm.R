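test_that("tICA recovers the AR(1) autocorrelation and ignores white noise", {
  set.seed(21)
  n <- 1e5
  rho <- 0.9
  x <- as.numeric(stats::arima.sim(list(ar = rho), n))
  tm <- tica_fit(matrix(x, ncol = 1), lag = 1)
  expect_equal(tm$eigenvalues[1], rho, tolerance = 0.02)

  wn <- matrix(rnorm(2 * n), ncol = 2)
  tw <- tica_fit(wn, lag = 1)
  expect_true(all(abs(tw$eigenvalues) < 0.05))
})

test_that("tICA eigenvalues are rotation invariant and components whitened", {
  set.seed(22)
  n <- 2e4
  x <- cbind(as.numeric(arima.sim(list(ar = 0.8), n)),
             as.numeric(arima.sim(list(ar = 0.3), n)),
             rnorm(n))
  t1 <- tica_fit(x, lag = 2)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  t2 <- tica_fit(x %*% Q, lag = 2)
  expect_equal(t1$eigenvalues, t2$eigenvalues, tolerance = 1e-8)
  # instantaneous covariance of the projections is the identity
  y <- tica_transform(t1, x)
  C <- crossprod(sweep(y, 2, colMeans(y))) / (n - 1)
  expect_lt(max(abs(C - diag(3))), 0.01)
  expect_error(tica_fit(x[1:2, ], lag = 5), "lag")
})

test_that("k-means recovers planted blobs and is deterministic", {
  set.seed(23)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  lab_true <- rep(1:3, each = 300)
  pts <- centers[lab_true, ] + matrix(rnorm(1800, sd = 0.5), ncol = 2)
  cl <- cluster_kmeans(pts, 3, seed = 1)
  expect_gt(rand_index(cl$assignment, lab_true), 0.99)
  cl2 <- cluster_kmeans(pts, 3, seed = 1)
  expect_identical(cl$assignment, cl2$assignment)
  # k = n gives zero inertia
  small <- pts[1:10, ]
  cln <- cluster_kmeans(small, 10, seed = 2)
  expect_equal(cln$inertia, 0, tolerance = 1e-20)
  expect_error(cluster_kmeans(small, 11), "exceed")
})

test_that("MSM estimation reproduces a deterministic cycle and a two-state chain", {
  # deterministic cycle 1 -> 2 -> 3 -> 1
  cyc <- rep(1:3, 400)
  m <- estimate_msm(cyc, lag = 1)
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 3] <- P[3, 1] <- 1
  expect_equal(m$T, P, tolerance = 1e-12)
  expect_equal(m$pi, rep(1 / 3, 3), tolerance = 1e-9)

  # symmetric two-state chain, p = 0.05 each way
  set.seed(24)
  n <- 1e6
  flips <- cumsum(rbinom(n, 1, 0.05)) %% 2L
  dtraj <- flips + 1L
  m2 <- estimate_msm(dtraj, lag = 1)
  expect_lt(abs(m2$T[1, 2] - 0.05), 0.002)
  expect_lt(abs(m2$T[2, 1] - 0.05), 0.002)
  its <- -1 / log(abs(eigen(m2$T)$values[2]))
  expect_equal(its, -1 / log(0.9), tolerance = 0.05 * 9.49)
})

test_that("MSM invariants hold: row stochasticity, stationarity, detailed balance", {
  set.seed(25)
  # reversible synthetic chain from a random symmetric count structure
  k <- 5
  W <- matrix(runif(k * k), k); W <- W + t(W); diag(W) <- diag(W) + 5
  Ptrue <- W / rowSums(W)
  dtraj <- integer(5e4)
  dtraj[1] <- 1L
  cum <- t(apply(Ptrue, 1, cumsum))
  u <- runif(5e4)
  for (t in 2:5e4) dtraj[t] <- findInterval(u[t], cum[dtraj[t - 1], ]) + 1L
  for (rev in c(FALSE, TRUE)) {
    m <- estimate_msm(dtraj, lag = 1, reversible = rev)
    expect_equal(rowSums(m$T), rep(1, k), tolerance = 1e-10)
    expect_equal(as.numeric(m$pi %*% m$T), m$pi, tolerance = 1e-8)
    expect_true(all(m$pi >= 0))
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
    if (rev) {
      F <- m$pi * m$T
      expect_lt(max(abs(F - t(F))), 1e-6)
    }
  }
  # reversible and non-reversible agree on detailed-balance counts: draw
  # Poisson counts around a symmetric stationary flux so every entry is
  # deeply sampled, then compare the two estimators entry-wise
  piv <- fretdyn:::stationary_distribution(Ptrue)
  Fexp <- 1e7 * piv * Ptrue
  C <- matrix(rpois(k * k, Fexp), k)
  Tn <- C / rowSums(C)
  Tr <- fretdyn:::reversible_mle(C)
  expect_lt(max(abs(Tn - Tr) / Tn), 0.005)
})

test_that("disconnected trajectories are restricted to the main component", {
  dtraj <- c(rep(1:2, 500), rep(4L, 20))  # state 4 unreachable back
  expect_warning(m <- estimate_msm(dtraj, lag = 1), "retained")
  expect_true(all(m$active_set %in% 1:2))
})

test_that("implied timescales are lag-independent for Markovian chains
           and flag non-Markovian and i.i.d. sequences", {
  set.seed(26)
  # exactly Markovian two-state chain
  n <- 2e5
  flips <- cumsum(rbinom(n, 1, 0.02)) %% 2L
  its <- implied_timescales(flips + 1L, lags = c(1, 2, 5, 10),
                            n_timescales = 1)
  t_ref <- its$timescale[its$lag == 1]
  expect_true(all(abs(its$timescale - t_ref) / t_ref < 0.05))

  # two-timescale planted model: 4 states, nested block structure
  P <- rbind(c(0.94, 0.05, 0.009, 0.001),
             c(0.05, 0.94, 0.001, 0.009),
             c(0.009, 0.001, 0.94, 0.05),
             c(0.001, 0.009, 0.05, 0.94))
  ev <- sort(abs(eigen(P)$values), decreasing = TRUE)
  planted <- -1 / log(ev[2:3])
  cum <- t(apply(P, 1, cumsum))
  dtraj <- integer(5e5); dtraj[1] <- 1L
  u <- runif(5e5)
  for (t in 2:5e5) dtraj[t] <- findInterval(u[t], cum[dtraj[t - 1], ]) + 1L
  its2 <- implied_timescales(dtraj, lags = c(1, 3), n_timescales = 2)
  for (lg in c(1, 3)) {
    est <- sort(its2$timescale[its2$lag == lg], decreasing = TRUE)
    expect_equal(est, planted, tolerance = 0.10)
  }

  # i.i.d. noise has no slow modes
  its3 <- implied_timescales(sample.int(4, 2e4, replace = TRUE),
                             lags = 1, n_timescales = 2)
  expect_true(all(is.na(its3$timescale) | its3$timescale < 1.5))
})

test_that("Chapman-Kolmogorov test validates Markovian data and flags
           lag-2 hidden dynamics", {
  set.seed(27)
  n <- 1e6
  flips <- cumsum(rbinom(n, 1, 0.05)) %% 2L
  m <- estimate_msm(flips + 1L, lag = 1)
  ck <- ck_test(m, flips + 1L, multiples = c(1, 2, 5), n_macro = 2)
  expect_lt(attr(ck, "max_deviation"), 0.02)
  expect_equal(ck$predicted[ck$multiple == 1], ck$estimated[ck$multiple == 1],
               tolerance = 1e-12)

  # semi-Markov construction: duplicate each symbol, so lag-1 dynamics
  # carry hidden memory
  base <- cumsum(rbinom(5e4, 1, 0.30)) %% 2L + 1L
  sticky <- rep(base, each = 2)
  ms <- estimate_msm(sticky, lag = 1)
  cks <- ck_test(ms, sticky, multiples = c(1, 2, 4), n_macro = 2)
  expect_gt(attr(cks, "max_deviation"), 0.02)
})

test_that("PCCA+ resolves planted block structure and keeps memberships
           on the simplex", {
  # two weakly coupled blocks
  eps <- 1e-3
  B <- function() {
    W <- matrix(runif(9, 0.5, 1), 3); W <- W + t(W)
    W / rowSums(W)
  }
  set.seed(28)
  T <- as.matrix(Matrix::bdiag(B(), B())) * (1 - eps) +
    eps * matrix(1 / 6, 6, 6)
  T <- T / rowSums(T)
  model <- structure(list(T = T, pi = fretdyn:::stationary_distribution(T),
                          lag = 1, active_set = 1:6, reversible = FALSE),
                     class = "markov_model")
  part <- pcca(model, 2)
  expect_equal(abs(rowSums(part$memberships)), rep(1, 6), tolerance = 1e-8)
  expect_true(all(part$memberships >= -1e-12 & part$memberships <= 1 + 1e-12))
  expect_equal(length(unique(part$crisp[1:3])), 1)
  expect_equal(length(unique(part$crisp[4:6])), 1)
  expect_false(part$crisp[1] == part$crisp[4])
  # m = 1 puts everything in one set
  p1 <- pcca(model, 1)
  expect_true(all(p1$memberships == 1))
  # coarse-grained transition matrix from memberships is row-stochastic
  chi <- part$memberships
  Pc <- t(chi) %*% diag(model$pi) %*% T %*% chi
  Pc <- Pc / rowSums(Pc)
  expect_equal(rowSums(Pc), rep(1, 2), tolerance = 1e-10)
})

test_that("free-energy surface is a Boltzmann inversion with zero minimum", {
  set.seed(29)
  # two-Gaussian mixture with 9:1 weights: basin depth difference ln 9
  n <- 2e5
  w <- rbinom(n, 1, 0.1)
  pts <- cbind(rnorm(n, mean = ifelse(w == 1, 4, 0), sd = 0.4),
               rnorm(n, sd = 0.4))
  fel <- free_energy_surface(pts, c(60, 20))
  expect_equal(min(fel$F), 0)
  # renormalization identity: exp(-F) proportional to the density
  occ <- is.finite(fel$F)
  expect_equal(exp(-fel$F[occ]) / sum(exp(-fel$F[occ])),
               fel$counts[occ] / sum(fel$counts), tolerance = 1e-9)
  # basin minima separated by ln 9
  xmid <- (fel$x_edges[-1] + fel$x_edges[-length(fel$x_edges)]) / 2
  Fmin_major <- min(fel$F[xmid < 2, ], na.rm = TRUE)
  Fmin_minor <- min(fel$F[xmid > 2, ], na.rm = TRUE)
  expect_equal(Fmin_minor - Fmin_major, log(9), tolerance = 0.2)

  # uniform points give a flat landscape within multinomial noise
  set.seed(30)
  u <- cbind(runif(5e4), runif(5e4))
  felu <- free_energy_surface(u, c(10, 10))
  # expected 500 counts per bin, relative sd ~4.5%; the min-shifted F
  # spread stays well under 0.3 at 3 sigma
  expect_lt(max(felu$F), 0.3)
  # single occupied bin
  fel1 <- free_energy_surface(matrix(c(1, 1), 1), c(5, 5))
  expect_equal(sum(is.finite(fel1$F)), 1)
  expect_equal(min(fel1$F), 0)
})

test_that("cosine content is 1 for a cosine, small for noise, large for
           a random walk", {
  T <- 1e4
  t_frac <- ((1:T) - 0.5) / T
  x <- cbind(cos(pi * t_frac), cos(2 * pi * t_frac) * 0.1)
  cc <- pca_cosine_content(x, 2)
  expect_equal(cc[1], 1, tolerance = 1e-6)
  expect_equal(cc[2], 1, tolerance = 1e-6)
  set.seed(31)
  ccn <- pca_cosine_content(matrix(rnorm(2 * T), ncol = 2), 2)
  expect_true(all(ccn < 0.05))
  rw <- cbind(cumsum(rnorm(T)), cumsum(rnorm(T)))
  ccw <- pca_cosine_content(rw, 1)
  expect_gt(ccw[1], 0.7)
})
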