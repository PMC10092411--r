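make_frames <- function(ref_A, mu_D, mu_A, times = NULL) {
  n <- nrow(ref_A)
  geometry_frames(times %||% (seq_len(n) - 1) * 5,
                  matrix(0, n, 3), ref_A, mu_D, mu_A)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("geometry table round-trips bitwise through the text dialect", {
  set.seed(5)
  spec <- scenario_preset("two-state-minimal", seed = 2)
  sim <- simulate_scenario(spec, 1000)
  path <- withr::local_tempfile(fileext = ".dat")
  write_geometry_table(sim$frames, path)
  back <- read_geometry_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$frames),
               tolerance = 0)
})

test_that("geometry reader rejects malformed input and bad dipoles", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# wrong header"), path)
  expect_error(read_geometry_table(path), "header")
  hdr <- "# time_ps refDx refDy refDz refAx refAy refAz muDx muDy muDz muAx muAy muAz"
  writeLines(c(hdr, paste(c(0, rep(0, 3), 1, 0, 0, 1, 0, 0, 1, 0, "oops"),
                          collapse = " ")), path)
  expect_error(read_geometry_table(path))
  # dipole 20% off unit length is rejected at construction
  expect_error(
    geometry_frames(0, matrix(0, 1, 3), matrix(c(1, 0, 0), 1),
                    matrix(c(1.2, 0, 0), 1), matrix(c(1, 0, 0), 1)),
    "unit length")
})

test_that("atomistic route picks the atom nearest the mass center", {
  # 4-atom toy chromophore: masses concentrate the center near atom 2
  coords <- array(0, c(1, 8, 3))
  coords[1, 1, ] <- c(0, 0, 0)
  coords[1, 2, ] <- c(1, 0, 0)
  coords[1, 3, ] <- c(2, 0, 0)
  coords[1, 4, ] <- c(3, 0, 0)
  coords[1, 5:8, ] <- rep(c(0, 1, 2, 3), 3) + 10  # acceptor far away
  cd <- chromophore_def(1:4, c(1, 10, 1, 1), c(1, 4))
  ca <- chromophore_def(5:8, rep(1, 4), c(5, 8))
  # exhaustive oracle: atom minimizing distance to the weighted centroid
  xyz <- coords[1, 1:4, ]
  com <- colSums(xyz * c(1, 10, 1, 1)) / 13
  oracle <- xyz[which.min(rowSums(sweep(xyz, 2, com)^2)), ]
  fr <- frames_from_coordinates(coords, 0, cd, ca)
  expect_equal(c(fr$refDx, fr$refDy, fr$refDz), oracle)
})

test_that("pair geometry reproduces hand-built configurations", {
  f1 <- make_frames(matrix(c(1, 0, 0), 1), matrix(c(1, 0, 0), 1),
                    matrix(c(1, 0, 0), 1))
  g1 <- pair_geometry(f1)
  expect_equal(g1$R_DA, 1)
  expect_equal(g1$theta_D, 0)
  expect_equal(g1$kappa2, 4)

  f2 <- make_frames(matrix(c(1, 0, 0), 1), matrix(c(0, 1, 0), 1),
                    matrix(c(0, 0, 1), 1))
  g2 <- pair_geometry(f2)
  expect_equal(g2$theta_D, pi / 2)
  expect_equal(g2$theta_A, pi / 2)
  expect_equal(abs(g2$phi), pi / 2)
  expect_equal(g2$kappa2, 0, tolerance = 1e-30)

  expect_error(pair_geometry(geometry_frames(
    0, matrix(1, 1, 3), matrix(1, 1, 3),
    matrix(c(1, 0, 0), 1), matrix(c(1, 0, 0), 1))), "oincident")
})

test_that("per-frame geometry matches the vector-formula oracle", {
  set.seed(77)
  n <- 500
  refA <- random_unit_vectors(n) * runif(n, 0.5, 3)
  muD <- random_unit_vectors(n)
  muA <- random_unit_vectors(n)
  fr <- make_frames(refA, muD, muA)
  g <- fretdyn:::all_pair_geometry(fr)
  for (i in seq_len(n)) {
    kv <- kappa_squared_vectors(muD[i, ], muA[i, ], refA[i, ])
    expect_lt(abs(g$kappa2[i] - kv$kappa2), 1e-10)
  }
})

test_that("fret_trace honours the kappa2 policy and recomputes exactly", {
  pars_dyn <- forster_pair_params(1.03e13, "dynamic", 0.25, 1.407)
  # kappa^2 = 0 throughout (perpendicular crossed dipoles) gives E = 0
  n <- 50
  refA <- cbind(runif(n, 0.5, 2), 0, 0)
  f0 <- make_frames(refA, matrix(rep(c(0, 1, 0), n), n, byrow = TRUE),
                    matrix(rep(c(0, 0, 1), n), n, byrow = TRUE))
  tr0 <- fret_trace(f0, pars_dyn)
  expect_true(all(tr0$efficiency < 1e-25))

  # single frame engineered to sit exactly at R0
  pars_fix <- forster_pair_params(1.03e13, 1, 0.25, 1.407)
  fr <- make_frames(matrix(c(pars_fix$R0, 0, 0), 1),
                    matrix(c(0, 1, 0), 1), matrix(c(0, 1, 0), 1))
  tr <- fret_trace(fr, pars_fix)
  expect_equal(tr$efficiency, 0.5)

  # stored columns recompute the efficiency to 1e-12
  spec <- scenario_preset("two-state-minimal", seed = 9)
  sim <- simulate_scenario(spec, 2000)
  tr2 <- fret_trace(sim$frames, pars_dyn)
  R0 <- forster_radius(pars_dyn$J, tr2$kappa2, pars_dyn$phiD0, pars_dyn$n)
  expect_equal(tr2$efficiency, fret_efficiency(tr2$R_DA, R0),
               tolerance = 1e-12)
  expect_error(fret_trace(sim$frames[0, ], pars_dyn), "empty")
})

test_that("fixed-kappa2 trace mean is invariant under rigid rotation", {
  set.seed(31)
  spec <- scenario_preset("two-state-minimal", seed = 4)
  sim <- simulate_scenario(spec, 1000)
  pars <- forster_pair_params(1.03e13, 2 / 3, 0.25, 1.407)
  tr <- fret_trace(sim$frames, pars)
  # random rotation matrix via QR
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  rot <- function(m) t(Q %*% t(m))
  fr <- sim$frames
  fr2 <- geometry_frames(fr$time_ps,
                         rot(as.matrix(fr[, 2:4])), rot(as.matrix(fr[, 5:7])),
                         rot(as.matrix(fr[, 8:10])), rot(as.matrix(fr[, 11:13])))
  tr2 <- fret_trace(fr2, pars)
  expect_equal(mean(tr2$efficiency), mean(tr$efficiency), tolerance = 1e-12)
})

test_that("scaling separations up never increases any frame's efficiency", {
  spec <- scenario_preset("two-state-minimal", seed = 6)
  sim <- simulate_scenario(spec, 500)
  pars <- forster_pair_params(1.03e13, "dynamic", 0.25, 1.407)
  tr1 <- fret_trace(sim$frames, pars)
  fr <- sim$frames
  s <- 1.7
  fr2 <- geometry_frames(fr$time_ps, s * as.matrix(fr[, 2:4]),
                         s * as.matrix(fr[, 5:7]),
                         as.matrix(fr[, 8:10]), as.matrix(fr[, 11:13]))
  tr2 <- fret_trace(fr2, pars)
  expect_true(all(tr2$efficiency <= tr1$efficiency + 1e-15))
})

test_that("efficiency histogram conserves counts and places mass correctly", {
  spec <- scenario_preset("two-state-minimal", seed = 8)
  sim <- simulate_scenario(spec, 3000)
  pars <- forster_pair_params(1.03e13, "dynamic", 0.25, 1.407)
  tr <- fret_trace(sim$frames, pars)
  h <- efficiency_histogram(tr, 25)
  expect_equal(sum(h$count), nrow(tr))
  # all-zero trace: all mass in the first bin
  tr0 <- tr
  tr0$efficiency <- 0
  h0 <- efficiency_histogram(tr0, 10)
  expect_equal(h0$count[1], nrow(tr0))
  expect_true(all(h0$count[-1] == 0))
  # approximately flat histogram for uniform synthetic efficiencies
  set.seed(12)
  tru <- tr[1:2000, ]
  tru$efficiency <- runif(2000)
  hu <- efficiency_histogram(tru, 10)
  expect_gt(chisq.test(hu$count)$p.value, 0.01)
})

test_that("distance stratification is exact and mass-conserving", {
  tr <- structure(
    data.frame(time_ps = 0:5 * 5,
               R_DA = c(0.5, 0.9, 1.0, 1.5, 2.0, 2.5),
               kappa2 = rep(2 / 3, 6),
               efficiency = c(0.9, 0.8, 0.7, 0.5, 0.2, 0.1)),
    class = c("fret_trace", "data.frame"))
  st <- stratify_by_distance(tr)
  # boundary frames: R = 1.0 joins the closed <=1 class, R = 2.0 the >=2 class
  expect_equal(st$n_frames, c(3L, 1L, 2L))
  expect_equal(st$mean_efficiency,
               c(mean(c(0.9, 0.8, 0.7)), 0.5, mean(c(0.2, 0.1))))
  expect_equal(sum(st$n_frames * st$mean_efficiency) / nrow(tr),
               mean(tr$efficiency), tolerance = 1e-9)
  # empty class reported as NA, trace entirely below 1 nm
  tr_low <- tr[tr$R_DA < 1, ]
  st_low <- stratify_by_distance(tr_low)
  expect_true(is.na(st_low$mean_efficiency[3]))
  expect_equal(st_low$mean_efficiency[1], mean(tr_low$efficiency))
  expect_error(stratify_by_distance(tr, edges = c(2, 1)), "increasing")
})

test_that("window extraction preserves times and handles empty windows", {
  spec <- scenario_preset("two-state-minimal", seed = 10)
  sim <- simulate_scenario(spec, 1000)
  pars <- forster_pair_params(1.03e13, "dynamic", 0.25, 1.407)
  tr <- fret_trace(sim$frames, pars)
  full <- window_extract(tr, min(tr$time_ps), max(tr$time_ps))
  expect_equal(nrow(full), nrow(tr))
  empty <- window_extract(tr, 1e7, 2e7)
  expect_equal(nrow(empty), 0)
  w <- window_extract(tr, 1000, 2000)
  expect_equal(nrow(w), sum(tr$time_ps >= 1000 & tr$time_ps <= 2000))
  expect_true(all(w$time_ps >= 1000 & w$time_ps <= 2000))
  expect_error(window_extract(tr, 5, 5), "t_start")
})
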