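# Markov state model estimation: microstate clustering, transition
# matrices, implied timescales, Chapman-Kolmogorov validation, and
# PCCA+ metastable lumping.

#' k-means microstate clustering
#'
#' Lloyd iterations with k-means++ initialization under a fixed seed.
#' A cluster that empties during iteration is re-seeded at the point
#' farthest from its nearest center, so exactly `k` populated states
#' are returned whenever `k` distinct points exist.
#'
#' @param x matrix of projected coordinates (rows = frames).
#' @param k number of microstates.
#' @param seed RNG seed (recorded in the result).
#' @param max_iter maximum Lloyd iterations.
#' @return list of class `microstates`: `assignment` (1..k per frame),
#'   `centers` (k x d), `inertia`, `iterations`, `seed`.
#' @export
cluster_kmeans <- function(x, k, seed = 42L, max_iter = 100L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of points")
  set.seed(seed)
  # k-means++ seeding
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  if (k > 1L) for (j in 2L:k) {
    if (sum(d2) <= 0) {
      centers[j, ] <- x[sample.int(n, 1L), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  xsq <- rowSums(x^2)
  assign_pts <- function(ctr) {
    # argmin_j |x - c_j|^2 via the expanded cross-product form
    D <- xsq - 2 * x %*% t(ctr) +
      matrix(rowSums(ctr^2), n, nrow(ctr), byrow = TRUE)
    max.col(-D, ties.method = "first")
  }
  lab <- assign_pts(centers)
  it <- 0L
  repeat {
    it <- it + 1L
    for (j in seq_len(k)) {
      idx <- lab == j
      if (!any(idx)) {
        # re-seed empty cluster at the point farthest from its center
        dmin <- rowSums((x - centers[lab, , drop = FALSE])^2)
        centers[j, ] <- x[which.max(dmin), ]
      } else {
        centers[j, ] <- colMeans(x[idx, , drop = FALSE])
      }
    }
    new_lab <- assign_pts(centers)
    if (identical(new_lab, lab) || it >= max_iter) {
      lab <- new_lab
      break
    }
    lab <- new_lab
  }
  inertia <- sum(rowSums((x - centers[lab, , drop = FALSE])^2))
  structure(list(assignment = lab, centers = centers, inertia = inertia,
                 iterations = it, seed = seed),
            class = "microstates")
}

# Sliding-window transition counts at a lag.
count_transitions <- function(dtraj, lag, k) {
  n <- length(dtraj)
  from <- dtraj[seq_len(n - lag)]
  to <- dtraj[(lag + 1L):n]
  C <- matrix(0, k, k)
  tab <- table(factor(from, levels = seq_len(k)),
               factor(to, levels = seq_len(k)))
  C[] <- as.numeric(tab)
  C
}

# Reversible maximum-likelihood estimator (detailed-balance fixed
# point): iterate x_ij = (c_ij + c_ji) / (c_i/x_i + c_j/x_j) with
# x_i = sum_j x_ij, then T_ij = x_ij / x_i.
reversible_mle <- function(C, tol = 1e-10, max_iter = 10000L) {
  k <- nrow(C)
  Cs <- C + t(C)
  ci <- rowSums(C)
  X <- Cs / sum(C)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, "+")
    Xn <- Cs / denom
    Xn[Cs == 0] <- 0
    Xn <- Xn / sum(Xn)
    if (max(abs(Xn - X)) < tol) {
      X <- Xn
      break
    }
    X <- Xn
  }
  X / rowSums(X)
}

# Stationary distribution = leading left eigenvector of T.
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Estimate a Markov state model from a discrete trajectory
#'
#' Sliding-window transition counts at the requested lag, restriction
#' to the largest strongly connected set of states, and row-normalized
#' (non-reversible) or detailed-balance maximum-likelihood (reversible)
#' transition matrix with its stationary distribution.
#'
#' @param dtraj integer microstate sequence (1-based), or a list of
#'   such sequences.
#' @param lag lag time in frames.
#' @param reversible logical; enforce detailed balance (default FALSE).
#' @param n_states total number of microstates (default max observed).
#' @return object of class `markov_model`: `lag`, `counts` (full),
#'   `active_set` (original state indices retained), `T` (row
#'   stochastic on the active set), `pi` (stationary), `reversible`,
#'   `retained_fraction` (share of counts kept).
#' @export
estimate_msm <- function(dtraj, lag, reversible = FALSE, n_states = NULL) {
  if (!is.list(dtraj)) dtraj <- list(dtraj)
  if (any(vapply(dtraj, length, 1L) <= lag))
    stop("every trajectory must be longer than the lag")
  k <- n_states %||% max(vapply(dtraj, max, 1L))
  C <- Reduce(`+`, lapply(dtraj, count_transitions, lag = lag, k = k))
  # largest strongly connected component on observed transitions
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tapply(rowSums(C) + colSums(C), comp$membership, sum)
  big <- as.integer(names(sizes)[which.max(sizes)])
  active <- which(comp$membership == big)
  retained <- sum(C[active, active]) / max(sum(C), 1)
  if (retained < 1 - 1e-12)
    warning(sprintf("disconnected discrete trajectory: retained %.1f%% of counts",
                    100 * retained))
  Ca <- C[active, active, drop = FALSE]
  T <- if (reversible) reversible_mle(Ca) else Ca / rowSums(Ca)
  structure(list(lag = lag, counts = C, active_set = active, T = T,
                 pi = stationary_distribution(T), reversible = reversible,
                 retained_fraction = retained),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf(
    "<markov_model: %d states, lag %d, %s, slowest timescale %.3g frames>\n",
    nrow(x$T), x$lag, if (x$reversible) "reversible" else "non-reversible",
    implied_timescales_model(x, 1)))
  invisible(x)
}

# Implied timescales of an estimated model: t_i = -lag / log|lambda_i|.
implied_timescales_model <- function(model, n_timescales = 3L) {
  lambda <- eigen(model$T)$values
  lambda <- lambda[order(-abs(lambda))]
  lam <- abs(lambda[-1])[seq_len(min(n_timescales, length(lambda) - 1L))]
  ifelse(lam <= 0 | lam >= 1, NA_real_, -model$lag / log(lam))
}

#' Implied timescales as a function of lag
#'
#' Re-estimates the MSM at each lag and reports
#' t_i(tau) = -tau / log|lambda_i(tau)| for the top non-unit
#' eigenvalues. Non-positive eigenvalues yield `NA` (undefined
#' timescale). A plateau across lags indicates Markovian dynamics at
#' those lags.
#'
#' @inheritParams estimate_msm
#' @param lags integer vector of lags (frames).
#' @param n_timescales how many timescales to report.
#' @return data frame: `lag`, `timescale_index`, `timescale` (frames).
#' @export
implied_timescales <- function(dtraj, lags, n_timescales = 3L,
                               reversible = FALSE) {
  res <- lapply(lags, function(l) {
    m <- estimate_msm(dtraj, l, reversible = reversible)
    lambda <- eigen(m$T)$values
    lambda <- lambda[order(-abs(lambda))][-1]
    nt <- min(n_timescales, length(lambda))
    lam <- lambda[seq_len(nt)]
    ts <- ifelse(Re(lam) <= 0 & abs(Im(lam)) < 1e-12, NA_real_,
                 ifelse(abs(lam) >= 1, NA_real_, -l / log(abs(lam))))
    data.frame(lag = l, timescale_index = seq_len(nt), timescale = ts)
  })
  do.call(rbind, res)
}

#' Chapman-Kolmogorov test
#'
#' Lumps the model into `n_macro` metastable sets (PCCA+) and compares
#' the set self-transition probabilities predicted by propagating the
#' lag-tau model, [T(tau)]^k, against models re-estimated at lag
#' k*tau, for each multiple k. Deviations small compared to the
#' self-transition probabilities indicate Markovianity at lag tau.
#'
#' @param model `markov_model` estimated at the base lag.
#' @param dtraj the discrete trajectory the model came from.
#' @param multiples integer lag multiples k.
#' @param n_macro number of metastable sets to compare on.
#' @return data frame: `multiple`, `set`, `predicted`, `estimated`,
#'   plus attribute `max_deviation`.
#' @export
ck_test <- function(model, dtraj, multiples = 1:5, n_macro = 2L) {
  part <- pcca(model, n_macro)
  labels <- part$crisp
  if (!is.list(dtraj)) dtraj <- list(dtraj)
  # map frames to active-set macro labels (0 = outside active set)
  act <- model$active_set
  macro_of_state <- rep(NA_integer_, max(act))
  macro_of_state[act] <- labels
  setprob_from_T <- function(T, pi) {
    vapply(seq_len(n_macro), function(s) {
      w <- pi[labels == s]
      Tm <- T[labels == s, labels == s, drop = FALSE]
      sum(w * rowSums(Tm)) / sum(w)
    }, numeric(1))
  }
  rows <- lapply(multiples, function(k) {
    Tk <- model$T
    if (k > 1) for (i in seq_len(k - 1L)) Tk <- Tk %*% model$T
    pred <- setprob_from_T(Tk, model$pi)
    mk <- estimate_msm(dtraj, model$lag * k, reversible = model$reversible,
                       n_states = nrow(model$counts))
    # align: compare only when the active sets agree
    if (!identical(mk$active_set, act)) {
      est <- rep(NA_real_, n_macro)
    } else {
      est <- setprob_from_T(mk$T, mk$pi)
    }
    data.frame(multiple = k, set = seq_len(n_macro),
               predicted = pred, estimated = est)
  })
  out <- do.call(rbind, rows)
  attr(out, "max_deviation") <- max(abs(out$predicted - out$estimated),
                                    na.rm = TRUE)
  out
}

#' PCCA+ metastable lumping
#'
#' Perron cluster cluster analysis: the top-m right eigenvectors of the
#' transition matrix span an m-simplex whose vertices correspond to
#' metastable sets. The vertices are located by the inner-simplex
#' algorithm (iterative farthest-point search with Gram-Schmidt
#' deflation); memberships are the linear transform of the eigenvector
#' rows onto barycentric coordinates, clipped to the simplex and
#' renormalized. Complex eigenvalues in the top-m block trigger a fall
#' back to real Schur vectors with a warning.
#'
#' @param model `markov_model`.
#' @param m number of metastable sets (2 <= m <= number of states).
#' @return object of class `metastable_partition`: `m`, `memberships`
#'   (k x m, rows on the simplex), `crisp` (argmax labels 1..m),
#'   `active_set` copied from the model.
#' @export
pcca <- function(model, m) {
  k <- nrow(model$T)
  if (m > k) stop("m must not exceed the number of states")
  if (m == 1L) {
    return(structure(list(m = 1L, memberships = matrix(1, k, 1),
                          crisp = rep(1L, k),
                          active_set = model$active_set),
                     class = "metastable_partition"))
  }
  e <- eigen(model$T)
  ord <- order(-abs(e$values))
  vals <- e$values[ord][seq_len(m)]
  if (any(abs(Im(vals)) > 1e-10)) {
    # complex conjugate pairs in the dominant block: span the same real
    # invariant subspace with Re/Im parts of one member of each pair
    warning("complex eigenvalues in the top-m block; using the real invariant subspace")
    X <- matrix(0, k, 0)
    j <- 1L
    while (ncol(X) < m) {
      v <- e$vectors[, ord[j]]
      if (abs(Im(e$values[ord[j]])) > 1e-10) {
        X <- cbind(X, Re(v), Im(v))
        j <- j + 2L   # skip the conjugate partner
      } else {
        X <- cbind(X, Re(v))
        j <- j + 1L
      }
    }
    X <- X[, seq_len(m), drop = FALSE]
  } else {
    X <- Re(e$vectors[, ord[seq_len(m)], drop = FALSE])
  }
  # normalize the stationary eigenvector column to a constant sign and
  # scale columns for numerical stability
  X[, 1] <- 1
  if (m > 1) for (j in 2:m) X[, j] <- X[, j] / max(abs(X[, j]))
  # inner-simplex vertex search
  idx <- integer(m)
  ortho <- X
  idx[1] <- which.max(rowSums(ortho^2))
  v <- ortho[idx[1], ]
  ortho <- sweep(ortho, 2, v)
  for (j in seq_len(m - 1L)) {
    nrm <- sqrt(rowSums(ortho^2))
    idx[j + 1L] <- which.max(nrm)
    v <- ortho[idx[j + 1L], ] / nrm[idx[j + 1L]]
    ortho <- ortho - (ortho %*% v) %*% t(v)
  }
  A <- X[idx, , drop = FALSE]
  chi <- X %*% solve(A)
  # clip to the simplex and renormalize rows
  chi[chi < 0] <- 0
  rs <- rowSums(chi)
  rs[rs == 0] <- 1
  chi <- chi / rs
  crisp <- max.col(chi, ties.method = "first")
  # guarantee non-empty sets: each vertex state claims its own set
  crisp[idx] <- seq_len(m)
  structure(list(m = m, memberships = chi, crisp = crisp,
                 active_set = model$active_set),
            class = "metastable_partition")
}

#' @export
print.metastable_partition <- function(x, ...) {
  cat(sprintf("<metastable_partition: %d sets over %d microstates, sizes %s>\n",
              x$m, nrow(x$memberships),
              paste(tabulate(x$crisp, x$m), collapse = "/")))
  invisible(x)
}

#' Free-energy landscape over two projected coordinates
#'
#' Boltzmann inversion of the empirical density on a 2-D grid:
#' F = -ln P in units of k_B T, with empty bins at +Inf and the global
#' minimum shifted to zero.
#'
#' @param projected n x 2 matrix of projected coordinates.
#' @param grid_shape integer vector of length 2: bins along each axis.
#' @return object of class `fel`: `F` (matrix, k_B T), `x_edges`,
#'   `y_edges`, `counts`.
#' @export
free_energy_surface <- function(projected, grid_shape = c(50L, 50L)) {
  X <- as.matrix(projected)
  if (nrow(X) < 1L || ncol(X) != 2L) stop("projected must be n x 2, n >= 1")
  xe <- seq(min(X[, 1]), max(X[, 1]), length.out = grid_shape[1] + 1L)
  ye <- seq(min(X[, 2]), max(X[, 2]), length.out = grid_shape[2] + 1L)
  if (xe[1] == xe[length(xe)]) xe <- xe[1] + c(-0.5, 0.5)
  if (ye[1] == ye[length(ye)]) ye <- ye[1] + c(-0.5, 0.5)
  ix <- pmin(pmax(findInterval(X[, 1], xe, rightmost.closed = TRUE), 1L),
             length(xe) - 1L)
  iy <- pmin(pmax(findInterval(X[, 2], ye, rightmost.closed = TRUE), 1L),
             length(ye) - 1L)
  counts <- matrix(0, length(xe) - 1L, length(ye) - 1L)
  for (i in seq_len(nrow(X))) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1
  P <- counts / nrow(X)
  F <- -log(P)              # +Inf in empty bins by construction
  F <- F - min(F)
  structure(list(F = F, x_edges = xe, y_edges = ye, counts = counts),
            class = "fel")
}
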