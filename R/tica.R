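# Time-lagged independent component analysis: linear projections that
# maximize autocorrelation at a lag, solved as the symmetrized
# generalized eigenproblem C(tau) v = lambda C(0) v on mean-free data.

#' Fit a tICA model
#'
#' Covariances are estimated from the paired frames (t, t + lag) with
#' the mean removed; C(tau) is symmetrized. C(0) is regularized by
#' `epsilon` on the diagonal and null directions (eigenvalue below
#' 1e-12 of the largest) are dropped with a warning. The eigenproblem
#' is solved by whitening: eigenvectors of
#' C(0)^-1/2 C_sym(tau) C(0)^-1/2 mapped back through the whitening
#' transform, so components are uncorrelated with unit variance at lag
#' 0.
#'
#' @param features numeric matrix, one row per frame, one column per
#'   feature (a vector is treated as a one-column matrix).
#' @param lag lag time in frames (>= 1, < number of frames).
#' @param epsilon diagonal regularization of C(0).
#' @return object of class `tica_model`: `lag`, `mean`, `eigenvalues`
#'   (descending), `components` (columns = projection vectors),
#'   `timescales` (implied, `-lag/log|lambda|`, frames).
#' @export
tica_fit <- function(features, lag, epsilon = 1e-10) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (lag < 1L || n <= lag) stop("need series length > lag >= 1")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  A <- Xc[seq_len(n - lag), , drop = FALSE]
  B <- Xc[(lag + 1L):n, , drop = FALSE]
  m <- n - lag
  # lag-0 covariance over both windows (standard symmetric estimate)
  C0 <- (crossprod(A) + crossprod(B)) / (2 * m)
  Ct <- crossprod(A, B) / m
  Ct <- (Ct + t(Ct)) / 2
  C0 <- C0 + diag(epsilon, ncol(X))
  e0 <- eigen(C0, symmetric = TRUE)
  keep <- e0$values > max(e0$values) * 1e-12
  if (!all(keep)) warning("dropping ", sum(!keep),
                          " null feature direction(s) in C(0)")
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  M <- t(W) %*% Ct %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)
  lambda <- em$values[ord]
  V <- W %*% em$vectors[, ord, drop = FALSE]
  out <- list(lag = lag, mean = mu, eigenvalues = lambda, components = V,
              timescales = ifelse(abs(lambda) >= 1 | lambda <= 0,
                                  NA_real_, -lag / log(abs(lambda))))
  class(out) <- "tica_model"
  out
}

#' Project frames onto tICA components
#'
#' @param model a `tica_model`.
#' @param features matrix of frames (same feature layout as the fit).
#' @param n_components number of leading components to keep.
#' @return matrix of projected coordinates.
#' @export
tica_transform <- function(model, features, n_components = NULL) {
  X <- sweep(as.matrix(features), 2, model$mean)
  V <- model$components
  if (!is.null(n_components))
    V <- V[, seq_len(n_components), drop = FALSE]
  X %*% V
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("<tica_model: lag %d frames, %d components, top eigenvalues %s>\n",
              x$lag, ncol(x$components),
              paste(sprintf("%.3f", utils::head(x$eigenvalues, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Cosine content of principal components
#'
#' The cosine content of the i-th principal component time series
#' p_i(t) over T frames,
#' \deqn{c_i = \frac{2}{T}\,
#'   \frac{\left(\sum_t \cos(i\pi t/T)\, p_i(t)\right)^2}{\sum_t p_i(t)^2},}
#' is close to 1 for an unconverged random-walk-like projection and
#' small when the sampling has decorrelated from its starting point, so
#' it serves as a sampling-quality diagnostic.
#'
#' @param coordinates matrix of frame coordinates (rows = frames).
#' @param n_components number of leading PCs to report.
#' @return numeric vector of cosine contents in \[0, 1\].
#' @export
pca_cosine_content <- function(coordinates, n_components = 2L) {
  X <- as.matrix(coordinates)
  if (nrow(X) < 4L) stop("need at least 4 frames")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  T <- nrow(X)
  t_frac <- (seq_len(T) - 0.5) / T
  vapply(seq_len(k), function(i) {
    p <- pc$x[, i]
    num <- sum(cos(i * pi * t_frac) * p)^2
    (2 / T) * num / sum(p^2)
  }, numeric(1))
}
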