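# Internal numerical helpers shared across modules.

# Trapezoidal quadrature on an arbitrary (increasing) grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

vec_norm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v) {
  nv <- vec_norm(v)
  if (nv == 0) stop("zero-length vector cannot be normalized")
  v / nv
}

# Orthonormal basis (e1, e2) spanning the plane perpendicular to unit vector u.
perp_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vector(ref - sum(ref * u) * u)
  e2 <- c(
    u[2] * e1[3] - u[3] * e1[2],
    u[3] * e1[1] - u[1] * e1[3],
    u[1] * e1[2] - u[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  invisible(x)
}
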