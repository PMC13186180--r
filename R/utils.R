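#' @importFrom stats rnorm runif var integrate optim setNames quantile
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical hemisphere representative of an axis
#'
#' Fiber orientations are axes (antipodally symmetric), so each axis has two
#' unit-vector representatives. The canonical one has nonnegative z; ties
#' (z = 0) are broken by nonnegative y, then nonnegative x.
#'
#' @param m A unit 3-vector, or a matrix with one unit vector per row.
#' @return The canonicalized vector(s), same shape as the input.
#' @export
canonicalize_axis <- function(m) {
  if (is.matrix(m)) return(t(apply(m, 1, canonicalize_axis)))
  flip <- (m[3] < 0) ||
    (m[3] == 0 && m[2] < 0) ||
    (m[3] == 0 && m[2] == 0 && m[1] < 0)
  if (flip) -m else m
}

unit_rows <- function(x, tol = 1e-8) {
  all(abs(sqrt(rowSums(x^2)) - 1) < tol)
}

normalize_rows <- function(x) x / sqrt(rowSums(x^2))

#' Angle between two axes, in radians
#'
#' The axial (antipodally invariant) angle `acos(|m1' m2|)`, in `[0, pi/2]`.
#'
#' @param m1,m2 Unit 3-vectors.
#' @return Angle in radians.
#' @export
axial_angle <- function(m1, m2) {
  acos(pmin(1, abs(sum(m1 * m2))))
}

#' Uniformly spread directions on the sphere
#'
#' Deterministic Fibonacci-spiral point set, used as a synthetic angular
#' sampling design when no measured gradient table is supplied.
#'
#' @param m Number of directions.
#' @return An `m` x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(m) {
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  unname(cbind(r * cos(phi), r * sin(phi), z))
}

#' Random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) (QR of a Gaussian matrix with a
#' determinant fix).
#'
#' @param rng_unused Ignored; draws use the current RNG state.
#' @return A 3 x 3 rotation matrix.
#' @export
random_rotation <- function(rng_unused = NULL) {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# (1 - exp(-x)) / x with a series branch near 0; the mean of exp(-x t) on [0,1].
expmean1 <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small] / 2 + x[small]^2 / 6
  out[!small] <- (1 - exp(-x[!small])) / x[!small]
  out
}
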