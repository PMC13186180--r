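#' Real symmetric spherical-harmonic basis
#'
#' The even-degree real spherical harmonics, orthonormal on the sphere and
#' antipodally symmetric, used to represent per-shell diffusion signals and
#' ODFs. Dimension `K = sum_{even l <= degree} (2l + 1)`: degree 8 gives 45
#' functions, degree 20 gives 231.
#'
#' @param degree Maximum even degree.
#' @return An `sh_basis` object with fields `degree`, `K`, `l` (per-function
#'   degree) and `m` (per-function order).
#' @export
sh_basis <- function(degree = 8) {
  if (degree %% 2 != 0) stop("degree must be even")
  ls <- seq(0, degree, by = 2)
  l <- unlist(lapply(ls, function(li) rep(li, 2 * li + 1)))
  m <- unlist(lapply(ls, function(li) seq(-li, li)))
  structure(list(degree = degree, K = length(l), l = l, m = m),
            class = "sh_basis")
}

#' Evaluate the basis at a set of directions
#'
#' @param basis An [sh_basis()].
#' @param dirs Matrix of unit direction vectors (rows).
#' @return An `M x K` evaluation matrix.
#' @export
sh_eval_matrix <- function(basis, dirs) {
  if (!is.matrix(dirs)) dirs <- matrix(dirs, nrow = 1)
  ct <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  out <- matrix(0, nrow(dirs), basis$K)
  col <- 1L
  for (li in seq(0, basis$degree, by = 2)) {
    # pracma::legendre returns P_l^m(x) for m = 0..l (rows), Condon-Shortley
    # phase included; orthonormalize with the standard factor.
    P <- pracma::legendre(li, ct)
    if (is.null(dim(P))) P <- matrix(P, nrow = li + 1)
    for (mi in seq(-li, li)) {
      am <- abs(mi)
      nl <- sqrt((2 * li + 1) / (4 * pi) *
                   exp(lgamma(li - am + 1) - lgamma(li + am + 1)))
      base <- nl * P[am + 1, ]
      out[, col] <- if (mi == 0) base
        else if (mi > 0) sqrt(2) * base * cos(mi * phi)
        else sqrt(2) * base * sin(am * phi)
      col <- col + 1L
    }
  }
  out
}

#' Least-squares spherical-harmonic fit of shell measurements
#'
#' Solves `c_hat = (Phi' Phi + lambda R)^{-1} Phi' s` with the
#' Laplace-Beltrami ridge penalty `R = diag(l^2 (l + 1)^2)`; `lambda = 0`
#' is ordinary least squares and requires at least `K` directions.
#'
#' @param s Measurement vector (one shell).
#' @param dirs Matrix of unit gradient directions for the shell.
#' @param basis An [sh_basis()].
#' @param lambda Ridge weight (nonnegative; default 0).
#' @return Coefficient vector of length `K`.
#' @export
fit_sh <- function(s, dirs, basis = sh_basis(8), lambda = 0) {
  phi <- sh_eval_matrix(basis, dirs)
  a <- crossprod(phi)
  if (lambda > 0) a <- a + lambda * diag(basis$l^2 * (basis$l + 1)^2)
  ch <- tryCatch(chol(a), error = function(e) NULL)
  if (is.null(ch))
    stop("normal matrix is singular; supply a positive ridge lambda")
  backsolve(ch, forwardsolve(t(ch), crossprod(phi, s)))[, 1]
}

#' Evaluate a fitted spherical-harmonic expansion
#'
#' @param coeffs Coefficient vector (length `K`) or a `K x C` matrix of
#'   channels.
#' @param dirs Points at which to evaluate (matrix of unit vectors).
#' @param basis The [sh_basis()] used for the fit.
#' @return A vector (or `M x C` matrix) of values.
#' @export
evaluate_signal <- function(coeffs, dirs, basis = sh_basis(8)) {
  cm <- if (is.matrix(coeffs)) coeffs else matrix(coeffs, ncol = 1)
  if (nrow(cm) != basis$K) stop("coefficient length does not match basis")
  val <- sh_eval_matrix(basis, dirs) %*% cm
  if (is.matrix(coeffs)) val else val[, 1]
}

# Per-shell SH fit of a signal_sample; returns K x L coefficient matrix.
fit_sh_shells <- function(s, scheme, basis = sh_basis(8), lambda = 0) {
  vapply(seq_along(scheme$shells), function(l) {
    fit_sh(s$s[[l]], scheme$shells[[l]]$dirs, basis, lambda)
  }, numeric(basis$K))
}
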