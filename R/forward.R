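#' Per-fiber standard-model kernel parameters
#'
#' One fiber population is described by the standard model of diffusion in
#' white matter: an intra-axonal "stick" compartment with parallel
#' diffusivity `Da` and an extra-axonal anisotropic Gaussian compartment
#' with parallel diffusivity `De_par` and perpendicular diffusivity
#' `De_perp`. The signal fractions `z1 = w * v` (intra-axonal) and
#' `z2 = w * (1 - v)` (extra-axonal) fold the fiber's mixture weight `w`
#' and intra-axonal volume fraction `v` into two nonnegative weights.
#'
#' Diffusivities are in micrometers^2/ms; with b-values in ms/micrometers^2
#' all exponents are dimensionless.
#'
#' @param Da Intra-axonal parallel diffusivity, in `[0.2, 3]`.
#' @param De_par Extra-axonal parallel diffusivity, in `[0.2, 3]`.
#' @param De_perp Extra-axonal perpendicular diffusivity, in
#'   `(0, 0.8 * De_par)`.
#' @param z1,z2 Nonnegative intra/extra-axonal signal fractions.
#' @return A named numeric vector of class `kernel_params`.
#' @export
kernel_params <- function(Da, De_par, De_perp, z1, z2) {
  k <- c(Da = Da, De_par = De_par, De_perp = De_perp, z1 = z1, z2 = z2)
  validate_kernel_params(k)
  class(k) <- "kernel_params"
  k
}

validate_kernel_params <- function(k) {
  if (k[["Da"]] < 0.2 || k[["Da"]] > 3 || k[["De_par"]] < 0.2 || k[["De_par"]] > 3)
    stop("parallel diffusivities must lie in [0.2, 3] um^2/ms")
  if (k[["De_perp"]] <= 0 || k[["De_perp"]] >= 0.8 * k[["De_par"]])
    stop("De_perp must satisfy 0 < De_perp < 0.8 * De_par")
  if (k[["z1"]] < 0 || k[["z2"]] < 0) stop("signal fractions must be nonnegative")
  invisible(k)
}

#' A voxel's ground-truth fiber configuration
#'
#' Bundles the number of fiber populations `n` (1 to 3), their axis
#' orientations (canonical hemisphere representatives) and per-fiber
#' standard-model kernel parameters. The signal fractions must sum to one
#' across fibers and compartments, and orientations must respect the
#' histologically motivated crossing-angle rules: every pairwise axial angle
#' at least 10 degrees and, for three fibers, the second-smallest pairwise
#' angle at least 30 degrees.
#'
#' @param orientations An `n` x 3 matrix of unit axis vectors.
#' @param kernels An `n` x 5 matrix (columns `Da`, `De_par`, `De_perp`,
#'   `z1`, `z2`) or a list of [kernel_params()] objects.
#' @param check Validate invariants (default `TRUE`).
#' @return An object of class `fiber_config`.
#' @export
fiber_config <- function(orientations, kernels, check = TRUE) {
  if (!is.matrix(orientations)) orientations <- matrix(orientations, nrow = 1)
  if (is.list(kernels)) kernels <- do.call(rbind, kernels)
  if (!is.matrix(kernels)) kernels <- matrix(kernels, nrow = 1)
  colnames(kernels) <- c("Da", "De_par", "De_perp", "z1", "z2")
  n <- nrow(orientations)
  cfg <- structure(
    list(n = n,
         orientations = canonicalize_axis(orientations),
         kernels = kernels),
    class = "fiber_config")
  if (check) validate_fiber_config(cfg)
  cfg
}

validate_fiber_config <- function(cfg) {
  n <- cfg$n
  if (n < 1 || n > 3) stop("fiber count must be between 1 and 3")
  if (nrow(cfg$kernels) != n) stop("one kernel parameter set per fiber required")
  if (!unit_rows(cfg$orientations)) stop("orientations must be unit vectors")
  for (i in seq_len(n)) validate_kernel_params(cfg$kernels[i, ])
  if (abs(sum(cfg$kernels[, c("z1", "z2")]) - 1) > 1e-10)
    stop("signal fractions z1 + z2 must sum to 1 across fibers")
  if (n > 1) {
    ang <- pairwise_axial_angles(cfg$orientations)
    if (min(ang) < 10 * pi / 180)
      stop("pairwise crossing angles must be at least 10 degrees")
    if (n == 3 && sort(ang)[2] < 30 * pi / 180)
      stop("second-smallest crossing angle must be at least 30 degrees")
  }
  invisible(cfg)
}

pairwise_axial_angles <- function(m) {
  n <- nrow(m)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  apply(idx, 1, function(ij) axial_angle(m[ij[1], ], m[ij[2], ]))
}

#' @export
print.fiber_config <- function(x, ...) {
  cat("<fiber_config> n =", x$n, "\n")
  print(round(cbind(x$orientations, x$kernels), 4))
  invisible(x)
}

#' Multi-shell acquisition scheme
#'
#' A diffusion sampling design: `L` shells, each a b-value (ms/um^2;
#' 1000 s/mm^2 is 1 ms/um^2) with a set of unit gradient directions, plus a
#' number of b = 0 volumes.
#'
#' @param bvals Numeric vector of `L` distinct positive b-values in ms/um^2.
#' @param dirs A list of `L` direction matrices (rows are unit vectors), or a
#'   single matrix recycled across shells.
#' @param n_b0 Number of b = 0 measurements.
#' @return An object of class `acquisition_scheme`.
#' @export
acquisition_scheme <- function(bvals, dirs, n_b0 = 0) {
  if (is.matrix(dirs)) dirs <- replicate(length(bvals), dirs, simplify = FALSE)
  stopifnot(length(bvals) == length(dirs), length(bvals) >= 1)
  if (any(bvals <= 0)) stop("shell b-values must be strictly positive")
  if (anyDuplicated(bvals)) stop("shell b-values must be distinct")
  dirs <- lapply(dirs, function(d) {
    if (!unit_rows(d)) stop("gradient directions must be unit vectors")
    d
  })
  structure(
    list(shells = Map(function(b, d) list(b = b, dirs = d), bvals, dirs),
         n_b0 = n_b0),
    class = "acquisition_scheme")
}

#' Default two-shell synthetic design
#'
#' An HCP-like design: shells at b = 1 and 3 ms/um^2 with 60 Fibonacci-spread
#' directions each and 12 b = 0 volumes.
#'
#' @param bvals Shell b-values (ms/um^2).
#' @param m Directions per shell.
#' @param n_b0 Number of b = 0 volumes.
#' @return An `acquisition_scheme`.
#' @export
default_scheme <- function(bvals = c(1, 3), m = 60, n_b0 = 12) {
  acquisition_scheme(bvals, fibonacci_directions(m), n_b0 = n_b0)
}

#' Shell b-values and sizes of a scheme
#'
#' @param scheme An [acquisition_scheme()].
#' @return `scheme_bvals`: numeric vector of shell b-values (ms/um^2);
#'   `scheme_sizes`: integer vector of per-shell direction counts.
#' @export
scheme_bvals <- function(scheme) vapply(scheme$shells, `[[`, numeric(1), "b")

#' @rdname scheme_bvals
#' @export
scheme_sizes <- function(scheme) vapply(scheme$shells, function(s) nrow(s$dirs), integer(1))

#' Standard-model kernel decay function
#'
#' The bi-exponential attenuation of one fiber as a function of the squared
#' projection `t = (p' m)^2` of the gradient direction on the fiber axis:
#' `z1 * exp(-b * Da * t) + z2 * exp(-b * De_perp - b * (De_par - De_perp) * t)`.
#'
#' @param t Squared projection(s) in `[0, 1]`.
#' @param b b-value in ms/um^2 (nonnegative).
#' @param k A [kernel_params()] object (or named vector).
#' @return Attenuation value(s) in `[0, z1 + z2]`, nonincreasing in `t`.
#' @export
standard_model_kernel <- function(t, b, k) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  if (b < 0) stop("b must be nonnegative")
  k <- as_kernel_vec(k)
  k[["z1"]] * exp(-b * k[["Da"]] * t) +
    k[["z2"]] * exp(-b * k[["De_perp"]] - b * (k[["De_par"]] - k[["De_perp"]]) * t)
}

#' Watson density on the sphere
#'
#' The axially symmetric Watson density
#' `C_kappa * exp(kappa * (m' u)^2)` with normalizing constant
#' `C_kappa = (2 * pi * integral_0^1 exp(kappa t^2) dt)^{-1}`, so that the
#' density integrates to 1 over the hemisphere (and to 2 over the full
#' sphere); it is antipodally symmetric.
#'
#' @param u Unit vector(s): a 3-vector or a matrix with unit rows.
#' @param m Mean axis (unit 3-vector).
#' @param kappa Concentration parameter, nonnegative; `kappa = 0` is the
#'   uniform density `1 / (2 * pi)`.
#' @return Density value(s).
#' @export
watson_density <- function(u, m, kappa) {
  if (kappa < 0) stop("kappa must be nonnegative")
  cmat <- if (is.matrix(u)) u else matrix(u, nrow = 1)
  ck <- 1 / (2 * pi * integrate(function(t) exp(kappa * t^2), 0, 1,
                                rel.tol = 1e-10)$value)
  val <- ck * exp(kappa * as.vector(cmat %*% m)^2)
  if (is.matrix(u)) val else val[[1]]
}

#' Mixture standard-model signal
#'
#' Noiseless attenuation of a multi-fiber voxel in the large-concentration
#' limit of the Watson mixture ODF: the sum over fibers of the standard-model
#' kernel evaluated at the squared projection on each fiber axis. Equals 1 at
#' b = 0 and is invariant to joint rotations and to antipodal flips of the
#' gradient direction or any fiber axis.
#'
#' @param p Gradient direction(s): unit 3-vector or matrix with unit rows.
#' @param b b-value in ms/um^2.
#' @param cfg A [fiber_config()].
#' @return Attenuation value(s).
#' @export
mixture_signal <- function(p, b, cfg) {
  pm <- if (is.matrix(p)) p else matrix(p, nrow = 1)
  t2 <- (pm %*% t(cfg$orientations))^2  # M x n squared projections
  out <- numeric(nrow(pm))
  for (i in seq_len(cfg$n))
    out <- out + standard_model_kernel(t2[, i], b, cfg$kernels[i, ])
  if (is.matrix(p)) out else out[[1]]
}

#' Noiseless signal sample over a scheme
#'
#' Evaluates [mixture_signal()] over every shell of an acquisition scheme.
#'
#' @param cfg A [fiber_config()].
#' @param scheme An [acquisition_scheme()].
#' @return A `signal_sample`: a list with per-shell attenuation vectors `s`.
#' @export
simulate_signal <- function(cfg, scheme) {
  s <- lapply(scheme$shells, function(sh) mixture_signal(sh$dirs, sh$b, cfg))
  structure(list(s = s), class = "signal_sample")
}

#' Centered kernel decay curve
#'
#' The kernel decay function minus its integral over `[0, 1]`; the centered
#' curves are the identifiable per-fiber components of the additive signal
#' model. The subtracted mean uses the closed forms
#' `integral_0^1 exp(-b D t) dt = (1 - exp(-b D)) / (b D)` per compartment
#' (limit 1 as `b D -> 0`).
#'
#' @param k Kernel parameters.
#' @param b b-value (ms/um^2).
#' @param grid Evaluation points in `[0, 1]`.
#' @return Curve values on the grid; nonincreasing, integrating to zero.
#' @export
centered_kernel_curve <- function(k, b, grid) {
  standard_model_kernel(grid, b, k) - kernel_curve_mean(k, b)
}

as_kernel_vec <- function(k) {
  if (is.null(names(k)))
    names(k) <- c("Da", "De_par", "De_perp", "z1", "z2")
  k
}

kernel_curve_mean <- function(k, b) {
  k <- as_kernel_vec(k)
  k[["z1"]] * expmean1(b * k[["Da"]]) +
    k[["z2"]] * exp(-b * k[["De_perp"]]) * expmean1(b * (k[["De_par"]] - k[["De_perp"]]))
}

#' Add homoscedastic Gaussian measurement noise
#'
#' Adds iid Gaussian noise with variance `sigma_e2` to every measurement of
#' a signal sample (the measurement-error model on b0-normalized
#' attenuations).
#'
#' @param f A `signal_sample` (from [simulate_signal()]).
#' @param sigma_e2 Noise variance on the attenuation scale (nonnegative).
#' @param seed Optional integer seed for reproducibility.
#' @return A `signal_sample` with noisy per-shell vectors.
#' @export
add_noise <- function(f, sigma_e2, seed = NULL) {
  if (sigma_e2 < 0) stop("sigma_e2 must be nonnegative")
  if (sigma_e2 == 0) return(f)
  if (!is.null(seed)) set.seed(seed)
  f$s <- lapply(f$s, function(v) v + rnorm(length(v), sd = sqrt(sigma_e2)))
  f
}

#' Signal-to-noise ratio implied by a noise variance
#'
#' On the unit-normalized attenuation scale the SNR of the b = 0 signal is
#' `1 / sigma_e`, i.e. `1 / sqrt(sigma_e2)`.
#'
#' @param sigma_e2 Noise variance on the attenuation scale.
#' @return The SNR.
#' @export
noise_snr <- function(sigma_e2) 1 / sqrt(sigma_e2)
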