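#' Biologically constrained prior configuration
#'
#' The prior support for per-fiber kernel parameters and orientations:
#' parallel diffusivities uniform on `[0.2, 3]` um^2/ms, perpendicular
#' diffusivity positive and below `0.8 * De_par` (a polytope sampled by
#' rejection from a box proposal), orientations uniform on the hemisphere
#' subject to a minimum pairwise crossing angle of 10 degrees (and a
#' 30-degree floor on the second-smallest angle for three fibers), signal
#' fractions flat-Dirichlet on the simplex with every intra-axonal fraction
#' at least 0.1, and at most three fibers per voxel.
#'
#' @param diff_lo,diff_hi Parallel-diffusivity bounds (um^2/ms).
#' @param perp_factor Upper bound on `De_perp / De_par`.
#' @param min_cross_deg Minimum pairwise crossing angle (degrees).
#' @param second_min_deg Floor on the second-smallest angle for n = 3.
#' @param min_z1 Minimum intra-axonal signal fraction per fiber.
#' @param n_max Maximum number of fibers.
#' @param n_weights Prior weights over the fiber count (default uniform).
#' @param max_reject Iteration cap for the rejection loops.
#' @return A `prior_config` list.
#' @export
prior_config <- function(diff_lo = 0.2, diff_hi = 3.0, perp_factor = 0.8,
                         min_cross_deg = 10, second_min_deg = 30,
                         min_z1 = 0.1, n_max = 3,
                         n_weights = rep(1 / n_max, n_max),
                         max_reject = 1e6) {
  stopifnot(diff_lo > 0, diff_hi > diff_lo, perp_factor > 0)
  if (length(n_weights) != n_max || abs(sum(n_weights) - 1) > 1e-8)
    stop("n_weights must have length n_max and sum to 1")
  structure(
    list(diff_lo = diff_lo, diff_hi = diff_hi, perp_factor = perp_factor,
         min_cross_deg = min_cross_deg, second_min_deg = second_min_deg,
         min_z1 = min_z1, n_max = n_max, n_weights = n_weights,
         max_reject = max_reject),
    class = "prior_config")
}

reject_cap <- function(i, cfg, what) {
  if (i > cfg$max_reject)
    stop("rejection sampling for ", what, " exceeded ", cfg$max_reject,
         " iterations; check the prior configuration")
}

#' Sample a diffusivity triple from the polytope prior
#'
#' Uniform on the box `[diff_lo, diff_hi]^2 x (0, perp_factor * diff_hi]`,
#' rejecting until `De_perp < perp_factor * De_par`.
#'
#' @param cfg A [prior_config()].
#' @return Named vector `(Da, De_par, De_perp)`.
#' @export
sample_diffusivities <- function(cfg = prior_config()) {
  i <- 0
  repeat {
    i <- i + 1; reject_cap(i, cfg, "diffusivities")
    Da <- runif(1, cfg$diff_lo, cfg$diff_hi)
    De_par <- runif(1, cfg$diff_lo, cfg$diff_hi)
    De_perp <- runif(1, 0, cfg$perp_factor * cfg$diff_hi)
    if (De_perp > 0 && De_perp < cfg$perp_factor * De_par)
      return(c(Da = Da, De_par = De_par, De_perp = De_perp))
  }
}

#' Sample fiber orientations under the crossing-angle prior
#'
#' Uniform per-axis on the hemisphere, rejecting until all pairwise axial
#' angles are at least `min_cross_deg` degrees and, for n = 3, the
#' second-smallest pairwise angle is at least `second_min_deg` degrees.
#' Outputs are canonical hemisphere representatives.
#'
#' @param n Number of fibers (1 to `n_max`).
#' @param cfg A [prior_config()].
#' @return An `n` x 3 matrix of unit axes.
#' @export
sample_orientations <- function(n, cfg = prior_config()) {
  stopifnot(n >= 1, n <= cfg$n_max)
  i <- 0
  repeat {
    i <- i + 1; reject_cap(i, cfg, "orientations")
    m <- canonicalize_axis(normalize_rows(matrix(rnorm(3 * n), n, 3)))
    if (n == 1) return(m)
    ang <- pairwise_axial_angles(m) * 180 / pi
    if (min(ang) < cfg$min_cross_deg) next
    if (n == 3 && sort(ang)[2] < cfg$second_min_deg) next
    return(m)
  }
}

#' Sample signal fractions from the truncated flat Dirichlet
#'
#' Draws `2n` fractions (intra/extra per fiber) from a flat Dirichlet on the
#' simplex, rejecting while any intra-axonal fraction `z[i, 1]` is below
#' `min_z1`.
#'
#' @param n Number of fibers.
#' @param cfg A [prior_config()].
#' @return An `n` x 2 matrix with columns `z1`, `z2`, summing to 1 overall.
#' @export
sample_fractions <- function(n, cfg = prior_config()) {
  i <- 0
  repeat {
    i <- i + 1; reject_cap(i, cfg, "fractions")
    e <- -log(runif(2 * n))        # flat Dirichlet via normalized exponentials
    z <- matrix(e / sum(e), n, 2)
    if (all(z[, 1] >= cfg$min_z1)) {
      colnames(z) <- c("z1", "z2")
      return(z)
    }
  }
}

#' Sample the fiber count
#'
#' @param cfg A [prior_config()]; the prior over n is `cfg$n_weights`
#'   (default uniform on 1..3; the count prior is a modeling choice).
#' @return An integer fiber count.
#' @export
sample_fiber_count <- function(cfg = prior_config()) {
  sample.int(cfg$n_max, 1, prob = cfg$n_weights)
}

#' Sample one voxel configuration from the priors
#'
#' @param cfg A [prior_config()].
#' @param n Optional fixed fiber count; drawn from the count prior if `NULL`.
#' @return A [fiber_config()].
#' @export
sample_fiber_config <- function(cfg = prior_config(), n = NULL) {
  n <- n %||% sample_fiber_count(cfg)
  m <- sample_orientations(n, cfg)
  z <- sample_fractions(n, cfg)
  kern <- t(vapply(seq_len(n), function(i) {
    c(sample_diffusivities(cfg), z[i, ])
  }, numeric(5)))
  colnames(kern) <- c("Da", "De_par", "De_perp", "z1", "z2")
  fiber_config(m, kern)
}

#' Generate a labeled synthetic dataset
#'
#' Draws `N` independent voxel configurations from the biologically
#' constrained priors, simulates noiseless multi-shell attenuation signals,
#' adds homoscedastic Gaussian noise, and (optionally) renders target ODFs
#' on a sphere mesh for inverter training. Fully reproducible under a seed.
#'
#' @param N Number of voxels.
#' @param scheme An [acquisition_scheme()].
#' @param sigma_e2 Noise variance on the attenuation scale.
#' @param cfg A [prior_config()].
#' @param seed Integer seed.
#' @param n Optional fixed fiber count for all voxels.
#' @param odf_spec Optional [odf_target_spec()]; when supplied, target ODFs
#'   are rendered on its mesh.
#' @return A `labeled_dataset`: list with `params` (a tibble, one row per
#'   fiber with voxel id, count, orientation and kernel columns), `configs`
#'   (list of [fiber_config()]), `clean` and `noisy` (N x sum(M) signal
#'   matrices, shells concatenated), `odf` (N x V matrix or `NULL`),
#'   `scheme`, `sigma_e2`, `seed`.
#' @export
generate_dataset <- function(N, scheme = default_scheme(), sigma_e2 = 0.0620^2,
                             cfg = prior_config(), seed = 1L, n = NULL,
                             odf_spec = NULL) {
  stopifnot(N >= 1)
  set.seed(seed)
  sizes <- scheme_sizes(scheme)
  configs <- vector("list", N)
  clean <- noisy <- matrix(NA_real_, N, sum(sizes))
  odf <- if (!is.null(odf_spec)) matrix(NA_real_, N, nrow(odf_spec$mesh$vertices))
  for (v in seq_len(N)) {
    fc <- sample_fiber_config(cfg, n = n)
    configs[[v]] <- fc
    f <- simulate_signal(fc, scheme)
    clean[v, ] <- unlist(f$s)
    noisy[v, ] <- unlist(add_noise(f, sigma_e2)$s)
    if (!is.null(odf_spec)) odf[v, ] <- render_target_odf(fc, odf_spec)$g
  }
  params <- purrr::map_dfr(seq_len(N), function(v) {
    fc <- configs[[v]]
    tibble::tibble(
      voxel = v, n = fc$n, fiber = seq_len(fc$n),
      mx = fc$orientations[, 1], my = fc$orientations[, 2],
      mz = fc$orientations[, 3],
      tibble::as_tibble(fc$kernels))
  })
  structure(
    list(params = params, configs = configs, clean = clean, noisy = noisy,
         odf = odf, scheme = scheme, sigma_e2 = sigma_e2, seed = seed),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset>", nrow(x$clean), "voxels,",
      length(x$scheme$shells), "shells, sigma_e2 =", signif(x$sigma_e2, 4),
      "\n")
  invisible(x)
}

dataset_signal_sample <- function(ds, v, noisy = TRUE) {
  sizes <- scheme_sizes(ds$scheme)
  ends <- cumsum(sizes); starts <- c(1, head(ends, -1) + 1)
  row <- if (noisy) ds$noisy[v, ] else ds$clean[v, ]
  structure(list(s = Map(function(a, b) row[a:b], starts, ends)),
            class = "signal_sample")
}

#' Write / read a labeled dataset
#'
#' Serializes a dataset to a directory: parameter table and signal matrices
#' as CSV, plus a JSON metadata file recording the scheme, noise level and
#' seed.
#'
#' @param ds A `labeled_dataset`.
#' @param path Directory to create.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the reconstructed `labeled_dataset` (without rendered ODF targets).
#' @export
write_dataset <- function(ds, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ds$params, file.path(path, "params.csv"), row.names = FALSE)
  utils::write.csv(ds$clean, file.path(path, "signals_clean.csv"), row.names = FALSE)
  utils::write.csv(ds$noisy, file.path(path, "signals_noisy.csv"), row.names = FALSE)
  meta <- list(
    sigma_e2 = ds$sigma_e2, seed = ds$seed, n_b0 = ds$scheme$n_b0,
    bvals = scheme_bvals(ds$scheme),
    dirs = lapply(ds$scheme$shells, function(sh) unname(sh$dirs)))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @param path Directory created by [write_dataset()].
#' @export
read_dataset <- function(path) {
  params <- tibble::as_tibble(utils::read.csv(file.path(path, "params.csv")))
  clean <- as.matrix(utils::read.csv(file.path(path, "signals_clean.csv")))
  noisy <- as.matrix(utils::read.csv(file.path(path, "signals_noisy.csv")))
  dimnames(clean) <- dimnames(noisy) <- NULL
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  dirs <- meta$dirs
  if (is.array(dirs) && length(dim(dirs)) == 3)
    dirs <- lapply(seq_len(dim(dirs)[1]), function(l) dirs[l, , ])
  scheme <- acquisition_scheme(meta$bvals,
                               lapply(dirs, function(d)
                                 unname(as.matrix(d))),
                               n_b0 = meta$n_b0)
  configs <- lapply(split(params, params$voxel), function(df) {
    fiber_config(as.matrix(df[, c("mx", "my", "mz")]),
                 as.matrix(df[, c("Da", "De_par", "De_perp", "z1", "z2")]))
  })
  names(configs) <- NULL
  structure(
    list(params = params, configs = configs, clean = clean, noisy = noisy,
         odf = NULL, scheme = scheme, sigma_e2 = meta$sigma_e2,
         seed = meta$seed),
    class = "labeled_dataset")
}
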