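#' Estimate the measurement-noise variance from b = 0 images
#'
#' Each voxel's b = 0 measurements are normalized by their mean, the
#' per-voxel empirical variance of the normalized values is computed, and
#' the variances are averaged over voxels — an asymptotically unbiased
#' estimator of the noise variance on the attenuation scale.
#'
#' @param b0 A `voxels x repeats` matrix of b = 0 measurements (at least 2
#'   repeats), or a vector for a single voxel.
#' @return The estimated noise variance `sigma_e2`.
#' @export
estimate_sigma_e <- function(b0) {
  if (is.null(dim(b0))) b0 <- matrix(b0, nrow = 1)
  if (ncol(b0) < 2)
    stop("at least two b = 0 measurements per voxel are required")
  means <- rowMeans(b0)
  ok <- means > 0
  norm <- b0[ok, , drop = FALSE] / means[ok]
  mean(apply(norm, 1, var))
}

#' Classify bootstrap peaks to the estimated orientations
#'
#' For each bootstrap replicate, peaks are assigned one-to-one to the
#' estimated orientations by greedy closest-pair matching on the axial
#' angle; at most one peak is assigned per estimate per replicate, and
#' unassigned (excess) peaks are discarded.
#'
#' @param peaks_list List over replicates; each element an `n_b x 3` matrix
#'   of replicate peak axes (possibly empty).
#' @param m_hat `n x 3` matrix of estimated orientations.
#' @return A list with `sets` (per estimate, a matrix of assigned axes over
#'   replicates) and `discarded` (total count of discarded peaks).
#' @export
classify_bootstrap_peaks <- function(peaks_list, m_hat) {
  if (!is.matrix(m_hat)) m_hat <- matrix(m_hat, nrow = 1)
  if (nrow(m_hat) == 0) stop("m_hat must be nonempty")
  n <- nrow(m_hat)
  sets <- lapply(seq_len(n), function(i) matrix(numeric(0), 0, 3))
  discarded <- 0L
  for (pk in peaks_list) {
    if (is.null(pk) || nrow(pk) == 0) next
    ang <- matrix(0, nrow(pk), n)
    for (j in seq_len(nrow(pk)))
      for (i in seq_len(n)) ang[j, i] <- axial_angle(pk[j, ], m_hat[i, ])
    avail_p <- rep(TRUE, nrow(pk)); avail_e <- rep(TRUE, n)
    repeat {
      sub <- ang
      sub[!avail_p, ] <- Inf
      sub[, !avail_e] <- Inf
      if (all(!is.finite(sub))) break
      idx <- arrayInd(which.min(sub), dim(sub))
      sets[[idx[2]]] <- rbind(sets[[idx[2]]], pk[idx[1], ])
      avail_p[idx[1]] <- FALSE; avail_e[idx[2]] <- FALSE
      if (!any(avail_p) || !any(avail_e)) break
    }
    discarded <- discarded + sum(avail_p)
  }
  list(sets = sets, discarded = discarded)
}

#' Detection rate and angular dispersion of a bootstrap orientation set
#'
#' `DR = |set| / B` is the fraction of replicates in which the fiber was
#' detected. `AD = asin(sqrt(1 - lambda_max))`, with `lambda_max` the
#' largest eigenvalue of the mean outer product of the assigned axes,
#' measures their angular spread: 0 when all replicates agree, up to
#' `asin(sqrt(2/3))` (about 0.955 rad) for uniformly scattered axes.
#'
#' @param set Matrix of assigned bootstrap axes (rows), possibly empty.
#' @param B Number of bootstrap replicates.
#' @return A list with `DR` and `AD` (`AD` is `NA` for an empty set).
#' @export
dr_ad <- function(set, B) {
  stopifnot(B >= 1)
  if (is.null(set) || nrow(set) == 0) return(list(DR = 0, AD = NA_real_))
  scatter <- crossprod(set) / nrow(set)
  lam <- max(eigen(scatter, symmetric = TRUE, only.values = TRUE)$values)
  list(DR = nrow(set) / B,
       AD = asin(sqrt(pmin(1, pmax(0, 1 - lam)))))
}

#' Full sequential inference for one voxel
#'
#' Runs the complete estimation and uncertainty-quantification algorithm on
#' one voxel's multi-shell signals: a pilot per-shell spherical-harmonic
#' fit; ODF inversion through the trained inverter and peak detection
#' (giving the fiber count and orientations); a parametric bootstrap around
#' the *fitted* signals (re-noised at the estimated noise variance, refitted
#' and re-inverted) for orientation uncertainty (detection rate and angular
#' dispersion per fiber); signal demixing conditional on the estimated
#' orientations; and per-fiber amortized posterior sampling with
#' posterior-mean and approximate-MAP point estimates and marginal
#' highest-density regions. Fully reproducible under a seed.
#'
#' @param s A `signal_sample`.
#' @param scheme The [acquisition_scheme()].
#' @param inverter A trained [inverter_model()].
#' @param mdn_models Named list of trained [mdn_model()]s keyed by fiber
#'   count (`"1"`, `"2"`, `"3"`); only the selected count's model is used.
#' @param sigma_e2 Estimated noise variance (e.g. [estimate_sigma_e()]).
#' @param Q Posterior sample count (default 5000).
#' @param B Bootstrap replicates (default 1000).
#' @param alpha HDR miscoverage level (default 0.05).
#' @param seed Seed.
#' @param sh_lambda Ridge weight for the pilot SH fits (default 0).
#' @param peak_args List of arguments for [find_odf_peaks()].
#' @return An `inference_result` with the fiber count, orientations,
#'   bootstrap sets, DR/AD, posterior samples, PM/MAP estimates, HDRs and
#'   diagnostics; or a degenerate result (`n = 0`) when no peaks are found.
#' @export
run_inference <- function(s, scheme, inverter, mdn_models, sigma_e2,
                          Q = 5000, B = 1000, alpha = 0.05, seed = 1L,
                          sh_lambda = 0, peak_args = list()) {
  stopifnot(Q >= 1, B >= 1)
  set.seed(seed)
  basis <- sh_basis(inverter$degree_in)
  ops <- inverter_ops(inverter)

  # pilot fit: per-shell coefficients and fitted (smoothed) signals
  hat_ops <- lapply(scheme$shells, function(sh) {
    phi <- sh_eval_matrix(basis, sh$dirs)
    a <- crossprod(phi)
    if (sh_lambda > 0) a <- a + sh_lambda * diag(basis$l^2 * (basis$l + 1)^2)
    list(phi = phi, solve_op = solve(a, t(phi)))
  })
  coeffs <- vapply(seq_along(scheme$shells), function(l)
    (hat_ops[[l]]$solve_op %*% s$s[[l]])[, 1], numeric(basis$K))
  fitted <- lapply(seq_along(scheme$shells), function(l)
    as.vector(hat_ops[[l]]$phi %*% coeffs[, l]))

  odf <- invert_coeffs(inverter, coeffs, ops)
  pk <- do.call(find_odf_peaks, c(list(odf), peak_args))
  if (pk$n == 0) {
    return(structure(list(n = 0, degenerate = TRUE, odf = odf,
                          diagnostics = list(sigma_e2 = sigma_e2,
                                             seed = seed)),
                     class = "inference_result"))
  }
  m_hat <- pk$orientations

  # parametric bootstrap around the fitted signals, batched inversion
  boot_coeffs <- lapply(seq_along(scheme$shells), function(l) {
    M <- length(fitted[[l]])
    noise <- matrix(rnorm(M * B, sd = sqrt(sigma_e2)), M, B)
    hat_ops[[l]]$solve_op %*% (fitted[[l]] + noise)
  })
  boot_vals <- invert_coeffs(inverter, boot_coeffs, ops, as_grid = FALSE)
  boot_peaks <- lapply(seq_len(B), function(b) {
    og <- odf_grid(boot_vals[, b], ops$mesh)
    do.call(find_odf_peaks, c(list(og), peak_args))$orientations
  })
  cls <- classify_bootstrap_peaks(boot_peaks, m_hat)
  uq <- lapply(cls$sets, dr_ad, B = B)

  # demixing conditional on the estimated orientations
  spb <- spline_basis()
  dm <- fit_additive_model(s, build_design(scheme, m_hat, spb), spb)

  # per-fiber posterior sampling, joint simplex projection, PM/MAP/HDR
  key <- as.character(pk$n)
  if (is.null(mdn_models[[key]]))
    stop("no trained MDN for n = ", pk$n)
  samples <- lapply(seq_len(pk$n), function(i)
    sample_posterior(mdn_models[[key]], demixed_input(dm, i), Q = Q))
  samples <- project_fractions(samples)
  pm <- lapply(samples, posterior_mean)
  map <- map_estimate(samples, s, scheme, m_hat, max(sigma_e2, 1e-12))
  sup <- kernel_supports()
  hdrs <- lapply(samples, function(sm)
    lapply(names(sup), function(p) hdr(sm[, p], alpha, sup[[p]])) |>
      setNames(names(sup)))

  structure(
    list(n = pk$n, orientations = m_hat, peak_heights = pk$heights,
         degenerate = pk$degenerate, odf = odf,
         bootstrap_sets = cls$sets, discarded_peaks = cls$discarded,
         dr = vapply(uq, `[[`, numeric(1), "DR"),
         ad = vapply(uq, function(u) u$AD %||% NA_real_, numeric(1)),
         curves = dm, samples = samples, pm = pm,
         map = map$estimates, map_index = map$index, hdrs = hdrs,
         diagnostics = list(sigma_e2 = sigma_e2, seed = seed, Q = Q, B = B,
                            alpha = alpha)),
    class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("<inference_result> n =", x$n, "\n")
  if (x$n > 0) {
    cat("  DR:", round(x$dr, 3), "| AD (rad):", round(x$ad, 3), "\n")
    for (i in seq_len(x$n))
      cat("  fiber", i, "PM:", round(x$pm[[i]], 3), "\n")
  }
  invisible(x)
}

#' Tidy an inference result
#'
#' @param x An `inference_result`.
#' @param ... Unused.
#' @return A tibble with one row per fiber and parameter: PM and MAP
#'   estimates, HDR interval count and total relative size, DR and AD.
#' @export
tidy.inference_result <- function(x, ...) {
  if (x$n == 0) return(tibble::tibble())
  sup <- kernel_supports()
  purrr::map_dfr(seq_len(x$n), function(i)
    purrr::map_dfr(names(sup), function(p)
      tibble::tibble(
        fiber = i, parameter = p,
        pm = x$pm[[i]][[p]], map = x$map[[i]][[p]],
        hdr_intervals = nrow(x$hdrs[[i]][[p]]),
        hdr_rel_size = hdr_size(x$hdrs[[i]][[p]], sup[[p]]),
        dr = x$dr[i], ad = x$ad[i])))
}

#' Plot the marginal posteriors of an inference result
#'
#' Histograms of the posterior samples per fiber and parameter with the
#' PM/MAP estimates marked.
#'
#' @param x An `inference_result` with `n >= 1`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inference_result <- function(x, ...) {
  if (x$n == 0) stop("degenerate result (no fibers detected)")
  df <- purrr::map_dfr(seq_len(x$n), function(i)
    tidyr::pivot_longer(
      tibble::as_tibble(x$samples[[i]]),
      dplyr::everything(), names_to = "parameter") |>
      dplyr::mutate(fiber = i))
  pts <- tidy.inference_result(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey65") +
    ggplot2::geom_vline(data = pts,
                        ggplot2::aes(xintercept = .data$pm, colour = "PM")) +
    ggplot2::geom_vline(data = pts,
                        ggplot2::aes(xintercept = .data$map, colour = "MAP")) +
    ggplot2::facet_grid(fiber ~ parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior draws", colour = NULL) +
    ggplot2::theme_minimal()
}
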