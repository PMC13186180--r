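#' Target-ODF rendering specification
#'
#' Settings for rendering ground-truth ODFs used as inverter training
#' targets: the Watson concentration (large, matching the high-concentration
#' forward-model assumption) and the sphere mesh. The default concentration
#' of 50 keeps essentially all of the target's energy inside the inverter's
#' even-degree-16 harmonic system on a level-4 mesh while remaining sharply
#' peaked (angular spread of a few degrees).
#'
#' @param kappa Watson concentration for the rendered targets (default 50).
#' @param mesh A [sphere_mesh()] (default level 4).
#' @return An `odf_target_spec`.
#' @export
odf_target_spec <- function(kappa = 50, mesh = default_mesh(4)) {
  stopifnot(kappa > 0)
  structure(list(kappa = kappa, mesh = mesh), class = "odf_target_spec")
}

#' Render the ground-truth ODF of a fiber configuration
#'
#' The equal-weight Watson mixture `n^{-1} sum_i Watson(m_i, kappa)`,
#' rendered on the mesh vertices and normalized to unit hemisphere mass.
#'
#' @param cfg A [fiber_config()].
#' @param spec An [odf_target_spec()].
#' @return An [odf_grid()].
#' @export
render_target_odf <- function(cfg, spec = odf_target_spec()) {
  v <- spec$mesh$vertices
  g <- numeric(nrow(v))
  for (i in seq_len(cfg$n))
    g <- g + watson_density(v, cfg$orientations[i, ], spec$kappa)
  odf_grid(g / cfg$n, spec$mesh)
}

# per-coefficient degree-block id for a basis
deg_index <- function(basis) match(basis$l, seq(0, basis$degree, by = 2))

# hemisphere synthesis/adjoint operators, cached per (mesh, degree);
# for antipodally symmetric functions the sphere quadrature is twice the
# hemisphere quadrature, so the adjoint uses doubled vertex weights.
mesh_hemi_ops <- function(mesh, degree) {
  key <- paste0("hemi_", mesh$subdiv, "_", degree)
  if (is.null(.mesh_cache[[key]])) {
    hemi <- which(seq_len(nrow(mesh$vertices)) <= mesh$antipode)
    phi <- sh_eval_matrix(sh_basis(degree), mesh$vertices[hemi, ])
    .mesh_cache[[key]] <- list(
      hemi = hemi, phi = phi, aw = t(phi * (2 * mesh$weights[hemi])))
  }
  .mesh_cache[[key]]
}

# mirror hemisphere values back to the full mesh
hemi_to_full <- function(vals, mesh, hemi) {
  out <- numeric(nrow(mesh$vertices))
  out[hemi] <- vals
  out[mesh$antipode[hemi]] <- vals
  out
}

#' Signal-to-ODF inverter model
#'
#' A rotation-equivariant operator mapping the multi-shell
#' spherical-harmonic signal representation to a discretized ODF, trained
#' on simulated pairs by empirical Bayes-risk minimization. The
#' architecture is an unrolled positive-deconvolution network with a
#' conditioned response:
#'
#' 1. *Conditioned response.* Per-degree, per-shell deconvolution kernels
#'    are predicted from rotation-invariant signal features (per-shell mean
#'    attenuation and normalized degree-2/4 spectral power) through
#'    regression coefficients learned from the training set. Conditioning
#'    on invariants preserves rotational equivariance exactly.
#' 2. *Unrolled constrained deconvolution.* A fixed number of ADMM
#'    iterations solve the super-resolved (degree-12), nonnegativity-
#'    constrained spherical deconvolution of the signal by the predicted
#'    response; the nonnegativity projection is pointwise on the mesh and
#'    therefore equivariant.
#' 3. *Spectral output head.* Learned per-degree gains (a rotationally
#'    symmetric filter, degree-16 system) calibrate the deconvolved field
#'    to the equal-weight Watson target ODF.
#'
#' Every weight acts per degree or pointwise, so the map commutes with
#' rotations up to mesh quadrature error.
#'
#' @param L Number of input channels (shells).
#' @param mesh_subdiv Icosphere subdivision level (default 4).
#' @param degree_in Even SH degree of the input signal fits (default 8).
#' @param degree_deconv Even SH degree of the super-resolved deconvolution
#'   (default 12).
#' @param degree_out Even SH degree of the output system (default 16).
#' @param rho ADMM augmented-Lagrangian weight (default 0.02).
#' @param admm_iters Number of unrolled ADMM iterations (default 60).
#' @param seed Seed for the (small) random initialization.
#' @return An `inverter_model`.
#' @export
inverter_model <- function(L = 2, mesh_subdiv = 4, degree_in = 8,
                           degree_deconv = 12, degree_out = 16,
                           rho = 0.02, admm_iters = 60, seed = 1L) {
  set.seed(seed)
  D_in <- degree_in / 2 + 1
  nf <- 1 + 3 * L
  params <- list(
    beta = array(rnorm(D_in * L * nf, sd = 0.05), c(D_in, L, nf)),
    gains = rep(0.1, degree_out / 2 + 1))
  structure(
    list(L = L, mesh_subdiv = mesh_subdiv, degree_in = degree_in,
         degree_deconv = degree_deconv, degree_out = degree_out,
         rho = rho, admm_iters = admm_iters, params = params,
         trained = FALSE, history = NULL, seed = seed),
    class = "inverter_model")
}

#' @export
print.inverter_model <- function(x, ...) {
  cat("<inverter_model>", x$L, "channels, degree", x$degree_in, "->",
      x$degree_deconv, "(deconv) ->", x$degree_out, "(out),",
      x$admm_iters, "ADMM iterations,",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

inverter_ops <- function(model) {
  mesh <- default_mesh(model$mesh_subdiv)
  basis_in <- sh_basis(model$degree_in)
  basis_dc <- sh_basis(model$degree_deconv)
  basis_out <- sh_basis(model$degree_out)
  hops_dc <- mesh_hemi_ops(mesh, model$degree_deconv)
  hops_out <- mesh_hemi_ops(mesh, model$degree_out)
  ops_out <- mesh_sh_operators(mesh, basis_out)
  key <- paste0("gram_", model$mesh_subdiv, "_", model$degree_out)
  if (is.null(.mesh_cache[[key]]))
    .mesh_cache[[key]] <- crossprod(ops_out$synthesis)
  list(mesh = mesh, basis_in = basis_in, basis_dc = basis_dc,
       basis_out = basis_out, hops_dc = hops_dc, hops_out = hops_out,
       phi_out = ops_out$synthesis, gram_out = .mesh_cache[[key]],
       deg_in = deg_index(basis_in), deg_dc = deg_index(basis_dc),
       deg_out = deg_index(basis_out))
}

# rotation-invariant conditioning features from per-shell degree-`in` SH
# coefficients; cin is a list (length L) of K_in x B matrices.
inverter_features <- function(cin, deg_in) {
  L <- length(cin)
  B <- ncol(cin[[1]])
  f <- matrix(0, B, 1 + 3 * L)
  f[, 1] <- 1
  for (ch in seq_len(L)) {
    c0 <- cin[[ch]][1, ]
    p2 <- sqrt(colSums(cin[[ch]][deg_in == 2, , drop = FALSE]^2))
    p4 <- sqrt(colSums(cin[[ch]][deg_in == 3, , drop = FALSE]^2))
    f[, 3 * ch - 1] <- c0 / sqrt(4 * pi)
    f[, 3 * ch]     <- p2 / pmax(c0, 1e-9)
    f[, 3 * ch + 1] <- p4 / pmax(c0, 1e-9)
  }
  f
}

# unrolled ADMM nonnegative deconvolution; returns hemisphere field (Vh x B)
inverter_deconv <- function(model, cin, ops) {
  L <- model$L
  B <- ncol(cin[[1]])
  feats <- inverter_features(cin, ops$deg_in)
  D_in <- dim(model$params$beta)[1]
  K_dc <- ops$basis_dc$K
  idx_in <- which(ops$basis_dc$l <= model$degree_in)
  Hc <- matrix(0, K_dc, B)
  H2 <- matrix(0, K_dc, B)
  for (ch in seq_len(L)) {
    Hch <- matrix(0, K_dc, B)
    for (d in seq_len(D_in)) {
      rows <- which(ops$deg_dc == d)
      Hch[rows, ] <- rep(feats %*% model$params$beta[d, ch, ], each = length(rows))
    }
    full <- matrix(0, K_dc, B)
    full[idx_in, ] <- cin[[ch]]
    Hc <- Hc + Hch * full
    H2 <- H2 + Hch^2
  }
  denom <- H2 + model$rho
  phi <- ops$hops_dc$phi
  aw <- ops$hops_dc$aw
  z <- u <- matrix(0, nrow(phi), B)
  c_g <- NULL
  for (t in seq_len(model$admm_iters)) {
    c_g <- (Hc + model$rho * (aw %*% (z - u))) / denom
    fg <- phi %*% c_g
    z <- pmax(fg + u, 0)
    u <- u + fg - z
  }
  pmax(phi %*% c_g, 0)
}

# output coefficients (degree_out system) from hemisphere deconv field
inverter_head <- function(model, g_hemi, ops) {
  model$params$gains[ops$deg_out] * (ops$hops_out$aw %*% g_hemi)
}

# full forward: per-shell degree_in coefficient channels -> output coeffs
inverter_forward <- function(model, cin, ops) {
  inverter_head(model, inverter_deconv(model, cin, ops), ops)
}

#' Empirical Bayes risk of an inverter on a labeled dataset
#'
#' The mean over samples of the squared vertex-wise error between the
#' rendered target ODF and the inverter output.
#'
#' @param model An [inverter_model()].
#' @param ds A `labeled_dataset` generated with ODF targets on the model's
#'   mesh.
#' @param idx Optional subset of sample indices.
#' @return Mean squared-error risk (summed over vertices, averaged over
#'   samples).
#' @export
inverter_risk <- function(model, ds, idx = NULL) {
  if (is.null(ds$odf)) stop("dataset has no rendered ODF targets")
  ops <- inverter_ops(model)
  idx <- idx %||% seq_len(nrow(ds$noisy))
  cin <- dataset_sh_coeffs(ds, model$degree_in)
  cin <- lapply(cin, function(m) m[, idx, drop = FALSE])
  out <- inverter_forward(model, cin, ops)
  diff <- ops$phi_out %*% out - t(ds$odf[idx, , drop = FALSE])
  mean(colSums(diff^2))
}

# per-shell SH coefficient channels (list of K x N) for a whole dataset
dataset_sh_coeffs <- function(ds, degree, noisy = TRUE, lambda = 0) {
  basis <- sh_basis(degree)
  sizes <- scheme_sizes(ds$scheme)
  ends <- cumsum(sizes); starts <- c(1, head(ends, -1) + 1)
  sig <- if (noisy) ds$noisy else ds$clean
  lapply(seq_along(ds$scheme$shells), function(l) {
    phi <- sh_eval_matrix(basis, ds$scheme$shells[[l]]$dirs)
    a <- crossprod(phi)
    if (lambda > 0) a <- a + lambda * diag(basis$l^2 * (basis$l + 1)^2)
    solve(a, t(phi)) %*% t(sig[, starts[l]:ends[l], drop = FALSE])
  })
}

#' Train the inverter by empirical Bayes-risk minimization
#'
#' Training proceeds in three phases on the simulated signal/target pairs:
#' the conditioned-response regression is solved in closed form per degree;
#' the unrolled deconvolution is run over the training set; and the
#' spectral output head is fitted to the rendered targets by
#' ridge-penalized risk minimization, initialized in closed form and then
#' refined with minibatch Adam on the penalized empirical risk. A held-out
#' fraction monitors the risk before and after training.
#'
#' @param ds A `labeled_dataset` with rendered ODF targets.
#' @param model An [inverter_model()].
#' @param iterations Adam iterations for the head refinement (default 200).
#' @param batch Minibatch size (default 256).
#' @param lr Learning rate (default 5e-3).
#' @param ridge Relative ridge weight shrinking per-degree gains with
#'   little spectral support (default 0.01; prevents clutter-amplifying
#'   gains at degrees the deconvolution barely populates).
#' @param holdout Fraction of samples held out for monitoring.
#' @param seed Seed controlling shuffling.
#' @return The trained `inverter_model` with `history`, `risk_before`,
#'   `risk_after` and the held-out index set.
#' @export
train_inverter <- function(ds, model = inverter_model(L = length(ds$scheme$shells)),
                           iterations = 200, batch = 256, lr = 5e-3,
                           ridge = 0.01, holdout = 0.1, seed = 1L) {
  if (is.null(ds$odf)) stop("dataset has no rendered ODF targets")
  ops <- inverter_ops(model)
  if (ncol(ds$odf) != nrow(ops$mesh$vertices))
    stop("ODF targets do not match the model mesh")
  set.seed(seed)
  N <- nrow(ds$noisy)
  n_hold <- max(1, round(holdout * N))
  hold <- sample.int(N, n_hold)
  trn <- setdiff(seq_len(N), hold)

  cin_all <- dataset_sh_coeffs(ds, model$degree_in)
  # target projections in the output system (full-sphere operators)
  ops_out_full <- mesh_sh_operators(ops$mesh, ops$basis_out)
  tgt_coef <- ops_out_full$analysis %*% t(ds$odf)   # K_out x N
  tgt_t <- crossprod(ops$phi_out, t(ds$odf))        # Phi' g
  g2 <- rowSums(ds$odf^2)

  risk_before <- inverter_risk_cached(model, cin_all, tgt_t, g2, hold, ops)

  # phase 1: conditioned-response regression, closed form per (degree, shell)
  feats <- inverter_features(cin_all, ops$deg_in)
  D_in <- dim(model$params$beta)[1]
  nf <- ncol(feats)
  idx_out_in <- which(ops$basis_out$l <= model$degree_in)
  for (d in seq_len(D_in)) {
    rows <- idx_out_in[ops$deg_out[idx_out_in] == d]
    co_odf <- tgt_coef[rows, trn, drop = FALSE]
    for (ch in seq_len(model$L)) {
      y <- as.vector(cin_all[[ch]][which(ops$deg_in == d), trn, drop = FALSE])
      X <- do.call(cbind, lapply(seq_len(nf), function(j)
        as.vector(co_odf * rep(feats[trn, j], each = nrow(co_odf)))))
      model$params$beta[d, ch, ] <-
        solve(crossprod(X) + 1e-8 * diag(nf), crossprod(X, y))
    }
  }

  # phase 2: unrolled deconvolution over the training set (chunked)
  Vh <- nrow(ops$hops_dc$phi)
  g_dc <- matrix(0, Vh, N)
  for (st in seq(1, N, by = 512)) {
    en <- min(st + 511, N)
    g_dc[, st:en] <- inverter_deconv(
      model, lapply(cin_all, function(x) x[, st:en, drop = FALSE]), ops)
  }
  Ag <- ops$hops_out$aw %*% g_dc                    # K_out x N channel coeffs

  # phase 3: spectral head, ridge closed form then Adam refinement
  D_out <- length(model$params$gains)
  pbar <- mean(rowSums(Ag[, trn, drop = FALSE]^2))
  lam <- ridge * length(trn) * pbar
  for (d in seq_len(D_out)) {
    rows <- which(ops$deg_out == d)
    x <- as.vector(Ag[rows, trn, drop = FALSE])
    y <- as.vector(tgt_coef[rows, trn, drop = FALSE])
    model$params$gains[d] <- sum(x * y) / (sum(x^2) + lam)
  }
  mom <- vel <- numeric(D_out)
  hist_it <- hist_loss <- numeric(0)
  V <- nrow(ops$mesh$vertices)
  for (it in seq_len(iterations)) {
    idx <- sample(trn, min(batch, length(trn)))
    out <- model$params$gains[ops$deg_out] * Ag[, idx, drop = FALSE]
    resid_c <- ops$gram_out %*% out - tgt_t[, idx, drop = FALSE]
    dout <- 2 * resid_c * Ag[, idx, drop = FALSE]
    grad <- rowsum(rowSums(dout), ops$deg_out)[, 1] / (length(idx) * V) +
      2 * ridge * pbar * model$params$gains / V
    mom <- 0.9 * mom + 0.1 * grad
    vel <- 0.999 * vel + 0.001 * grad^2
    model$params$gains <- model$params$gains -
      lr * (mom / (1 - 0.9^it)) / (sqrt(vel / (1 - 0.999^it)) + 1e-8)
    if (it %% 25 == 0 || it == iterations) {
      loss <- mean(g2[idx] - 2 * colSums(out * tgt_t[, idx, drop = FALSE]) +
                     colSums(out * (ops$gram_out %*% out)))
      hist_it <- c(hist_it, it); hist_loss <- c(hist_loss, loss)
    }
  }
  model$trained <- TRUE
  model$history <- tibble::tibble(iteration = hist_it, batch_risk = hist_loss)
  model$risk_before <- risk_before
  model$risk_after <- inverter_risk_cached(model, cin_all, tgt_t, g2, hold, ops)
  model$holdout <- hold
  model
}

inverter_risk_cached <- function(model, cin_all, tgt_t, g2, idx, ops) {
  cin <- lapply(cin_all, function(x) x[, idx, drop = FALSE])
  out <- inverter_forward(model, cin, ops)
  mean(g2[idx] - 2 * colSums(out * tgt_t[, idx, drop = FALSE]) +
         colSums(out * (ops$gram_out %*% out)))
}

#' Invert a mesh-discretized signal to an ODF
#'
#' Applies the trained inverse operator to the per-shell signal values on
#' the mesh and post-processes the output into a valid discretized ODF
#' (clamped nonnegative, antipodally symmetrized, hemisphere-renormalized).
#' The output lives in the model's even-degree harmonic system, so peak
#' localization operates on a smooth band-limited representation.
#'
#' @param model A trained [inverter_model()].
#' @param f_mesh A `V x L` matrix of per-shell signal values on the model's
#'   mesh vertices (typically SH fits evaluated on the mesh).
#' @return An [odf_grid()].
#' @export
invert_signal <- function(model, f_mesh) {
  if (!model$trained)
    warning("inverter has not been trained; returning raw output")
  ops <- inverter_ops(model)
  ops_in <- mesh_sh_operators(ops$mesh, ops$basis_in)
  cin <- lapply(seq_len(model$L), function(ch)
    ops_in$analysis %*% f_mesh[, ch, drop = FALSE])
  out <- inverter_forward(model, cin, ops)
  odf_grid(as.vector(ops$phi_out %*% out), ops$mesh)
}

# fast path: invert from per-shell degree_in coefficients (K_in x L matrix,
# or a list of K_in x B batches); returns odf_grid (single) or V x B matrix
invert_coeffs <- function(model, coeffs, ops = inverter_ops(model),
                          as_grid = TRUE) {
  cin <- if (is.list(coeffs)) coeffs
    else lapply(seq_len(model$L), function(ch) coeffs[, ch, drop = FALSE])
  out <- inverter_forward(model, cin, ops)
  vals <- ops$phi_out %*% out
  if (as_grid && ncol(vals) == 1) odf_grid(as.vector(vals), ops$mesh)
  else vals
}

#' Model selection from an estimated ODF
#'
#' The number of fibers and their orientations are read off as the modes of
#' the estimated ODF.
#'
#' @param odf An [odf_grid()].
#' @param ... Passed to [find_odf_peaks()].
#' @return A list with `n`, `orientations` and peak diagnostics.
#' @export
select_model <- function(odf, ...) {
  find_odf_peaks(odf, ...)
}

#' Equivariance error of an inverter
#'
#' Median over random rotations of the relative discrepancy
#' `||A(R f) - R A(f)|| / ||A(f)||`, where rotation of mesh functions is by
#' band-limited spherical-harmonic resampling.
#'
#' @param model A trained [inverter_model()].
#' @param ds Dataset supplying test signals.
#' @param n_rot Number of random rotations (default 20).
#' @param seed Seed.
#' @return Median relative equivariance error.
#' @export
equivariance_error <- function(model, ds, n_rot = 20, seed = 1L) {
  set.seed(seed)
  ops <- inverter_ops(model)
  ops_in <- mesh_sh_operators(ops$mesh, ops$basis_in)
  cin_all <- dataset_sh_coeffs(ds, model$degree_in)
  N <- ncol(cin_all[[1]])
  errs <- vapply(seq_len(n_rot), function(r) {
    i <- sample.int(N, 1)
    rot <- random_rotation()
    cin <- lapply(cin_all, function(x) x[, i, drop = FALSE])
    g0 <- as.vector(invert_coeffs(model, cin, ops, as_grid = FALSE))
    g0_rot <- rotate_mesh_function(g0, rot, ops$mesh, model$degree_out)
    f_mesh <- vapply(cin, function(x) as.vector(ops_in$synthesis %*% x),
                     numeric(nrow(ops$mesh$vertices)))
    f_rot <- rotate_mesh_function(f_mesh, rot, ops$mesh, model$degree_in)
    cin_rot <- lapply(seq_len(model$L), function(ch)
      ops_in$analysis %*% f_rot[, ch, drop = FALSE])
    g1 <- as.vector(invert_coeffs(model, cin_rot, ops, as_grid = FALSE))
    sqrt(sum((g1 - g0_rot)^2) / sum(g0^2))
  }, numeric(1))
  stats::median(errs)
}
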