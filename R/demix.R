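#' Cubic B-spline basis on the unit interval
#'
#' Rank-`J` cubic B-spline system with uniform clamped knots on `[0, 1]`,
#' used to discretize the centered per-fiber kernel decay curves. The basis
#' is a partition of unity.
#'
#' @param J Basis rank (default 20).
#' @return A `spline_basis` with the knot vector and exact basis integrals.
#' @export
spline_basis <- function(J = 20) {
  stopifnot(J >= 5)
  knots <- c(rep(0, 3), seq(0, 1, length.out = J - 2), rep(1, 3))
  # integral of an order-4 B-spline: (t_{j+4} - t_j) / 4
  integrals <- (knots[seq_len(J) + 4] - knots[seq_len(J)]) / 4
  structure(list(J = J, knots = knots, integrals = integrals),
            class = "spline_basis")
}

spline_eval <- function(basis, x) {
  splines::splineDesign(basis$knots, x, ord = 4)
}

#' Per-fiber demixing design matrices
#'
#' Computes the squared projections `t*_{l,m,i} = (p_{l,m}' m_i)^2` of each
#' gradient direction on each fiber axis and the corresponding B-spline
#' evaluation matrices.
#'
#' @param scheme An [acquisition_scheme()].
#' @param orientations `n x 3` matrix of unit fiber axes.
#' @param basis A [spline_basis()].
#' @return A list with one element per shell: `tstar` (`M x n`) and
#'   `gamma` (list of `M x J` matrices, one per fiber).
#' @export
build_design <- function(scheme, orientations, basis = spline_basis()) {
  if (!is.matrix(orientations)) orientations <- matrix(orientations, nrow = 1)
  if (!unit_rows(orientations)) stop("orientations must be unit vectors")
  lapply(scheme$shells, function(sh) {
    tstar <- (sh$dirs %*% t(orientations))^2
    tstar[tstar > 1] <- 1
    gamma <- lapply(seq_len(ncol(tstar)), function(i)
      spline_eval(basis, tstar[, i]))
    list(tstar = tstar, gamma = gamma)
  })
}

#' Demix a multi-fiber signal into centered kernel decay curves
#'
#' Conditional on the fiber orientations, the signal is an additive model in
#' the transformed coordinates `t*_i`: a per-shell intercept plus one
#' centered, monotone-nonincreasing decay curve per fiber. Each shell is
#' fitted independently by penalized least squares over monotone B-spline
#' curves, with monotonicity enforced by reparameterizing coefficient
#' differences as negative exponentials and the integral-to-zero centering
#' applied exactly through the spline's closed-form integral (the
#' intercepts absorb the means). Solved by BFGS with analytic gradients
#' (initialized from the unconstrained ridge fit).
#'
#' @param s A `signal_sample`.
#' @param designs Output of [build_design()] for the same scheme and the
#'   conditioning orientations.
#' @param basis The [spline_basis()] used in the designs.
#' @param grid_size Number of uniform grid points on `[0, 1]` at which the
#'   fitted curves are tabulated (default 100).
#' @param max_iter Optimizer iteration cap per shell (default 500).
#' @return A `demixed_curves` object: `curves` (list per fiber of `L x G`
#'   matrices), `mu` (per-shell intercepts), `coeffs` (centered spline
#'   coefficients per fiber and shell), `grid`, `basis`.
#' @export
fit_additive_model <- function(s, designs, basis = spline_basis(),
                               grid_size = 100, max_iter = 500) {
  L <- length(s$s)
  stopifnot(length(designs) == L)
  n <- ncol(designs[[1]]$tstar)
  J <- basis$J

  # geometry guard: collapse near-collinear fibers to a shared curve.
  # Collinearity is read off the designs' t* columns: for axes separated by
  # angle d, max_p |t*_i - t*_j| <= sin(d), so sin(5 deg) bounds the guard.
  groups <- as.list(seq_len(n))
  if (n > 1) {
    merged <- rep(NA_integer_, n)
    gid <- 0
    for (i in seq_len(n)) {
      if (!is.na(merged[i])) next
      gid <- gid + 1
      merged[i] <- gid
      for (j in seq_len(n)) {
        if (j <= i || !is.na(merged[j])) next
        dmax <- max(abs(designs[[1]]$tstar[, i] - designs[[1]]$tstar[, j]))
        if (dmax < 1e-12)
          stop("rank-deficient design: fibers ", i, " and ", j,
               " have identical orientations")
        if (dmax < sin(5 * pi / 180)) {
          merged[j] <- gid
          warning("fibers ", i, " and ", j,
                  " are within ~5 degrees; fitting a shared curve")
        }
      }
    }
    groups <- split(seq_len(n), merged)
  }
  n_eff <- length(groups)
  reps <- vapply(groups, `[`, integer(1), 1)  # representative fiber per group

  grid <- seq(0, 1, length.out = grid_size)
  gamma_grid <- spline_eval(basis, grid)
  curves <- lapply(seq_len(n), function(i) matrix(0, L, grid_size))
  coeffs <- lapply(seq_len(n), function(i) matrix(0, J, L))
  mu <- numeric(L)

  for (l in seq_len(L)) {
    sl <- s$s[[l]]
    gammas <- lapply(reps, function(i) designs[[l]]$gamma[[i]])
    fit <- fit_monotone_shell(sl, gammas, J, max_iter)
    # exact integral-to-zero centering; intercept absorbs the means
    mu_l <- fit$mu
    for (gi in seq_len(n_eff)) {
      a <- fit$a[, gi]
      ci <- sum(a * basis$integrals)
      a <- a - ci          # partition of unity: constant shift of the curve
      mu_l <- mu_l + ci
      vals <- as.vector(gamma_grid %*% a)
      for (i in groups[[gi]]) {
        curves[[i]][l, ] <- vals
        coeffs[[i]][, l] <- a
      }
    }
    mu[l] <- mu_l
  }
  structure(list(curves = curves, mu = mu, coeffs = coeffs, grid = grid,
                 basis = basis, n = n),
            class = "demixed_curves")
}

# One shell: minimize ||s - mu - sum_i Gamma_i a_i||^2 over monotone
# nonincreasing spline coefficient vectors a_i. Because the B-splines sum
# to one, each fiber's level is confounded with the intercept, so the
# problem is reparameterized exactly in nonnegative coefficient decrements
# d_i (a_i = -cumsum(c(0, d_i)) up to a level absorbed by mu): a
# nonnegative least-squares problem with one free intercept, solved by
# cyclic coordinate descent on its quadratic form (each update is a
# one-dimensional exact minimization with clamping).
fit_monotone_shell <- function(sl, gammas, J, max_iter) {
  n_eff <- length(gammas)
  # regressors: per fiber the negated cumulative column sums of Gamma_i
  # (the image of the strictly-lower cumsum map on the decrements)
  cols <- vector("list", n_eff)
  for (gi in seq_len(n_eff)) {
    G <- gammas[[gi]]
    # column k of G %*% Cum is rowSums of columns (k+1)..J
    rc <- t(apply(G[, J:1, drop = FALSE], 1, cumsum))[, J:1, drop = FALSE]
    cols[[gi]] <- -rc[, -1, drop = FALSE]
  }
  X <- do.call(cbind, cols)
  # project out the free intercept by centering
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  sc <- sl - mean(sl)
  q <- crossprod(Xc)
  # light ridge on the decrements stabilizes the curve tail (t near 1),
  # where squared projections are sparsely sampled and the fit would
  # otherwise extrapolate freely under the monotonicity cone
  ridge <- 1e-4 * mean(diag(q))
  diag(q) <- diag(q) + ridge
  d <- nnls_quad(q, crossprod(Xc, sc)[, 1], max_iter)
  a <- vapply(seq_len(n_eff), function(gi) {
    di <- d[(gi - 1) * (J - 1) + seq_len(J - 1)]
    c(0, -cumsum(di))
  }, numeric(J))
  list(mu = mean(sl) - sum(xm * d), a = a)
}

# Lawson-Hanson active-set NNLS on the quadratic form:
# min 0.5 d' q d - c' d  subject to d >= 0 (q positive definite)
nnls_quad <- function(q, cvec, max_iter = 500) {
  p <- length(cvec)
  d <- numeric(p)
  pass <- logical(p)
  tol <- 1e-10 * max(abs(cvec), 1)
  for (outer in seq_len(max_iter)) {
    w <- cvec - q %*% d
    w[pass] <- -Inf
    j <- which.max(w)
    if (w[j] <= tol) break
    pass[j] <- TRUE
    repeat {
      idx <- which(pass)
      z <- numeric(p)
      z[idx] <- solve(q[idx, idx, drop = FALSE], cvec[idx])
      if (all(z[idx] > 0)) { d <- z; break }
      viol <- idx[z[idx] <= 0]
      alpha <- min(d[viol] / (d[viol] - z[viol]))
      d <- d + alpha * (z - d)
      pass[d <= 1e-12] <- FALSE
      d[!pass] <- 0
    }
  }
  d
}

#' Evaluate the demixed curves of one fiber on the grid
#'
#' @param curves A `demixed_curves` object.
#' @param i Fiber index.
#' @return An `L x G` matrix of curve values.
#' @export
evaluate_demixed <- function(curves, i) {
  if (i < 1 || i > curves$n) stop("fiber index out of range")
  curves$curves[[i]]
}

#' @export
print.demixed_curves <- function(x, ...) {
  cat("<demixed_curves>", x$n, "fiber(s),", nrow(x$curves[[1]]), "shells,",
      length(x$grid), "grid points\n")
  invisible(x)
}

#' Tidy a demixed-curves object
#'
#' @param x A `demixed_curves` object.
#' @param ... Unused.
#' @return A tibble with columns `fiber`, `shell`, `t`, `value`.
#' @export
tidy.demixed_curves <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n), function(i)
    purrr::map_dfr(seq_len(nrow(x$curves[[i]])), function(l)
      tibble::tibble(fiber = i, shell = l, t = x$grid,
                     value = x$curves[[i]][l, ])))
}

#' Plot demixed per-fiber decay curves
#'
#' @param x A `demixed_curves` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_demixed_curves <- function(x, ...) {
  df <- tidy.demixed_curves(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = factor(.data$shell))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~fiber, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "t* (squared projection)", y = "centered decay",
                  colour = "shell") +
    ggplot2::theme_minimal()
}

# flatten a fiber's curves into the MDN input vector (length L * G)
demixed_input <- function(curves, i) {
  as.vector(t(evaluate_demixed(curves, i)))
}
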