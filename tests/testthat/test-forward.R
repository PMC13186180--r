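test_that("standard-model kernel matches direct arithmetic", {
  k <- kernel_params(1, 2, 1.4, 0.3, 0.7)
  expect_equal(standard_model_kernel(0, 1, k), 0.3 + 0.7 * exp(-1.4))
  expect_equal(standard_model_kernel(1, 1, k), 0.3 * exp(-1) + 0.7 * exp(-2))
  # b = 0 gives exactly 1 when fractions sum to one
  expect_equal(standard_model_kernel(runif(5), 0, k), rep(1, 5))
  # strictly decreasing in t on a fine grid for b > 0
  g <- seq(0, 1, length.out = 200)
  expect_true(all(diff(standard_model_kernel(g, 2, k)) < 0))
  expect_error(standard_model_kernel(-0.1, 1, k), "0, 1")
  expect_error(standard_model_kernel(0.5, -1, k), "nonnegative")
})

test_that("kernel parameter invariants are enforced", {
  expect_error(kernel_params(0.1, 2, 1.4, 0.3, 0.7), "0.2")
  expect_error(kernel_params(1, 2, 1.7, 0.3, 0.7), "De_perp")
  expect_error(kernel_params(1, 2, 1.4, -0.1, 0.7), "nonnegative")
  expect_silent(kernel_params(1, 2, 1.4, 0.3, 0.7))
})

test_that("Watson density is normalized on the hemisphere and symmetric", {
  m <- c(0, 0, 1)
  expect_equal(watson_density(c(1, 0, 0), m, 0), 1 / (2 * pi))
  for (kap in c(5, 30, 100)) {
    # high concentrations need the finer mesh for accurate quadrature
    mesh <- default_mesh(if (kap > 30) 4 else 3)
    g <- watson_density(mesh$vertices, m, kap)
    expect_equal(sum(mesh$weights * g) / 2, 1, tolerance = 0.01)
    # mode at the mean axis, antipodal symmetry
    expect_true(watson_density(m, m, kap) >= max(g))
    u <- normalize_rows(matrix(rnorm(3), 1))[1, ]
    expect_equal(watson_density(u, m, kap), watson_density(-u, m, kap))
  }
  expect_error(watson_density(c(1, 0, 0), m, -1), "nonnegative")
})

test_that("mixture signal is 1 at b = 0 and rotation/flip invariant", {
  set.seed(11)
  for (r in 1:5) {
    cfg <- sample_fiber_config()
    p <- normalize_rows(matrix(rnorm(3), 1))[1, ]
    expect_equal(mixture_signal(p, 0, cfg), 1)
    rot <- random_rotation()
    cfg_rot <- cfg
    cfg_rot$orientations <- cfg$orientations %*% t(rot)
    expect_equal(mixture_signal(as.vector(rot %*% p), 1.7, cfg_rot),
                 mixture_signal(p, 1.7, cfg), tolerance = 1e-12)
    expect_equal(mixture_signal(-p, 3, cfg), mixture_signal(p, 3, cfg))
    i <- sample.int(cfg$n, 1)
    cfg_flip <- cfg
    cfg_flip$orientations[i, ] <- -cfg$orientations[i, ]
    expect_equal(mixture_signal(p, 3, cfg_flip), mixture_signal(p, 3, cfg))
  }
  # single fiber along the gradient reduces to the kernel at t = 1
  k <- kernel_params(1, 2, 1.4, 0.3, 0.7)
  cfg1 <- fiber_config(c(0, 0, 1), matrix(unclass(k), 1))
  expect_equal(mixture_signal(c(0, 0, 1), 1, cfg1),
               0.3 * exp(-1) + 0.7 * exp(-2))
})

test_that("centered kernel curves integrate to zero and decrease", {
  grid <- seq(0, 1, length.out = 1000)
  k <- kernel_params(1, 2, 1.4, 0.3, 0.7)
  cc <- centered_kernel_curve(k, 1, grid)
  expect_lt(abs(pracma::trapz(grid, cc)), 1e-4)
  expect_true(all(diff(cc) < 0))
  # closed-form single-compartment mean
  k1 <- kernel_params(1, 2, 1.4, 1, 0)
  expect_equal(fiberlfi:::kernel_curve_mean(k1, 1), 1 - exp(-1))
  # independence: the curve ignores other fibers entirely (by construction
  # it is a function of one kernel only)
  set.seed(2)
  for (r in 1:3) {
    kk <- sample_diffusivities()
    kp <- c(kk, z1 = 0.4, z2 = 0.6)
    expect_true(all(diff(centered_kernel_curve(kp, 2.5, grid)) < 0))
    expect_lt(abs(pracma::trapz(grid, centered_kernel_curve(kp, 2.5, grid))),
              1e-4)
  }
})

test_that("additive noise is seeded, unbiased in variance, and optional", {
  cfg <- fiber_config(c(0, 0, 1), matrix(unclass(kernel_params(1, 2, 1.4, 0.3, 0.7)), 1))
  f <- simulate_signal(cfg, default_scheme())
  expect_identical(add_noise(f, 0), f)
  n1 <- add_noise(f, 0.004, seed = 5)
  n2 <- add_noise(f, 0.004, seed = 5)
  expect_identical(n1, n2)
  # empirical variance over many draws matches sigma_e2 = 0.004
  set.seed(6)
  draws <- replicate(900, unlist(add_noise(f, 0.004)$s) - unlist(f$s))
  expect_equal(var(as.vector(draws)), 0.004, tolerance = 0.01)
})

test_that("orientation canonicalization picks the upper-hemisphere axis", {
  expect_equal(canonicalize_axis(c(0, 0, -1)), c(0, 0, 1))
  expect_equal(canonicalize_axis(c(0, -1, 0)), c(0, 1, 0))
  expect_equal(canonicalize_axis(c(-1, 0, 0)), c(1, 0, 0))
  m <- normalize_rows(matrix(rnorm(30), 10))
  cm <- canonicalize_axis(m)
  expect_true(all(cm[, 3] >= 0))
  expect_equal(abs(rowSums(cm * m)), rep(1, 10), tolerance = 1e-12)
})
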