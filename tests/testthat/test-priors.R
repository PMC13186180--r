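test_that("diffusivity sampler respects the polytope and box marginals", {
  set.seed(1)
  draws <- t(replicate(10000, sample_diffusivities()))
  expect_true(all(draws[, "Da"] >= 0.2 & draws[, "Da"] <= 3))
  expect_true(all(draws[, "De_par"] >= 0.2 & draws[, "De_par"] <= 3))
  expect_true(all(draws[, "De_perp"] > 0 &
                    draws[, "De_perp"] < 0.8 * draws[, "De_par"]))
  # Da stays uniform after rejection; De_par picks up the linear tilt of
  # the uniform-on-polytope density (its De_perp width grows like
  # 0.8 * De_par), with CDF (x^2 - 0.2^2) / (3^2 - 0.2^2)
  expect_gt(stats::ks.test(draws[, "Da"], "punif", 0.2, 3)$p.value, 1e-3)
  lin_cdf <- function(q) (q^2 - 0.04) / (9 - 0.04)
  expect_gt(stats::ks.test(draws[, "De_par"], lin_cdf)$p.value, 1e-3)
})

test_that("box-proposal acceptance rate matches a grid-integration oracle", {
  # oracle: fraction of the box [0.2,3]x(0,2.4] with De_perp < 0.8 De_par,
  # by brute-force grid integration over (De_par, De_perp)
  gp <- seq(0.2, 3, length.out = 400)
  gq <- seq(1e-4, 2.4, length.out = 400)
  frac <- mean(outer(gp, gq, function(p, q) q < 0.8 * p))
  set.seed(2)
  n_try <- 20000
  acc <- mean(replicate(n_try, {
    De_par <- runif(1, 0.2, 3); De_perp <- runif(1, 0, 2.4)
    De_perp < 0.8 * De_par
  }))
  expect_equal(acc, frac, tolerance = 0.02)
})

test_that("orientation sampler enforces the crossing-angle rules", {
  set.seed(3)
  for (r in 1:300) {
    n <- sample(2:3, 1)
    m <- sample_orientations(n)
    ang <- pairwise_axial_angles(m) * 180 / pi
    expect_true(all(ang >= 10))
    if (n == 3) expect_gte(sort(ang)[2], 30)
    expect_true(all(m[, 3] >= 0))
  }
  expect_equal(dim(sample_orientations(1)), c(1, 3))
})

test_that("fraction sampler gives a truncated flat Dirichlet", {
  set.seed(4)
  z1s <- numeric(3000)
  for (r in 1:3000) {
    n <- sample(1:3, 1)
    z <- sample_fractions(n)
    expect_equal(sum(z), 1, tolerance = 1e-12)
    expect_true(all(z[, "z1"] >= 0.1))
    if (n == 1) z1s[r] <- z[1, "z1"] else z1s[r] <- NA
  }
  # for n = 1 the z1 marginal is Uniform(0,1) truncated to [0.1, 1]
  z1s <- z1s[!is.na(z1s)]
  expect_gt(stats::ks.test(z1s, function(q) punif(q, 0.1, 1))$p.value, 1e-3)
})

test_that("fiber-count prior honours its weights", {
  set.seed(5)
  n_draw <- replicate(6000, sample_fiber_count())
  expect_equal(as.vector(table(n_draw)) / 6000, rep(1 / 3, 3),
               tolerance = 0.05)
  cfg1 <- prior_config(n_weights = c(1, 0, 0))
  expect_true(all(replicate(50, sample_fiber_count(cfg1)) == 1))
  expect_error(prior_config(n_weights = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("generated datasets satisfy all invariants and are seeded", {
  ds <- generate_dataset(40, seed = 9)
  for (cfg in ds$configs) expect_silent(fiberlfi:::validate_fiber_config(cfg))
  # noiseless signals at b = 0 would be exactly 1; check attenuations are
  # bounded and finite instead (the scheme stores diffusion shells only)
  expect_true(all(is.finite(ds$clean)) && all(ds$clean <= 1 + 1e-12))
  ds2 <- generate_dataset(40, seed = 9)
  expect_identical(ds$clean, ds2$clean)
  expect_identical(ds$noisy, ds2$noisy)
  expect_false(identical(ds$noisy, generate_dataset(40, seed = 10)$noisy))
})

test_that("dataset serialization round-trips", {
  ds <- generate_dataset(8, seed = 13)
  dir <- file.path(tempdir(), "ds_roundtrip")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$clean, ds$clean, tolerance = 1e-6)
  expect_equal(back$noisy, ds$noisy, tolerance = 1e-6)
  expect_equal(back$sigma_e2, ds$sigma_e2)
  expect_equal(scheme_bvals(back$scheme), scheme_bvals(ds$scheme))
  expect_equal(back$params$Da, ds$params$Da, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
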