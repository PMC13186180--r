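test_that("the MDN defines a proper conditional mixture", {
  m <- mdn_model(1, input_dim = 10, depth = 2, width = 16, seed = 1)
  m$scale <- list(x_mean = rep(0, 10), x_sd = rep(1, 10),
                  xi_mean = rep(0, 5), xi_sd = rep(1, 5))
  set.seed(1)
  for (r in 1:10) {
    mix <- fiberlfi:::mdn_mixture(m, rnorm(10))
    expect_equal(sum(mix$weights), 1, tolerance = 1e-6)
    expect_true(all(mix$weights > 0))
    expect_true(all(mix$sds > 0))
  }
})

test_that("training tracks an analytic linear-Gaussian conditional mean", {
  # toy: xi1 = a' x + noise; the posterior mean of xi1 given x is a' x
  set.seed(7)
  N <- 4000; d <- 12
  a <- rnorm(d) / sqrt(d)
  X <- matrix(rnorm(N * d), N, d)
  XI <- cbind(X %*% a + rnorm(N, sd = 0.3),
              matrix(rnorm(N * 4), N, 4))
  pairs <- list(x = X, xi = XI)
  m <- mdn_model(1, input_dim = d, depth = 2, width = 32, seed = 3)
  m <- train_mdn(pairs, 1, m, iterations = 2500, lr = 1e-3, seed = 3)
  # compare model conditional mean to the analytic mean at fresh points
  errs <- vapply(1:50, function(r) {
    x <- rnorm(d)
    mix <- fiberlfi:::mdn_mixture(m, x)
    mu <- sum(mix$weights * mix$means[, 1])
    mu - sum(a * x)
  }, numeric(1))
  # MC standard error of the check: residual sd 0.3 over model smoothing;
  # tolerance of two standard errors of the mean discrepancy
  expect_lt(abs(mean(errs)), 2 * 0.3 / sqrt(50) + 0.1)
  expect_lt(mean(abs(errs)), 0.35)
  expect_gt(m$score_after, m$score_before)
})

test_that("mixed-n training sets are rejected", {
  pairs <- list(x = matrix(rnorm(20), 4), xi = matrix(runif(20), 4),
                n = c(1, 1, 2, 1))
  expect_error(train_mdn(pairs, 1), "mixed")
})

test_that("posterior sampling respects constraints, pairing and seeding", {
  fx <- trained_mdn1()
  m <- fx$model
  x <- fx$cal_pairs$x[1, ]
  s1 <- sample_posterior(m, x, Q = 800, seed = 5)
  s2 <- sample_posterior(m, x, Q = 800, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1[, "De_perp"] < 0.8 * s1[, "De_par"]))
  expect_true(all(s1[, "De_perp"] > 0))
  expect_true(all(s1[, "Da"] >= 0.2 & s1[, "Da"] <= 3))
  expect_true(all(s1[, c("z1", "z2")] >= 0))
  # joint projection: unit simplex per paired draw, within-fiber ratio kept
  sl <- list(s1, sample_posterior(m, fx$cal_pairs$x[2, ], Q = 800, seed = 6))
  pr <- project_fractions(sl)
  tot <- pr[[1]][, "z1"] + pr[[1]][, "z2"] + pr[[2]][, "z1"] + pr[[2]][, "z2"]
  expect_equal(tot, rep(1, 800), tolerance = 1e-12)
  expect_equal(pr[[1]][, "z1"] / pr[[1]][, "z2"],
               s1[, "z1"] / s1[, "z2"], tolerance = 1e-9)
})

test_that("point estimators behave on degenerate and planted cases", {
  one <- matrix(rep(c(1, 2, 1.4, 0.3, 0.7), each = 3), 3,
                dimnames = list(NULL, c("Da", "De_par", "De_perp", "z1", "z2")))
  expect_equal(posterior_mean(one), one[1, ])
  two <- one[1:2, ]; two[2, ] <- c(2, 1, 0.5, 0.5, 0.5)
  expect_equal(posterior_mean(two), colMeans(two))
  expect_error(posterior_mean(one[0, , drop = FALSE]), "empty")

  # MAP selects the generating parameters on noiseless data
  sch <- test_scheme()
  truth <- c(Da = 1, De_par = 2, De_perp = 1.4, z1 = 0.3, z2 = 0.7)
  m1 <- matrix(c(0, 0, 1), 1)
  s <- simulate_signal(fiber_config(m1, matrix(truth, 1)), sch)
  set.seed(8)
  cand <- matrix(runif(200 * 5), 200, 5,
                 dimnames = list(NULL, names(truth)))
  cand[, "Da"] <- runif(200, 0.2, 3); cand[, "De_par"] <- runif(200, 0.2, 3)
  planted <- 57
  cand[planted, ] <- truth
  mp <- map_estimate(list(cand), s, sch, m1, sigma_e2 = 1e-6)
  expect_equal(mp$index, planted)
  expect_equal(mp$estimates[[1]], truth)
  # permuting candidates changes only the index, not the value
  perm <- sample(200)
  mp2 <- map_estimate(list(cand[perm, ]), s, sch, m1, sigma_e2 = 1e-6)
  expect_equal(mp2$estimates[[1]], truth)
  # single candidate returns it
  mp3 <- map_estimate(list(cand[3, , drop = FALSE]), s, sch, m1, 1e-6)
  expect_equal(mp3$estimates[[1]], cand[3, ])
})

test_that("HDRs match analytic normal quantiles and resolve bimodality", {
  set.seed(9)
  s <- rnorm(1e5)
  h <- hdr(s, 0.05, c(-8, 8))
  expect_equal(nrow(h), 1)
  expect_equal(h$lo, -1.96, tolerance = 0.05)
  expect_equal(h$hi, 1.96, tolerance = 0.05)
  expect_gte(attr(h, "mass"), 0.94)
  # well-separated mixture: two disjoint intervals
  s2 <- c(rnorm(4e4), rnorm(4e4, mean = 10))
  h2 <- hdr(s2, 0.05, c(-8, 18))
  expect_equal(nrow(h2), 2)
  expect_true(h2$hi[1] < h2$lo[2])
  expect_error(hdr(s, 1.5, c(-8, 8)), "alpha")
  expect_error(hdr(rnorm(10), 0.05, c(-8, 8)), "100")
  # relative size arithmetic
  fake <- tibble::tibble(lo = c(0, 1), hi = c(0.3, 1.4))
  expect_equal(hdr_size(fake, c(0, 2.8)), 0.25)
})

test_that("held-out log score improves through training and calibration", {
  fx <- trained_mdn1()
  m <- fx$model
  expect_gt(mdn_log_score(m, fx$cal_pairs), m$score_before)
})

test_that("single-fiber HDR coverage is calibrated on fresh voxels", {
  ecp_all <- single_fiber_ecp()
  # calibration property: every parameter's 95% HDR coverage in [0.90, 0.98]
  expect_true(all(ecp_all >= 0.90 & ecp_all <= 0.98))
})

test_that("posterior spread widens with the training noise level", {
  # train two tiny MDNs on the same configurations at different noise
  # levels; average HDR sizes must not shrink as noise grows
  sizes <- vapply(c(0.02, 0.0620, 0.12), function(sg) {
    ds <- generate_dataset(1000, test_scheme(), sg^2, seed = 55, n = 1)
    pairs <- build_mdn_pairs(ds)
    m <- train_mdn(pairs, 1, iterations = 1200, lr = 1e-3, seed = 5)
    ds2 <- generate_dataset(30, test_scheme(), sg^2, seed = 56, n = 1)
    sup <- kernel_supports()
    mean(vapply(1:30, function(v) {
      s <- fiberlfi:::dataset_signal_sample(ds2, v)
      dm <- fit_additive_model(
        s, build_design(ds2$scheme, ds2$configs[[v]]$orientations))
      sm <- sample_posterior(m, fiberlfi:::demixed_input(dm, 1), Q = 600,
                             seed = v)
      mean(vapply(names(sup), function(p)
        hdr_size(hdr(sm[, p], 0.05, sup[[p]]), sup[[p]]), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sizes) > 0))
})
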