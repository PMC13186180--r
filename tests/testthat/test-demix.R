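test_that("design matrices carry the squared projections", {
  sch <- test_scheme()
  m <- rbind(c(0, 0, 1), c(1, 0, 0))
  des <- build_design(sch, m)
  # direct dot-product oracle
  for (l in 1:2) {
    expect_equal(des[[l]]$tstar,
                 (sch$shells[[l]]$dirs %*% t(m))^2, tolerance = 1e-12)
    expect_equal(dim(des[[l]]$gamma[[1]]), c(60, 20))
  }
  # p perpendicular / parallel to the axis
  sch1 <- acquisition_scheme(1, rbind(c(1, 0, 0), c(0, 0, 1), c(0, 0, -1)))
  d1 <- build_design(sch1, matrix(c(0, 0, 1), 1))
  expect_equal(as.vector(d1[[1]]$tstar), c(0, 1, 1))
  expect_error(build_design(sch, m * 2), "unit")
})

test_that("spline basis is a partition of unity with exact integrals", {
  b <- spline_basis(20)
  x <- seq(0, 1, length.out = 57)
  expect_equal(rowSums(fiberlfi:::spline_eval(b, x)), rep(1, 57),
               tolerance = 1e-10)
  expect_equal(sum(b$integrals), 1, tolerance = 1e-12)
})

test_that("noiseless single-fiber demixing recovers the centered curve", {
  sch <- test_scheme()
  k <- kernel_params(1, 2, 1.4, 0.3, 0.7)
  cfg <- fiber_config(c(0, 0, 1), matrix(unclass(k), 1))
  dm <- fit_additive_model(simulate_signal(cfg, sch),
                           build_design(sch, cfg$orientations))
  for (l in 1:2) {
    truth <- centered_kernel_curve(k, scheme_bvals(sch)[l], dm$grid)
    expect_lt(max(abs(dm$curves[[1]][l, ] - truth)), 0.01)
    # integral-to-zero holds exactly through the spline integral and to
    # trapezoid accuracy on the grid
    expect_lt(abs(sum(dm$coeffs[[1]][, l] * dm$basis$integrals)), 1e-6)
    expect_lt(abs(pracma::trapz(dm$grid, dm$curves[[1]][l, ])), 1e-3)
    expect_true(all(diff(dm$curves[[1]][l, ]) <= 1e-9))
  }
})

test_that("two crossing fibers demix into their own centered curves", {
  sch <- test_scheme()
  m <- rbind(c(0, 0, 1), c(1, 0, 0))
  kern <- rbind(c(1, 2, 1.4, 0.2, 0.4), c(2.2, 1.5, 0.5, 0.25, 0.15))
  dm <- fit_additive_model(simulate_signal(fiber_config(m, kern), sch),
                           build_design(sch, m))
  for (i in 1:2) for (l in 1:2) {
    truth <- centered_kernel_curve(kern[i, ], scheme_bvals(sch)[l], dm$grid)
    expect_lt(max(abs(dm$curves[[i]][l, ] - truth)), 0.02)
  }
})

test_that("fiber order permutes outputs identically", {
  sch <- test_scheme()
  m <- rbind(c(0, 0, 1), c(1, 0, 0))
  kern <- rbind(c(1, 2, 1.4, 0.2, 0.4), c(2.2, 1.5, 0.5, 0.25, 0.15))
  s <- simulate_signal(fiber_config(m, kern), sch)
  d12 <- fit_additive_model(s, build_design(sch, m))
  d21 <- fit_additive_model(s, build_design(sch, m[2:1, ]))
  expect_equal(d21$curves[[1]], d12$curves[[2]], tolerance = 1e-8)
  expect_equal(d21$curves[[2]], d12$curves[[1]], tolerance = 1e-8)
})

test_that("recovered curves converge to truth as noise shrinks", {
  sch <- test_scheme()
  k <- kernel_params(1, 2, 1.4, 0.3, 0.7)
  cfg <- fiber_config(c(0, 0, 1), matrix(unclass(k), 1))
  f <- simulate_signal(cfg, sch)
  des <- build_design(sch, cfg$orientations)
  errs <- vapply(c(0.05, 0.01, 0.001), function(sg) {
    # average over replicates to suppress Monte-Carlo wiggle
    mean(vapply(1:5, function(r) {
      dm <- fit_additive_model(add_noise(f, sg^2, seed = 100 * sg + r), des)
      max(abs(dm$curves[[1]][2, ] -
                centered_kernel_curve(k, scheme_bvals(sch)[2], dm$grid)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("degenerate geometry is guarded", {
  sch <- test_scheme()
  m_id <- rbind(c(0, 0, 1), c(0, 0, 1))
  kern <- rbind(c(1, 2, 1.4, 0.2, 0.4), c(2.2, 1.5, 0.5, 0.25, 0.15))
  s <- simulate_signal(fiber_config(m_id, kern, check = FALSE), sch)
  expect_error(
    fit_additive_model(s, build_design(sch, m_id)),
    "rank-deficient")
  # ~3 degrees apart: shared curve with a warning, duplicated outputs
  m_close <- rbind(c(0, 0, 1), c(sin(3 * pi / 180), 0, cos(3 * pi / 180)))
  s2 <- simulate_signal(fiber_config(m_close, kern, check = FALSE), sch)
  expect_warning(
    dm <- fit_additive_model(s2, build_design(sch, m_close)),
    "shared curve")
  expect_equal(dm$curves[[1]], dm$curves[[2]])
})

test_that("evaluate_demixed returns the tabulated grid values", {
  sch <- test_scheme()
  k <- kernel_params(1, 2, 1.4, 0.3, 0.7)
  cfg <- fiber_config(c(0, 0, 1), matrix(unclass(k), 1))
  dm <- fit_additive_model(simulate_signal(cfg, sch),
                           build_design(sch, cfg$orientations))
  v <- evaluate_demixed(dm, 1)
  expect_equal(dim(v), c(2, 100))
  # direct spline-evaluation oracle at the grid points
  direct <- t(fiberlfi:::spline_eval(dm$basis, dm$grid) %*% dm$coeffs[[1]])
  expect_equal(v, direct, tolerance = 1e-12)
  expect_error(evaluate_demixed(dm, 2), "range")
})
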