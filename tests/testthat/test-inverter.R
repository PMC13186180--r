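test_that("rendered target ODFs are valid discretized densities", {
  spec <- odf_target_spec()
  set.seed(41)
  for (r in 1:4) {
    cfg <- sample_fiber_config()
    og <- render_target_odf(cfg, spec)
    mesh <- spec$mesh
    expect_equal(og$g, og$g[mesh$antipode])
    expect_equal(sum(mesh$weights * og$g) / 2, 1, tolerance = 1e-8)
    expect_true(all(og$g >= 0))
  }
  # single fiber: global max at the vertex nearest the axis
  cfg1 <- well_separated_config(1)
  og1 <- render_target_odf(cfg1, spec)
  vmax <- spec$mesh$vertices[which.max(og1$g), ]
  expect_lt(axial_angle(vmax, cfg1$orientations[1, ]) * 180 / pi, 4)
})

test_that("training reduces the held-out Bayes risk below half", {
  # single-fiber training set, as in the desk-scale protocol
  ds <- generate_dataset(900, test_scheme(), test_sigma2(), seed = 13,
                         n = 1, odf_spec = odf_target_spec())
  mod <- train_inverter(ds, iterations = 120, seed = 2)
  expect_lt(mod$risk_after, 0.5 * mod$risk_before)
  # the trained risk also beats the zero map (= mean squared target norm)
  zero_risk <- mean(rowSums(ds$odf[mod$holdout, ]^2))
  expect_lt(mod$risk_after, zero_risk)
  # determinism: identical seeds give identical parameters and risks
  mod2 <- train_inverter(ds, iterations = 120, seed = 2)
  expect_identical(mod$params, mod2$params)
  expect_identical(mod$risk_after, mod2$risk_after)
})

test_that("inverted ODFs satisfy the grid invariants", {
  fx <- trained_inverter()
  mod <- fx$model
  set.seed(42)
  for (r in 1:4) {
    cfg <- sample_fiber_config()
    s <- add_noise(simulate_signal(cfg, test_scheme()), test_sigma2())
    odf <- fiberlfi:::invert_coeffs(mod, fit_sh_shells(s, test_scheme()))
    mesh <- odf$mesh
    expect_true(all(odf$g >= 0))
    expect_equal(odf$g, odf$g[mesh$antipode], tolerance = 1e-9)
    expect_equal(sum(mesh$weights * odf$g) / 2, 1, tolerance = 1e-6)
  }
  # untrained models warn and still return output
  raw <- inverter_model(L = 2)
  mesh <- default_mesh(4)
  fm <- matrix(0.5, nrow(mesh$vertices), 2)
  expect_warning(invert_signal(raw, fm), "trained")
})

test_that("the trained inverter is rotationally equivariant", {
  fx <- trained_inverter()
  err <- equivariance_error(fx$model, fx$ds, n_rot = 15, seed = 3)
  expect_lt(err, 0.05)
})

test_that("single-fiber peaks land within ten degrees on clean signals", {
  fx <- trained_inverter()
  mod <- fx$model
  set.seed(44)
  hits <- 0; trials <- 120
  for (r in seq_len(trials)) {
    cfg <- well_separated_config(1)
    odf <- fiberlfi:::invert_coeffs(
      mod, fit_sh_shells(simulate_signal(cfg, test_scheme()), test_scheme()))
    pk <- find_odf_peaks(odf)
    if (pk$n >= 1 &&
        axial_angle(pk$orientations[1, ], cfg$orientations[1, ]) *
          180 / pi <= 10)
      hits <- hits + 1
  }
  expect_gte(hits / trials, 0.95)
})

test_that("model selection is reliable for well-separated crossings", {
  expect_gte(twofiber_selection_rate(), 0.9)
  # rendered targets select their own counts
  tg <- render_target_odf(well_separated_config(2, 45), odf_target_spec())
  expect_equal(select_model(tg)$n, 2)
  tg1 <- render_target_odf(well_separated_config(1), odf_target_spec())
  expect_equal(select_model(tg1)$n, 1)
  # constant ODF is degenerate
  mesh <- default_mesh(4)
  expect_true(select_model(odf_grid(rep(1, nrow(mesh$vertices)),
                                    mesh))$degenerate)
})
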