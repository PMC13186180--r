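# Shared fixtures: trained models are expensive, so they are built lazily
# once per test session and cached. Sizes are desk-scale: large enough for
# the statistical checks, small enough for a single-CPU test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

test_scheme <- function() default_scheme()

test_sigma2 <- function() 0.0620^2

trained_inverter <- function() {
  fixture("inverter", function() {
    ds <- generate_dataset(1000, test_scheme(), test_sigma2(), seed = 3,
                           odf_spec = odf_target_spec())
    list(model = train_inverter(ds, iterations = 150, seed = 1), ds = ds)
  })
}

trained_mdn1 <- function() {
  fixture("mdn1", function() {
    ds <- generate_dataset(12000, test_scheme(), test_sigma2(), seed = 21,
                           n = 1)
    pairs <- build_mdn_pairs(ds)
    m <- train_mdn(pairs, 1, iterations = 6000, lr = 5e-4, seed = 2)
    dcal <- generate_dataset(450, test_scheme(), test_sigma2(), seed = 31,
                             n = 1)
    pcal <- build_mdn_pairs(dcal)
    m <- calibrate_mdn(m, pcal, Q = 800, max_pairs = 350, seed = 3)
    list(model = m, pairs = pairs, cal_pairs = pcal)
  })
}

trained_mdn2 <- function() {
  fixture("mdn2", function() {
    ds <- generate_dataset(1500, test_scheme(), test_sigma2(), seed = 41,
                           n = 2)
    pairs <- build_mdn_pairs(ds)
    train_mdn(pairs, 2, iterations = 2500, lr = 5e-4, seed = 4)
  })
}

# 95% HDR coverage of the trained single-fiber posterior over 500 fresh
# simulated voxels (shared between the calibration test and the
# acceptance check); returns a named vector of per-parameter coverages
single_fiber_ecp <- function() {
  fixture("ecp1", function() {
    m <- trained_mdn1()$model
    ds_test <- generate_dataset(500, test_scheme(), test_sigma2(),
                                seed = 99, n = 1)
    sup <- kernel_supports()
    cov <- matrix(0, 500, 5, dimnames = list(NULL, names(sup)))
    set.seed(7)
    for (v in 1:500) {
      cfg <- ds_test$configs[[v]]
      s <- fiberlfi:::dataset_signal_sample(ds_test, v)
      dm <- fit_additive_model(s, build_design(ds_test$scheme,
                                               cfg$orientations))
      sm <- sample_posterior(m, fiberlfi:::demixed_input(dm, 1), Q = 2000)
      sm <- project_fractions(list(sm))[[1]]
      for (p in names(sup))
        cov[v, p] <- hdr_contains(hdr(sm[, p], 0.05, sup[[p]]),
                                  cfg$kernels[1, p])
    }
    colMeans(cov)
  })
}

# noiseless well-separated two-fiber model-selection rate of the shared
# trained inverter (120 trials)
twofiber_selection_rate <- function() {
  fixture("sel2", function() {
    mod <- trained_inverter()$model
    set.seed(45)
    ok <- 0; trials <- 120
    for (r in seq_len(trials)) {
      cfg <- well_separated_config(2, deg = 45)
      odf <- fiberlfi:::invert_coeffs(
        mod,
        fit_sh_shells(simulate_signal(cfg, test_scheme()), test_scheme()))
      if (select_model(odf)$n == 2) ok <- ok + 1
    }
    ok / trials
  })
}

# fiber config drawn until the minimum crossing angle is at least `deg`
well_separated_config <- function(n, deg = 45) {
  repeat {
    cfg <- sample_fiber_config(n = n)
    if (n == 1 ||
        min(pairwise_axial_angles(cfg$orientations)) * 180 / pi >= deg)
      return(cfg)
  }
}
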