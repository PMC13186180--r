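test_that("peak-count accuracy and coverage summaries are arithmetic", {
  rec <- tibble::tibble(n_true = c(1, 2, 2, 3), n_hat = c(1, 2, 1, 3))
  expect_equal(pcp(rec), 0.75)
  expect_equal(pcp(dplyr::mutate(rec, n_hat = n_true)), 1)
  expect_equal(pcp(dplyr::mutate(rec, n_hat = n_true + 1)), 0)
  expect_error(pcp(rec[0, ]), "records")
  cov <- tibble::tibble(parameter = rep(c("Da", "z1"), each = 4),
                        covered = c(TRUE, TRUE, FALSE, TRUE,
                                    TRUE, TRUE, TRUE, TRUE),
                        hdr_rel_size = rep(c(0.5, 0.25), each = 4))
  e <- ecp(cov)
  expect_equal(e$ecp[e$parameter == "Da"], 0.75)
  expect_equal(e$ecp[e$parameter == "z1"], 1)
  h <- hdr_s(cov)
  expect_equal(h$hdr_s, c(0.5, 0.25))
})

test_that("angular error minimizes over labelings and flips", {
  m <- rbind(c(0, 0, 1), c(1, 0, 0))
  expect_equal(angular_error(m, m), 0)
  expect_equal(angular_error(m, m[2:1, ]), 0)
  expect_equal(angular_error(m, -m), 0)
  expect_error(angular_error(m, m[1, , drop = FALSE]), "differ")
  # random 2-fiber case agrees with explicit enumeration of assignments
  set.seed(71)
  for (r in 1:20) {
    mt <- sample_orientations(2)
    me <- normalize_rows(mt + 0.2 * matrix(rnorm(6), 2))
    direct <- min(
      mean(c(axial_angle(mt[1, ], me[1, ]), axial_angle(mt[2, ], me[2, ]))),
      mean(c(axial_angle(mt[1, ], me[2, ]), axial_angle(mt[2, ], me[1, ]))))
    expect_equal(angular_error(mt, me), direct * 180 / pi, tolerance = 1e-10)
  }
})

test_that("the benchmark harness emits the table structure", {
  inv <- trained_inverter()$model
  mdns <- list("1" = trained_mdn1()$model, "2" = trained_mdn2())
  bench <- run_benchmark(8, inv, mdns, methods = c("lfi", "mle1"),
                         Q = 300, B = 20, n_fixed = 1, seed = 2)
  expect_true(all(c("method", "n_true", "pcp", "ae") %in%
                    names(bench$orientation)))
  expect_true(all(c("mean_abs_error", "median_abs_error", "bias") %in%
                    names(bench$kernel_error)))
  expect_true(nrow(bench$calibration) >= 1)
  # bias equals a hand computation on the raw error records
  err <- bench$records$errors
  one <- dplyr::filter(err, .data$method == "LFI-PM",
                       .data$parameter == "Da")
  row <- dplyr::filter(bench$kernel_error, .data$method == "LFI-PM",
                       .data$parameter == "Da")
  expect_equal(row$bias, mean(one$error))
  expect_equal(row$median_abs_error, stats::median(abs(one$error)))
  # the paper-scale preset is refused on the desk profile
  expect_error(run_benchmark(8, inv, mdns, scale = "paper"), "GPU")
})
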