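test_that("symmetric basis dimension follows the even-degree count", {
  expect_equal(sh_basis(8)$K, 45)
  expect_equal(sh_basis(20)$K, 231)
  expect_equal(sh_basis(0)$K, 1)
  expect_error(sh_basis(7), "even")
})

test_that("basis is orthonormal under mesh quadrature", {
  mesh <- default_mesh(4)
  phi <- sh_eval_matrix(sh_basis(8), mesh$vertices)
  gram <- t(phi * mesh$weights) %*% phi
  expect_lt(max(abs(gram - diag(ncol(phi)))), 0.01)
})

test_that("least-squares fit recovers band-limited signals exactly", {
  set.seed(21)
  dirs <- fibonacci_directions(60)
  basis <- sh_basis(8)
  c0 <- rnorm(basis$K)
  s <- evaluate_signal(c0, dirs, basis)
  expect_equal(fit_sh(s, dirs, basis), c0, tolerance = 1e-8)
  # constant signal loads only the l = 0 coefficient
  ch <- fit_sh(rep(2.5, 60), dirs, basis)
  expect_equal(ch[1], 2.5 * sqrt(4 * pi), tolerance = 1e-8)
  expect_lt(max(abs(ch[-1])), 1e-10)
  # ridge path stays close to OLS for tiny lambda
  expect_equal(fit_sh(s, dirs, basis, lambda = 1e-10), c0, tolerance = 1e-6)
  # underdetermined OLS errors, advising a ridge
  expect_error(fit_sh(s[1:10], dirs[1:10, ], basis), "ridge")
})

test_that("evaluation agrees with a direct basis-sum oracle", {
  set.seed(22)
  basis <- sh_basis(4)
  c0 <- rnorm(basis$K)
  pts <- normalize_rows(matrix(rnorm(30), 10))
  direct <- as.vector(sh_eval_matrix(basis, pts) %*% c0)
  expect_equal(evaluate_signal(c0, pts, basis), direct)
  # even-degree basis means antipodal symmetry of any expansion
  expect_equal(evaluate_signal(c0, -pts, basis), direct)
  expect_error(evaluate_signal(c0[-1], pts, basis), "match")
})

test_that("sphere mesh has exact antipodes and full quadrature mass", {
  mesh <- default_mesh(3)
  expect_equal(sum(mesh$weights), 4 * pi, tolerance = 1e-10)
  expect_equal(mesh$vertices, -mesh$vertices[mesh$antipode, ])
  expect_equal(nrow(default_mesh(4)$vertices), 2562)
  expect_equal(nrow(mesh$vertices), 642)
})

test_that("peak finding localizes rendered Watson mixtures", {
  mesh <- default_mesh(4)
  set.seed(23)
  # single Watson: one peak within one mesh-edge angle (~4 degrees)
  ax <- canonicalize_axis(normalize_rows(matrix(rnorm(3), 1)))[1, ]
  og <- odf_grid(watson_density(mesh$vertices, ax, 100), mesh)
  pk <- find_odf_peaks(og)
  expect_equal(pk$n, 1)
  expect_lt(axial_angle(pk$orientations[1, ], ax) * 180 / pi, 4)
  # two equal Watsons 90 degrees apart: two peaks
  g2 <- watson_density(mesh$vertices, c(0, 0, 1), 100) +
    watson_density(mesh$vertices, c(1, 0, 0), 100)
  pk2 <- find_odf_peaks(odf_grid(g2, mesh))
  expect_equal(pk2$n, 2)
  # constant ODF: flagged degenerate, at most max_peaks peaks
  pk3 <- find_odf_peaks(odf_grid(rep(1, nrow(mesh$vertices)), mesh))
  expect_true(pk3$degenerate)
  expect_lte(pk3$n, 3)
})

test_that("peak counts match truth for separated high-concentration mixtures", {
  mesh <- default_mesh(4)
  set.seed(24)
  ok <- 0; trials <- 60
  for (r in seq_len(trials)) {
    n <- sample(1:3, 1)
    m <- if (n == 1) sample_orientations(1) else {
      repeat {
        mm <- sample_orientations(n)
        if (min(pairwise_axial_angles(mm)) * 180 / pi >= 30) break
      }
      mm
    }
    g <- 0
    for (i in seq_len(n)) g <- g + watson_density(mesh$vertices, m[i, ], 150)
    pk <- find_odf_peaks(odf_grid(g, mesh), min_sep_deg = 15)
    if (pk$n == n) ok <- ok + 1
  }
  expect_gte(ok / trials, 0.95)
})

test_that("band-limited rotation resampling is near-exact", {
  mesh <- default_mesh(4)
  set.seed(25)
  basis <- sh_basis(8)
  f <- evaluate_signal(rnorm(basis$K), mesh$vertices, basis)
  rot <- random_rotation()
  f_rot <- rotate_mesh_function(f, rot, mesh, degree = 8)
  f_direct <- evaluate_signal(fit_sh(f, mesh$vertices, basis),
                              mesh$vertices %*% rot, basis)
  expect_equal(f_rot, f_direct, tolerance = 1e-6)
})
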