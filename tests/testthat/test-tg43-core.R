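test_that("geometry function matches direct numerical integration of the line kernel", {
  cases <- expand.grid(r = c(0.3, 0.5, 1, 2, 5, 10),
                       theta = c(0, 0.5, 10, 45, 90, 135, 179.5))
  for (i in seq_len(nrow(cases))) {
    G <- geometry_function(cases$r[i], cases$theta[i], L = 0.19)
    expect_equal(G, oracle_geometry(cases$r[i], cases$theta[i], L = 0.19),
                 tolerance = 1e-10,
                 label = sprintf("G(%g, %g)", cases$r[i], cases$theta[i]))
  }
})

test_that("geometry function symmetry, branch continuity and point-source limit", {
  # exact mirror symmetry about the transverse plane
  r <- c(0.25, 0.5, 1, 2, 5, 20)
  for (th in c(0, 10, 30, 70, 89)) {
    expect_identical(geometry_function(r, th), geometry_function(r, 180 - th))
  }
  # continuity across the on-axis branch switch (1e-6 degree band)
  eps <- 2e-6
  G0 <- geometry_function(r, 0)
  Geps <- geometry_function(r, eps)
  expect_lt(max(abs(Geps - G0) / G0), 1e-4)
  # point-source limit: G * r^2 -> 1 as L -> 0
  grid <- expand.grid(r = c(1, 2, 5, 10, 20), theta = c(0, 30, 60, 90))
  dev <- abs(geometry_function_normalized(grid$r, grid$theta, L = 1e-6) - 1)
  expect_lt(max(dev), 1e-8)
})

test_that("geometry function rejects points inside the line-source domain boundary", {
  expect_error(geometry_function(0.05, 0, L = 0.19), "L/2")
  expect_error(geometry_function(0, 90), "positive")
  expect_error(geometry_function(1, 200), "0, 180")
  expect_error(geometry_function(1, 90, L = -1), "positive")
})

test_that("dose-rate constant is the ratio of reference dose rate to air-kerma strength", {
  expect_identical(dose_rate_constant(1.104, 1), 1.104)
  expect_identical(dose_rate_constant(0, 5), 0)
  expect_equal(dose_rate_constant(2.208, 2), 1.104)
  expect_error(dose_rate_constant(1, 0), "Sk")
  # on a synthetic kernel with known amplitude and Sk = 1, the recovered
  # constant is the amplitude itself
  spec <- kernel_spec(lambda_true = 2.5)
  expect_equal(dose_rate_constant(evaluate_kernel(spec, 1, 90), 1), 2.5)
})

test_that("g(r) and F(r,theta) extraction invert a noise-free kernel exactly", {
  spec <- kernel_preset("gzp6-no3")
  s <- generate_samples(spec, r_nodes = c(0.5, 1, 2, 3, 5, 8),
                        theta_nodes = c(0, 15, 45, 90, 120, 165))
  g <- radial_dose_function(s, L = spec$L)
  expect_identical(g$g[g$r_cm == 1], 1)
  expect_lt(max(abs(g$g - kernel_g_true(spec, g$r_cm)) /
                  kernel_g_true(spec, g$r_cm)), 1e-10)
  Ft <- anisotropy_function(s, L = spec$L)
  expect_true(all(Ft$F[Ft$theta_deg == 90] == 1))
  Ftru <- kernel_F_true(spec, Ft$r_cm, Ft$theta_deg)
  expect_lt(max(abs(Ft$F - Ftru) / Ftru), 1e-10)
})

test_that("extraction demands the reference samples it normalizes by", {
  spec <- kernel_preset("gzp6-no3")
  s <- generate_samples(spec, r_nodes = c(2, 3), theta_nodes = c(45, 90))
  expect_error(radial_dose_function(s), "r0")
  s2 <- generate_samples(spec, r_nodes = c(1, 2), theta_nodes = c(0, 45))
  expect_error(anisotropy_function(s2), "r = 1")
})

test_that("table lookups after loading the packaged g and F tables", {
  g5 <- load_fixture("table5")
  expect_identical(g5$g[g5$r_cm == 5], 0.921)
  f6 <- load_fixture("table6")
  expect_identical(f6$F[f6$r_cm == 2 & f6$theta_deg == 0], 0.849)
})

test_that("quintic fit recovers exact polynomial data and beats any hand-supplied quintic", {
  # interpolation case: data generated exactly from a known quintic
  a_true <- c(1.01, -0.01, -0.004, 7e-4, -5e-5, 1.2e-6)
  r <- seq(1, 20, length.out = 12)
  g <- drop(outer(r, 0:5, `^`) %*% a_true)
  fit <- fit_radial_polynomial(data.frame(r_cm = r, g = g))
  expect_equal(unname(fit$coefficients), a_true, tolerance = 1e-8)
  expect_gt(fit$r_squared, 1 - 1e-12)
  expect_equal(evaluate_radial_polynomial(fit, r), g, tolerance = 1e-10)

  # least-squares optimality: no hand-supplied quintic can beat OLS R^2 on
  # the packaged radial table (reference check: the published coefficients)
  tab <- load_fixture("table5")
  fit5 <- fit_radial_polynomial(tab)
  a_pub <- c(1.0087, -0.01, -0.0039, 7e-4, -5e-5, 1e-6)
  pred <- drop(outer(tab$r_cm, 0:5, `^`) %*% a_pub)
  r2_pub <- 1 - sum((tab$g - pred)^2) / sum((tab$g - mean(tab$g))^2)
  expect_gte(fit5$r_squared, r2_pub)

  # degenerate designs are refused
  expect_error(fit_radial_polynomial(
    data.frame(r_cm = c(1, 1, 2, 3, 4, 5, 6), g = rep(1, 7))), "duplicate")
  expect_error(fit_radial_polynomial(
    data.frame(r_cm = 1:4, g = rep(1, 4))), "at least")
})

test_that("dose reconstruction reproduces the five-factor product", {
  p <- gzp6_parameter_set()
  # at the reference point with Sk = 1 U the product collapses to lambda
  expect_identical(reconstruct_dose_rate(p, 1, 1, 90), 1.104)
  # Sk scales linearly
  expect_equal(reconstruct_dose_rate(p, 3, 1, 90), 3 * 1.104)
  # transverse point at 2 cm: printed lambda and g(2) composed with the
  # analytic geometry ratio (independent integral oracle)
  expected <- 1.104 * 0.976 * oracle_geometry(2, 90) / oracle_geometry(1, 90)
  expect_equal(reconstruct_dose_rate(p, 1, 2, 90), expected, tolerance = 1e-9)
  expect_equal(reconstruct_dose_rate(p, 1, 2, 90), 0.26998, tolerance = 1e-4)
})

test_that("reconstruction extrapolation policy: strict errors, lenient clamps", {
  p <- gzp6_parameter_set()
  expect_error(reconstruct_dose_rate(p, 1, 25, 90), "largest tabulated")
  w <- capture_warnings(v <- reconstruct_dose_rate(p, 1, 25, 90,
                                                   mode = "lenient"))
  expect_true(any(grepl("clamping", w)))
  expect_gt(v, 0)
  # below the smallest tabulated radius: nearest column with warning
  w <- capture_warnings(v0 <- reconstruct_dose_rate(p, 1, 0.5, 90))
  expect_true(any(grepl("nearest", w)))
  expect_gt(v0, 0)
})

test_that("round trip: parameters extracted from a noise-free kernel reconstruct it", {
  spec <- kernel_preset("gzp6-no3")
  r_nodes <- c(1, 1.5, 2, 3, 4, 5, 7, 10)
  th_nodes <- c(0, 20, 40, 60, 80, 90, 100, 130, 160, 180)
  s <- generate_samples(spec, r_nodes, th_nodes)
  params <- tg43_parameter_set(
    lambda = dose_rate_constant(
      s$dose_rate[abs(s$r - 1) < 1e-9 & abs(s$theta - 90) < 1e-9][1], 1),
    L = spec$L,
    g_table = radial_dose_function(s, L = spec$L),
    F_table = anisotropy_function(s, L = spec$L))
  recon <- reconstruct_dose_rate(params, 1, s$r, s$theta)
  expect_lt(max(abs(recon - s$dose_rate) / s$dose_rate), 1e-10)
})

test_that("parameter sets serialize to JSON and back without loss", {
  p <- gzp6_parameter_set()
  path <- tempfile(fileext = ".json")
  write_tg43_params(p, path)
  q <- read_tg43_params(path)
  expect_equal(q$lambda, p$lambda)
  expect_equal(q$g_table, p$g_table)
  expect_equal(q$F_table, p$F_table, ignore_attr = TRUE)
})
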