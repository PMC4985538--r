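test_that("expected counts follow indirect standardisation", {
  g <- build_lattice_graph(2, 3)
  # one stratum, equal populations, known rate
  pop <- generate_population(g, strata = 1, seed = 1,
                             pop_range = c(1000, 1000), gamma = 0.01)
  expect_equal(pop$E, rep(10, g$n))

  # two strata, hand sum: 600*0.005 + 400*0.02 = 11
  N <- matrix(rep(c(600, 400), each = g$n), ncol = 2)
  expect_equal(indirect_standardise(N, c(0.005, 0.02)), rep(11, g$n))

  # closure: rates computed from realised deaths give sum(E) = sum(Y)
  set.seed(9)
  deaths <- matrix(rpois(2 * g$n, 5), ncol = 2)
  gam <- rates_from_counts(N, deaths)
  expect_equal(sum(indirect_standardise(N, gam)), sum(deaths))

  # defaults: populations in band, E near the seven-year scale
  pop <- generate_population(build_lattice_graph(10, 10), seed = 3)
  totals <- rowSums(pop$N)
  expect_true(all(totals >= 490 & totals <= 1000))
  expect_gt(mean(pop$E), 15)
  expect_lt(mean(pop$E), 40)
})

test_that("deprivation generator approaches its target correlation", {
  g <- build_lattice_graph(46, 46, n_keep = 2089)

  d0 <- generate_deprivation(g, target_corr = diag(6), seed = 2)
  C0 <- stats::cor(as.matrix(d0[, 1:6]))
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.08)   # 3/sqrt(n) sampling bound

  d1 <- generate_deprivation(g, seed = 2)
  C1 <- stats::cor(as.matrix(d1[, 1:6]))
  expect_equal(C1["income", "employment"], 0.946, tolerance = 0.02)
  expect_equal(C1["education", "income"], 0.860, tolerance = 0.03)
  expect_lt(C1["access", "housing"], 0)
  # composite correlates with its strongest domains
  expect_gt(stats::cor(d1$simd, d1$income), 0.5)

  # degenerate n = 2: sample correlations are exactly +/-1
  g2 <- build_lattice_graph(1, 2)
  d2 <- generate_deprivation(g2, seed = 1)
  C2 <- stats::cor(as.matrix(d2[, 1:6]))
  expect_equal(abs(C2[upper.tri(C2)]), rep(1, 15), tolerance = 1e-9)

  bad <- diag(6); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(generate_deprivation(g2, target_corr = bad), "unit diagonal|positive definite")
})

test_that("exposure pair honours degenerate and shifted calibrations", {
  g <- build_lattice_graph(6, 6)
  # zero-variance discrepancy + identity calibration -> identical surfaces
  em0 <- fusion_emulator(alpha = c(0, 1), sigma2 = 0)
  p0 <- generate_exposure_pair(g, em0, seed = 5)
  expect_identical(p0$x_modelled, p0$x_fusion)

  # +5 everywhere calibration
  em5 <- fusion_emulator(alpha = c(5, 1), sigma2 = 0)
  p5 <- generate_exposure_pair(g, em5, seed = 5)
  expect_equal(mean(p5$x_fusion - p5$x_modelled), 5, tolerance = 1e-9)
})

test_that("default exposure pair lands in the generator's own correlation band", {
  g <- build_lattice_graph(15, 15)
  em <- fusion_emulator()
  cors <- vapply(1:5, function(s) {
    p <- generate_exposure_pair(g, em, seed = 40 + s)
    stats::cor(p$x_modelled, p$x_fusion)
  }, numeric(1))
  expect_lt(abs(mean(cors) - em$corr_target), em$corr_tol)
})

test_that("count generator is seed-reproducible with mean SMR near 1 and an overflow guard", {
  g <- build_lattice_graph(12, 12)
  set.seed(1)
  x <- stats::rnorm(g$n, 18, 5)
  u <- stats::rnorm(g$n)
  Z <- build_design(x, u)
  E <- generate_population(g, seed = 2)$E

  truth <- scenario_truth(c(-beta_for_rr(1.02) * 18, beta_for_rr(1.02), 0),
                          rho = 0.8, tau2 = 0.05, seed = 7)
  a <- generate_counts(E, Z, truth, g)
  b <- generate_counts(E, Z, truth, g)
  expect_identical(a$counts$Y, b$counts$Y)
  expect_identical(a$truth$phi, b$truth$phi)
  expect_equal(mean(a$counts$smr), 1, tolerance = 0.1)
  expect_equal(sum(a$truth$phi), 0, tolerance = 1e-10)

  # null scenario: beta = 0, tiny field -> SMR approx 1 and equidispersion
  truth0 <- scenario_truth(c(0, 0, 0), rho = 0.5, tau2 = 1e-8, seed = 3)
  c0 <- generate_counts(E, Z, truth0, g)$counts
  expect_equal(mean(c0$Y / E), 1, tolerance = 0.05)
  disp <- overdispersion_statistic(c0$Y, E, Z)
  expect_lt(abs(disp - 1), 0.35)

  bad <- scenario_truth(c(40, 0, 0), rho = 0.5, tau2 = 0.01, seed = 1)
  expect_error(generate_counts(E, Z, bad, g), "overflow|eta")
  expect_error(scenario_truth(c(0, 0, 0), rho = 1, tau2 = 1), "improper|rho")
})

test_that("a smooth CAR scenario yields overdispersion and positive Moran's I", {
  g <- build_lattice_graph(15, 15)
  d <- sim_dataset(g, rr = 1.0, rho = 0.9, tau2 = 0.23, seed = 17, beta3 = 0)
  expect_gt(overdispersion_statistic(d$Y, d$E, d$Z), 2)
  mi <- morans_i_permutation_test(d$truth$phi, g, n_perm = 199, seed = 1)
  expect_lt(mi$p_value, 0.05)
})

test_that("a full study generates, writes and reads back consistently", {
  sc <- default_scenario(n = 48, rows = 7, cols = 7)
  st <- generate_study(sc, seed = 3)
  expect_equal(st$graph$n, 48)
  expect_true(all(c("Y", "E", "smr", "exposure_modelled", "exposure_fusion",
                    "income", "simd") %in% names(st$zones)))
  expect_true(all(st$zones$E > 0))
  # same seed -> identical study
  st2 <- generate_study(sc, seed = 3)
  expect_identical(st$zones, st2$zones)

  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)
  expect_equal(back$graph$W, st$graph$W, ignore_attr = TRUE)
  expect_equal(back$zones$Y, st$zones$Y)
  expect_equal(back$truth$beta, st$truth$beta, tolerance = 1e-12)
})

test_that("the default-scale scenario tracks its SMR targets", {
  # full-size study: mean SMR near 1.066 with zero-SMR zones present
  st <- generate_study(default_scenario(), seed = 11)
  expect_equal(st$graph$n, 2089)
  expect_equal(mean(st$zones$smr), 1.066, tolerance = 0.06)
  expect_gt(stats::sd(st$zones$smr), 0.2)
})
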