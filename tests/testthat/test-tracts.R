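# Ancestry switch rate, hazard integration and tract-length moments.

test_that("constant hazard gives the exponential distribution back", {
  c0 <- 40
  hz <- structure(list(r = seq(1e-6, 0.5, length.out = 2000),
                       tau = rep(c0, 2000), probe = 1e-6, r_max = 0.5,
                       tail_survival = exp(-c0 * 0.5), scenario = NULL,
                       trajectory_mode = "constant"),
                  class = "hazard_curve")
  d <- tract_length_distribution(hz)
  expect_lt(abs(d$one_sided_mean * c0 - 1), 1e-4)
  expect_lt(abs(d$mean * c0 / 2 - 1), 1e-4)
  expect_lt(abs(d$sd * c0 / sqrt(2) - 1), 1e-3)
  expect_equal(d$var, 2 * d$one_sided_var)
  expect_true(all(diff(d$survival) <= 0) && d$survival[1] <= 1)
})

test_that("switch rate is non-negative and decouples far from the sweep", {
  sc <- fig1_scenario()
  tr <- build_trajectory(sc)
  tau_far <- tau10(0.5, sc, tr)
  expect_gte(tau_far, 0)
  # ancestry is assigned at introgression time, so a locus far from the
  # selected site sees the neutral ancestry mosaic of an omega1-fraction
  # pulse, not the swept-up sampling frequency: its switch rate sits
  # near the constant-trajectory value at omega1 and far above the one
  # at the observed frequency omega0
  tau_at_omega1 <- tau10(0.5, scenario(omega1 = sc$omega1, T = sc$T,
                                       two_ne = sc$two_ne,
                                       mode = "constant"))
  tau_at_omega0 <- tau10(0.5, scenario(omega1 = 0.94, T = sc$T,
                                       two_ne = sc$two_ne,
                                       mode = "constant"))
  expect_lt(abs(tau_far / tau_at_omega1 - 1), 0.15)
  expect_gt(tau_far, 5 * tau_at_omega0)
  # near the selected site the sweep suppresses the switch rate below
  # the far-field mosaic level
  expect_lt(tau10(1e-4, sc, tr), tau_far)
})

test_that("halving the probe width barely moves the switch rate", {
  sc <- scenario(omega1 = 0.05, s = 0.01, T = 200, two_ne = 10000)
  tr <- build_trajectory(sc)
  r <- c(0.003, 0.03)
  t1 <- tau10(r, sc, tr, probe = 1e-6)
  t2 <- tau10(r, sc, tr, probe = 5e-7)
  expect_true(all(abs(t2 / t1 - 1) < 1e-3))
})

test_that("hazard grid is strictly increasing, finite, default 1000 points", {
  sc <- scenario(omega1 = 0.05, s = 0.01, T = 100, two_ne = 10000)
  expect_identical(sc$n_points, 1000L)
  hz <- hazard_curve(sc, n_points = 150)
  expect_true(all(diff(hz$r) > 0))
  expect_true(all(is.finite(hz$tau)) && all(hz$tau >= 0))
  expect_gt(hz$r[1], 0)
  expect_lt(hz$tail_survival, 1e-6)
})

test_that("neutral closed form matches its frozen values and limits", {
  expect_equal(neutral_expected_tract_length(0.1, 10, 20000), 0.222278,
               tolerance = 1e-6)
  expect_equal(neutral_expected_tract_length(6e-4, 2672, 20000), 0.00080,
               tolerance = 1e-3)
  # long-time limit 2 / (2Ne (1 - omega1))
  expect_equal(neutral_expected_tract_length(0.2, 1e9, 5000),
               2 / (5000 * 0.8), tolerance = 1e-9)
  # short-time limit 2 / ((1 - omega1) T)
  expect_equal(neutral_expected_tract_length(0.2, 0.01, 5000),
               2 / (0.8 * 0.01), tolerance = 1e-5)
})

test_that("constant-trajectory pipeline agrees with the neutral formula", {
  for (p in list(c(0.1, 10), c(0.1, 1000), c(0.01, 100))) {
    got <- expected_tract_length(
      scenario(omega1 = p[1], T = p[2], two_ne = 20000, mode = "constant",
               n_points = 400))
    expect_lt(
      abs(got / neutral_expected_tract_length(p[1], p[2], 20000) - 1),
      0.025)
  }
})

test_that("selection lengthens tracts at a fixed admixture fraction", {
  sel <- expected_tract_length(
    scenario(omega1 = 0.05, s = 0.01, T = 500, two_ne = 10000,
             n_points = 300))
  expect_gt(sel, neutral_expected_tract_length(0.05, 500, 10000))
})

test_that("expected length grows with omega1 and with s at fixed T", {
  by_omega <- vapply(c(0.01, 0.05, 0.1), function(om)
    expected_tract_length(scenario(omega1 = om, s = 0.05, T = 100,
                                   two_ne = 10000, n_points = 200)),
    numeric(1))
  expect_true(all(diff(by_omega) > 0))
  by_s <- vapply(c(0.01, 0.05, 0.1), function(s)
    expected_tract_length(scenario(omega1 = 0.05, s = s, T = 100,
                                   two_ne = 10000, n_points = 200)),
    numeric(1))
  expect_true(all(diff(by_s) > 0))
})

test_that("at fixed observed frequency stronger selection shortens tracts", {
  by_s <- vapply(c(0.01, 0.02, 0.05), function(s)
    expected_tract_length(scenario(omega0 = 0.5, s = s, T = 100,
                                   two_ne = 10000, n_points = 200)),
    numeric(1))
  expect_true(all(diff(by_s) < 0))
})

test_that("one-sided distribution is not exponential under a sweep", {
  m <- tract_model(omega1 = 0.1, s = 0.01, T = 1000, two_ne = 20000,
                   n_points = 400)
  d <- m$dist
  S_exp <- exp(-d$r / d$one_sided_mean)
  expect_gt(max(abs(d$survival - S_exp)), 0.02)
})

test_that("full-tract variance doubles the one-sided variance", {
  m <- tract_model(omega1 = 0.05, s = 0.01, T = 100, two_ne = 10000,
                   n_points = 200)
  expect_equal(m$dist$var, 2 * m$dist$one_sided_var)
  expect_equal(m$sd, sqrt(2 * m$dist$one_sided_var))
})
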