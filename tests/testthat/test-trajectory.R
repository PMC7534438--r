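# Logistic trajectory, its inverse, anchoring, and the conditioned-mean
# Wright-Fisher trajectory estimator.

test_that("logistic frequency and its closed-form inverse agree", {
  expect_equal(logistic_frequency(0, 0.01), 0.5)
  # frozen from the closed-form inverse t = (2/s) log((1-w)/w)
  expect_equal(logistic_frequency(439.44, 0.01), 0.1, tolerance = 1e-4)
  expect_equal(logistic_time(0.5, 0.037), 0)
  expect_equal(logistic_time(0.1, 0.01), 439.4445, tolerance = 1e-6)
  expect_equal(logistic_time(0.0006, 0.01), 1483.596, tolerance = 1e-6)
  # round trip over a wide parameter box; restricted to |s t / 2| < 18
  # because beyond that 1 - omega loses enough double-precision digits
  # to cancellation that no inverse can recover t to 1e-9
  for (s in c(0.001, 0.005, 0.02, 0.1)) {
    t <- seq(-2000, 2000, length.out = 41)
    ok <- abs(s * t / 2) < 18
    w <- logistic_frequency(t[ok], s)
    expect_equal(logistic_time(w, s), t[ok], tolerance = 1e-9)
  }
  # numerically stable far in the tails
  expect_identical(logistic_frequency(1e6, 0.01), 0)
  expect_identical(logistic_frequency(-1e6, 0.01), 1)
})

test_that("neutral selection coefficients are rejected with guidance", {
  expect_error(logistic_frequency(10, 0), "constant")
  expect_error(logistic_time(0.5, -0.01), "constant")
  expect_error(logistic_time(1.2, 0.01), "inside")
})

test_that("build_trajectory anchors t0/t1 in all three modes", {
  # constant mode is flat
  tr <- build_trajectory(scenario(omega1 = 0.1, T = 100, two_ne = 1000,
                                  mode = "constant"))
  tt <- c(tr$t0, (tr$t0 + tr$t1) / 2, tr$t1)
  expect_equal(trajectory_frequency(tr, tt), rep(0.1, 3))

  # logistic anchored at the admixture fraction; frozen closed-form values
  tr <- build_trajectory(scenario(omega1 = 0.05, s = 0.01, T = 1000,
                                  two_ne = 10000))
  expect_equal(tr$t1, 588.8878, tolerance = 1e-6)
  expect_equal(tr$t0, -411.1122, tolerance = 1e-6)
  expect_equal(trajectory_frequency(tr, tr$t0), 0.886516, tolerance = 1e-5)

  # observed-frequency parameterization implies the admixture fraction
  # (close to 0.1, matching the forward anchoring at omega1 = 0.1 whose
  # rounded sampling frequency is 0.94)
  tr <- build_trajectory(scenario(omega0 = 0.94, s = 0.01, T = 1000,
                                  two_ne = 10000))
  expect_equal(tr$omega1, 0.095481, tolerance = 1e-4)
  expect_equal(tr$omega1, 0.1, tolerance = 0.05)

  # inconsistent double parameterization is refused
  expect_error(
    build_trajectory(scenario(omega1 = 0.3, s = 0.01, T = 1000,
                              two_ne = 1000, omega0 = 0.94)),
    "inconsistent")

  # tabulated mode interpolates piecewise linearly in backward time
  tab <- data.frame(generation = 0:10, mean_frequency = seq(0.1, 0.6, 0.05))
  sc <- scenario(omega1 = 0.1, s = 0.01, T = 10, two_ne = 1000,
                 mode = "tabulated")
  tr <- build_trajectory(sc, table = tab)
  expect_equal(trajectory_frequency(tr, tr$t1), 0.1)      # introgression
  expect_equal(trajectory_frequency(tr, tr$t0), 0.6)      # sampling
  expect_equal(trajectory_frequency(tr, tr$t1 - 2.5), 0.225)
})

test_that("fig 1 sampling frequency of 0.94 falls out of the logistic", {
  tr <- build_trajectory(fig1_scenario())
  expect_equal(round(trajectory_frequency(tr, tr$t0), 2), 0.94)
})

test_that("neutral conditioned mean stays at its initial frequency", {
  # frequency is a martingale without selection; at omega1 = 0.5 and
  # 2Ne = 1000 loss over 50 generations is negligible
  tr <- conditional_mean_trajectory(0.5, 0, 1000, horizon = 50,
                                    n_reps = 2000, seed = 5)
  se <- 0.5 / sqrt(2000 * 1000 / 50) # generous envelope
  expect_true(all(abs(tr$table$mean_frequency - 0.5) < 0.02))
  expect_equal(mean(tr$table$mean_frequency), 0.5, tolerance = 3 * se + 1e-3)
})

test_that("conditioning is negligible when loss is improbable", {
  # initial count 0.1 * 2Ne: conditioned and unconditioned means within
  # 1%. With per-generation conditioning, lost replicates contribute
  # zero frequency, so the unconditioned mean is the conditioned mean
  # scaled by the surviving fraction.
  tr <- conditional_mean_trajectory(0.1, 0.02, 2000, horizon = 100,
                                    n_reps = 5000, seed = 9,
                                    condition = "generation")
  uncond <- tr$table$mean_frequency * tr$table$n_surviving / 5000
  expect_true(all(abs(tr$table$mean_frequency / uncond - 1) < 0.01))
})

test_that("conditioning accelerates the sweep for rare alleles", {
  # Denisovan-like pulse: conditioned mean reaches the target frequency
  # earlier than the deterministic logistic does
  tr <- conditional_mean_trajectory(6e-4, 0.02, 10000, horizon = 1200,
                                    n_reps = 5000, seed = 13)
  t_cond <- time_to_frequency(tr, 0.5)
  t_det <- logistic_time(6e-4, 0.02) - logistic_time(0.5, 0.02)
  expect_lt(t_cond, t_det)
  # conditioned mean dominates the unconditioned mean everywhere
  uncond_mean <- 6e-4 # unconditioned WF mean grows slower than conditioned
  expect_true(all(diff(tr$table$mean_frequency) > -0.02))
  expect_true(all(tr$table$mean_frequency >= uncond_mean - 1e-12))
})

test_that("the two conditioning events give nearly identical means here", {
  a <- conditional_mean_trajectory(0.01, 0.05, 2000, horizon = 200,
                                   n_reps = 4000, seed = 3)
  b <- conditional_mean_trajectory(0.01, 0.05, 2000, horizon = 200,
                                   n_reps = 4000, seed = 3,
                                   condition = "generation")
  expect_true(all(a$table$mean_frequency >= b$table$mean_frequency - 1e-9))
  expect_lt(max(abs(a$table$mean_frequency - b$table$mean_frequency)) /
              max(b$table$mean_frequency), 0.05)
})

test_that("time_to_frequency is self-consistent and handles edges", {
  # tabulate the logistic itself: crossing time recovers T
  sc <- scenario(omega1 = 0.1, s = 0.01, T = 300, two_ne = 10000)
  tr <- build_trajectory(sc)
  g <- 0:300
  tab <- data.frame(generation = g,
                    mean_frequency = trajectory_frequency(tr, tr$t1 - g))
  ttr <- build_trajectory(
    scenario(omega1 = 0.1, s = 0.01, T = 300, two_ne = 10000,
             mode = "tabulated"), table = tab)
  target <- tab$mean_frequency[301]
  expect_equal(time_to_frequency(ttr, target), 300)
  expect_equal(time_to_frequency(ttr, target, interpolate = TRUE), 300,
               tolerance = 1e-6)
  # target below the initial frequency
  expect_equal(time_to_frequency(ttr, 0.05), 0)
  # unreachable target
  expect_error(time_to_frequency(ttr, 0.999), "never reaches")
})

test_that("trajectory TSV round-trips through write/read", {
  tr <- conditional_mean_trajectory(0.2, 0.01, 500, horizon = 20,
                                    n_reps = 1000, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$table$mean_frequency, tr$table$mean_frequency)
  expect_equal(tr2$table$n_surviving, tr$table$n_surviving)
  expect_equal(tr2$meta$two_ne, 500)
  unlink(f)
})
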