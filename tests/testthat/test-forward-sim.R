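# Forward diploid Wright-Fisher admixture simulator with junction tracking.

test_that("tracts partition the chromosome with alternating ancestry", {
  cfg <- sim_config(N = 200, omega1 = 0.3, s = 0, T = 30, seed = 1)
  pop <- simulate_admixture(cfg)
  tr <- sample_tracts(pop, n_chromosomes = 50, seed = 2)
  for (chr in split(tr, tr$chromosome)) {
    expect_equal(chr$start[1], 0)
    expect_equal(chr$end[nrow(chr)], cfg$L)
    if (nrow(chr) > 1) {
      expect_equal(chr$start[-1], chr$end[-nrow(chr)])
      expect_true(all(diff(chr$ancestry) != 0))
    }
  }
})

test_that("generation zero is junction-free and matches the pulse", {
  cfg <- sim_config(N = 500, omega1 = 0.2, s = 0, T = 1, seed = 3)
  pop <- simulate_admixture(cfg)
  expect_equal(pop$freq_path[1], 0.2)
  # after one neutral generation the donor fraction stays near omega1
  tr <- sample_tracts(pop, n_chromosomes = 1000, seed = 4)
  donor <- sum((tr$end - tr$start)[tr$ancestry == 1])
  total <- sum(tr$end - tr$start)
  se <- sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(donor / total - 0.2), 3 * se + 0.01)
})

test_that("focal tract has donor ancestry iff the chromosome carries A", {
  cfg <- sim_config(N = 300, omega1 = 0.2, s = 0.05, T = 40, seed = 7)
  pop <- simulate_admixture(cfg)
  tr <- sample_tracts(pop, n_chromosomes = 600, focal_position = 0.5,
                      seed = 8)
  expect_equal(nrow(tr), 600) # exactly one covering tract per chromosome
  expect_equal(tr$ancestry, pop$allele[tr$chromosome])
})

test_that("selected-site path matches the haploid binomial sampler", {
  # distributional check at s = 0: per-generation mean and variance of
  # the diploid junction simulator's allele path vs the haploid sampler
  set.seed(11)
  n_rep <- 60; Tg <- 25; N <- 150
  dip <- replicate(n_rep, {
    simulate_admixture(sim_config(N = N, omega1 = 0.3, s = 0, T = Tg),
                       seed = NULL)$freq_path[Tg + 1]
  })
  hap <- replicate(n_rep, {
    k <- as.integer(0.3 * 2 * N)
    for (g in 1:Tg) k <- rbinom(1, 2 * N, k / (2 * N))
    k / (2 * N)
  })
  expect_equal(mean(dip), mean(hap), tolerance = 0.1)
  expect_lt(abs(var(dip) - var(hap)) / var(hap), 0.75)
})

test_that("junction count grows with time since admixture", {
  nj <- vapply(c(5L, 40L, 160L), function(Tg) {
    pop <- simulate_admixture(
      sim_config(N = 150, omega1 = 0.3, s = 0, T = Tg), seed = 20 + Tg)
    mean(lengths(pop$breaks))
  }, numeric(1))
  expect_true(all(diff(nj) > 0))
})

test_that("neutral short-time empirical mean matches the closed form", {
  cfg <- sim_config(N = 500, omega1 = 0.2, s = 0, T = 20)
  set.seed(31)
  lens <- unlist(lapply(1:40, function(i) {
    pop <- simulate_admixture(cfg, seed = NULL)
    tr <- sample_tracts(pop, n_chromosomes = 1000, focal_position = 0.5,
                        replicate = i)
    (tr$end - tr$start)[tr$ancestry == 1]
  }))
  # chromosome edges truncate tracts; compare against the edge-aware
  # expectation E[min(X1, 0.5) + min(X2, 0.5)] for one-sided exponentials
  # with the neutral hazard, a good approximation at T = 20
  m_free <- neutral_expected_tract_length(0.2, 20, 1000)
  rate <- 2 / m_free
  m_edge <- 2 * (1 - exp(-rate * 0.5)) / rate
  expect_equal(mean(lens), m_edge, tolerance = 0.1)
})

test_that("empirical_summary pools and splits variance as documented", {
  tracts <- data.frame(replicate = c(1, 1, 2, 2),
                       start = 0, end = c(0.2, 0.2, 0.4, 0.4),
                       ancestry = 1)
  s <- empirical_summary(tracts)
  expect_equal(s$mean, 0.3)
  expect_equal(s$sd_within, 0)
  expect_gt(s$sd_across, 0)
  expect_equal(s$n_tracts, 4L)
  expect_error(empirical_summary(tracts[1, ]), "fewer than two")
  # ancestry filter
  tracts$ancestry <- c(1, 0, 0, 0)
  expect_error(empirical_summary(tracts), "fewer than two")
})

test_that("identical seeds reproduce the simulation bit for bit", {
  cfg <- sim_config(N = 100, omega1 = 0.1, s = 0.02, T = 15)
  a <- simulate_admixture(cfg, seed = 99)
  b <- simulate_admixture(cfg, seed = 99)
  expect_identical(a$anc0, b$anc0)
  expect_identical(a$breaks, b$breaks)
  expect_identical(a$freq_path, b$freq_path)
})
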