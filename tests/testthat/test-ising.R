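test_that("normalize_coupling rescales, zeroes the diagonal and rejects degenerate input", {
  expect_equal(normalize_coupling(matrix(c(0, 4, 4, 0), 2)),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  expect_equal(normalize_coupling(matrix(c(5, 4, 4, 5), 2)),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  expect_error(normalize_coupling(matrix(0, 2, 2)), "positive")
  expect_error(normalize_coupling(matrix(c(0, -1, -1, 0), 2)), "negative")
  # mean normalization fixes the off-diagonal mean at 1
  J <- normalize_coupling(random_J(6) + 0.1, method = "mean")
  expect_equal(sum(J) / (6 * 5), 1, tolerance = 1e-12)
})

test_that("total energy follows the double-sum convention and a loop oracle", {
  J <- matrix(c(0, 1, 1, 0), 2)
  expect_identical(total_energy(J, c(1, 1)), -2)
  expect_identical(total_energy(J, c(1, -1)), 2)
  withr::with_seed(11, {
    for (i in 1:20) {
      J <- random_J(4)
      s <- sample(c(-1, 1), 4, replace = TRUE)
      expect_equal(total_energy(J, s), energy_double_loop(J, s),
                   tolerance = 1e-12)
    }
  })
  expect_error(total_energy(J, c(1, 1, 1)), "length")
})

test_that("delta_energy equals the explicit flip-and-recompute difference", {
  J <- matrix(c(0, 1, 1, 0), 2)
  expect_identical(delta_energy(J, c(1, 1), 1), 4)
  expect_identical(delta_energy(J, c(1, -1), 1), -4)
  withr::with_seed(7, {
    for (i in 1:100) {
      n <- sample(3:8, 1)
      J <- random_J(n)
      s <- sample(c(-1, 1), n, replace = TRUE)
      k <- sample(n, 1)
      s2 <- s
      s2[k] <- -s2[k]
      expect_equal(delta_energy(J, s, k),
                   energy_double_loop(J, s2) - energy_double_loop(J, s),
                   tolerance = 1e-10)
    }
  })
  expect_error(delta_energy(matrix(c(0, 1, 1, 0), 2), c(1, 1), 3),
               "out of range")
})

test_that("metropolis_sweep freezes an ordered ferromagnet at tiny temperature", {
  J <- uniform_J(6, 1)
  s <- rep(1L, 6)
  withr::with_seed(1, {
    for (i in 1:20) expect_identical(metropolis_sweep(J, s, 1e-6), s)
  })
  expect_error(metropolis_sweep(J, s, 0), "positive")
})

test_that("long-run state frequencies match the Boltzmann distribution (N=3)", {
  J <- uniform_J(3, 0.2)
  exact <- enum_boltzmann(J, 1.0)
  p <- sim_params(temperature = 1.0, n_equil_sweeps = 1000,
                  n_samples = 200000, sample_interval_sweeps = 2, seed = 42)
  tr <- simulate_at_temperature(J, p)
  key <- tr$samples %*% c(1, 2, 4)  # injective over the 8 states
  exact_key <- exact$states %*% c(1, 2, 4)
  counts <- vapply(exact_key, function(k) sum(key == k), numeric(1))
  gof <- suppressWarnings(stats::chisq.test(counts, p = exact$p))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulate_at_temperature honours the sampling contract and seed", {
  J <- uniform_J(5, 0.2)
  p <- sim_params(temperature = 1.2, n_equil_sweeps = 50, n_samples = 100,
                  sample_interval_sweeps = 3, seed = 9)
  tr <- simulate_at_temperature(J, p)
  expect_identical(dim(tr$samples), c(100L, 5L))
  expect_true(all(tr$samples %in% c(-1L, 1L)))
  expect_equal(tr$magnetization, rowMeans(tr$samples), tolerance = 1e-12)
  # stored energies equal the energy of the stored configurations
  recomputed <- apply(tr$samples, 1L, function(s) total_energy(J, s))
  expect_equal(tr$energy, recomputed, tolerance = 1e-9)
  # bit-identical reproduction from the same params
  tr2 <- simulate_at_temperature(J, p)
  expect_identical(tr$samples, tr2$samples)
  # a fixed initial configuration is honoured
  tr3 <- simulate_at_temperature(J, sim_params(temperature = 1e-6, seed = 2,
                                               n_equil_sweeps = 0,
                                               n_samples = 5,
                                               sample_interval_sweeps = 1),
                                 initial = rep(1, 5))
  expect_true(all(tr3$samples == 1L))
})

test_that("the disordered limit has near-zero mean magnetization", {
  J <- normalize_coupling(geometric_connectome(n = 84, seed = 3))
  p <- sim_params(temperature = 100 * 84, n_equil_sweeps = 50,
                  n_samples = 400, sample_interval_sweeps = 1, seed = 5)
  tr <- simulate_at_temperature(J, p)
  expect_lt(abs(mean(tr$magnetization)), 0.1)
})

test_that("susceptibility matches its definition, enumeration, and symmetries", {
  # constant magnetization -> zero
  tr <- structure(list(samples = matrix(1L, 10, 2),
                       magnetization = rep(1, 10),
                       energy = rep(-2, 10),
                       params = sim_params(temperature = 1)),
                  class = "spin_trace")
  expect_equal(susceptibility(tr), 0)
  # +1/-1 alternating magnetization folds to zero under the |m| convention
  tr$magnetization <- rep(c(1, -1), 5)
  expect_equal(susceptibility(tr), 0)
  expect_error(susceptibility(structure(list(samples = matrix(1L, 1, 2),
                                             magnetization = 1, energy = -2,
                                             params = sim_params()),
                                        class = "spin_trace")),
               "2 samples")
  # invariance under a global spin flip of every sample
  J <- uniform_J(5, 0.2)
  tr <- simulate_at_temperature(J, sim_params(temperature = 1.5, seed = 8,
                                              n_equil_sweeps = 100,
                                              n_samples = 500,
                                              sample_interval_sweeps = 1))
  flipped <- tr
  flipped$samples <- -tr$samples
  flipped$magnetization <- -tr$magnetization
  expect_equal(susceptibility(flipped), susceptibility(tr), tolerance = 1e-12)
  # enumeration oracle at N=5
  exact <- enum_boltzmann(J, 1.5)
  mc <- mc_moments(J, 1.5, n_runs = 6, seed0 = 21)
  expect_lt(abs(mc$mean["chi"] - exact$chi), 3 * mc$se["chi"] + 1e-6)
})

test_that("mean |m| decreases with temperature for a ferromagnet", {
  J <- uniform_J(8, 0.3)
  t_hat <- mean_field_tc(J)
  temps <- c(0.2, 0.6, 1.0, 1.6, 3) * t_hat
  mabs <- vapply(temps, function(T) {
    tr <- simulate_at_temperature(J, sim_params(temperature = T, seed = 4,
                                                n_equil_sweeps = 400,
                                                n_samples = 800,
                                                sample_interval_sweeps = 1))
    mean(abs(tr$magnetization))
  }, numeric(1))
  expect_gt(mabs[1], 0.95)                      # ordered limit
  expect_lt(mabs[5], 3 / sqrt(8))               # disordered, O(N^-1/2)
  expect_true(all(diff(mabs) < 0.05))           # non-increasing within MC error
})
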