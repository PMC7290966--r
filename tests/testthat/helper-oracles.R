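# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: energies by explicit double loops, Boltzmann
# moments by exhaustive state enumeration, Mantel p-values by enumerating
# all node permutations.

# Explicit O(N^2) double-loop energy (full double-sum convention).
energy_double_loop <- function(J, s) {
  e <- 0
  n <- nrow(J)
  for (i in seq_len(n)) for (j in seq_len(n)) e <- e - J[i, j] * s[i] * s[j]
  e
}

# All 2^N spin configurations as rows.
all_states <- function(n) {
  as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
}

# Exact Boltzmann moments of magnetization at temperature T.
enum_boltzmann <- function(J, temperature) {
  states <- all_states(nrow(J))
  E <- apply(states, 1L, function(s) energy_double_loop(J, s))
  w <- exp(-(E - min(E)) / temperature)
  p <- w / sum(w)
  m <- rowMeans(states)
  list(states = states, E = E, p = p,
       m2 = sum(p * m^2), mabs = sum(p * abs(m)),
       chi = nrow(J) * (sum(p * m^2) - sum(p * abs(m))^2) / temperature)
}

# Monte-Carlo estimate with a standard error taken over independent runs.
mc_moments <- function(J, temperature, n_runs = 8, seed0 = 1,
                       params = sim_params(n_equil_sweeps = 500,
                                           n_samples = 2000,
                                           sample_interval_sweeps = 2)) {
  per_run <- vapply(seq_len(n_runs), function(r) {
    p <- params
    p$temperature <- temperature
    p$seed <- derive_seed(seed0, "mc-oracle", temperature, r)
    tr <- simulate_at_temperature(J, p)
    c(m2 = mean(tr$magnetization^2),
      mabs = mean(abs(tr$magnetization)),
      chi = susceptibility(tr))
  }, c(m2 = 0, mabs = 0, chi = 0))
  list(mean = rowMeans(per_run),
       se = apply(per_run, 1L, stats::sd) / sqrt(n_runs))
}

# Small uniform coupling matrix (off-diagonal j, zero diagonal).
uniform_J <- function(n, j) {
  J <- matrix(j, n, n)
  diag(J) <- 0
  J
}

# Random symmetric non-negative coupling matrix with zero diagonal.
random_J <- function(n, scale = 1) {
  m <- matrix(runif(n * n), n, n) * scale
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
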