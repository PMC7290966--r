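#' Simulation parameters for the spin model
#'
#' Bundles the Metropolis Monte Carlo settings for one temperature:
#' equilibration length, number of recorded samples, sampling interval and
#' seed. Temperature is dimensionless (Boltzmann constant set to 1).
#'
#' @param temperature Positive bath temperature.
#' @param n_equil_sweeps Sweeps discarded before sampling (>= 0).
#' @param n_samples Number of recorded spin configurations (>= 2).
#' @param sample_interval_sweeps Sweeps between recorded samples (>= 1).
#' @param seed Integer RNG seed for the trajectory.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(temperature = 1, n_equil_sweeps = 1000,
                       n_samples = 1000, sample_interval_sweeps = 2,
                       seed = 1L) {
  stopifnot(temperature > 0, n_equil_sweeps >= 0, n_samples >= 2,
            sample_interval_sweeps >= 1)
  structure(list(temperature = temperature,
                 n_equil_sweeps = as.integer(n_equil_sweeps),
                 n_samples = as.integer(n_samples),
                 sample_interval_sweeps = as.integer(sample_interval_sweeps),
                 seed = as.integer(seed)),
            class = "sim_params")
}

check_spins <- function(s, n = NULL) {
  if (!is.numeric(s) || !all(s %in% c(-1, 1)))
    stop("spin configuration must contain only +1 and -1")
  if (!is.null(n) && length(s) != n)
    stop("spin configuration length ", length(s), " does not match ", n, " regions")
  as.integer(s)
}

random_spins <- function(n) {
  ifelse(runif(n) < 0.5, 1L, -1L)
}

#' Total energy of a spin configuration
#'
#' `E = -sum_{i,j} J_ij s_i s_j` over the full double index range: each
#' unordered pair contributes twice (the diagonal is zero). All temperatures
#' reported by this package are on the scale set by this convention.
#'
#' @param J Coupling matrix.
#' @param s Spin vector with entries +1/-1.
#' @return Scalar energy.
#' @examples
#' total_energy(matrix(c(0, 1, 1, 0), 2), c(1, 1))  # -2
#' @export
total_energy <- function(J, s) {
  validate_coupling(J)
  s <- check_spins(s, nrow(J))
  -drop(crossprod(s, J %*% s))
}

#' Energy change of a single spin flip
#'
#' Incremental form of the double-sum energy: flipping spin `k` changes the
#' energy by `4 * s_k * sum_j J_kj s_j`.
#'
#' @param J Coupling matrix.
#' @param s Current spin vector.
#' @param k Region index (1-based).
#' @return Scalar energy difference (flipped minus current).
#' @export
delta_energy <- function(J, s, k) {
  validate_coupling(J)
  s <- check_spins(s, nrow(J))
  if (!(k %in% seq_len(nrow(J)))) stop("region index out of range: ", k)
  4 * s[k] * drop(J[k, ] %*% s)
}

#' One Metropolis sweep
#'
#' Proposes `N` single-spin flips at uniformly random sites (with
#' replacement); each proposal is accepted with probability
#' `min(1, exp(-dE/T))`. Randomness comes from R's RNG, so `set.seed()`
#' makes the sweep reproducible.
#'
#' @param J Coupling matrix.
#' @param s Spin vector.
#' @param temperature Positive temperature.
#' @param n_sweeps Number of sweeps to perform (default 1).
#' @return Updated spin vector (integer +1/-1).
#' @export
metropolis_sweep <- function(J, s, temperature, n_sweeps = 1L) {
  validate_coupling(J)
  if (temperature <= 0) stop("temperature must be positive")
  s <- check_spins(s, nrow(J))
  cpp_metropolis_sweeps(unname(J), s, temperature, as.integer(n_sweeps))
}

#' Simulate the spin model at one temperature
#'
#' Starts from a random (or given) configuration, discards
#' `n_equil_sweeps`, then records `n_samples` configurations every
#' `sample_interval_sweeps` sweeps. The recorded trace carries the
#' per-sample magnetization and (exactly recomputed) energy series.
#' Identical parameters and seed give a bit-identical trace.
#'
#' @param J Coupling matrix.
#' @param params A [sim_params()] object.
#' @param initial `"random"` (default) or a +1/-1 vector of length `N`.
#' @return An object of class `spin_trace` with elements `samples`
#'   (`n_samples` x `N` integer matrix), `magnetization`, `energy`,
#'   `acceptance_rate` and `params`.
#' @export
simulate_at_temperature <- function(J, params, initial = "random") {
  validate_coupling(J)
  stopifnot(inherits(params, "sim_params"))
  out <- with_seed(params$seed, {
    init <- if (identical(initial, "random")) random_spins(nrow(J))
            else check_spins(initial, nrow(J))
    cpp_ising_simulate(unname(J), init, params$temperature,
                       params$n_equil_sweeps, params$n_samples,
                       params$sample_interval_sweeps)
  })
  structure(list(samples = out$samples,
                 magnetization = as.numeric(out$magnetization),
                 energy = as.numeric(out$energy),
                 acceptance_rate = out$acceptance_rate,
                 params = params),
            class = "spin_trace")
}

#' @export
print.spin_trace <- function(x, ...) {
  cat("Spin trace:", nrow(x$samples), "samples of", ncol(x$samples),
      "spins at T =", format(x$params$temperature, digits = 4), "\n")
  cat("  mean |m| =", format(mean(abs(x$magnetization)), digits = 4),
      " mean E =", format(mean(x$energy), digits = 4),
      " acceptance =", format(x$acceptance_rate, digits = 3), "\n")
  invisible(x)
}

#' Magnetic susceptibility of a spin trace
#'
#' `chi = N * (<m^2> - <|m|>^2) / T` from the trace's sample moments. The
#' absolute-magnetization convention avoids the spurious inflation a finite
#' system's tunnelling between the +m and -m branches would cause below the
#' critical temperature; set `use_abs = FALSE` for the raw `<m>` estimator.
#'
#' @param trace A `spin_trace`.
#' @param use_abs Use `<|m|>` (default) or `<m>` in the centred moment.
#' @return Non-negative scalar (the `use_abs` form; the raw form can be
#'   negative only through sampling noise, not in expectation).
#' @export
susceptibility <- function(trace, use_abs = TRUE) {
  stopifnot(inherits(trace, "spin_trace"))
  m <- trace$magnetization
  if (length(m) < 2) stop("need at least 2 samples for susceptibility")
  N <- ncol(trace$samples)
  centre <- if (use_abs) mean(abs(m)) else mean(m)
  N * (mean(m^2) - centre^2) / trace$params$temperature
}
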