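#' Default temperature grid for a coupling matrix
#'
#' Linear grid from `0.1 * T_hat` to `3 * T_hat`, where `T_hat` is the
#' mean-field critical-temperature anchor [mean_field_tc()]. The window is
#' wide enough to show the ordered plateau, the susceptibility peak and the
#' disordered tail for connectome-like matrices.
#'
#' @param J Coupling matrix.
#' @param n_points Number of grid points (>= 5, default 30).
#' @return Strictly ascending numeric vector of temperatures.
#' @export
default_temperature_grid <- function(J, n_points = 30L) {
  stopifnot(n_points >= 5)
  t_hat <- mean_field_tc(J)
  seq(0.1 * t_hat, 3 * t_hat, length.out = as.integer(n_points))
}

#' Temperature sweep with repeated simulations
#'
#' Simulates the spin model at every grid temperature `n_runs` times, each
#' run from a fresh random start with its own deterministic sub-seed, and
#' assembles the run-averaged susceptibility curve. Per-run simulated
#' functional connectivity (Pearson correlation of the spin samples) is
#' retained by default so the best-fit temperature search can reuse the
#' sweep instead of re-simulating.
#'
#' @param J Coupling matrix.
#' @param grid Ascending vector of positive temperatures (default
#'   [default_temperature_grid()]).
#' @param params Template [sim_params()]; its temperature and seed are
#'   overridden per grid point and run.
#' @param n_runs Independent repeats per temperature (default 10).
#' @param master_seed Master seed from which all per-(T, run) sub-seeds are
#'   derived.
#' @param subject_id Label entering the sub-seed derivation (keeps subjects
#'   independent under one master seed).
#' @param retain `"fc"` (default) keeps the run-averaged and per-run
#'   simulated FC per temperature; `"traces"` additionally keeps the raw
#'   spin traces; `"none"` keeps only the susceptibility curve.
#' @return An object of class `susceptibility_curve`: `temperatures`,
#'   `chi_mean`, `chi_per_run` (`n_runs` x `n_temperatures`), `mean_abs_m`,
#'   `acceptance_rate`, and (per `retain`) `fc_mean`, `fc_runs`, `traces`.
#' @export
temperature_sweep <- function(J, grid = default_temperature_grid(J),
                              params = sim_params(), n_runs = 10L,
                              master_seed = 1L, subject_id = "subject",
                              retain = c("fc", "traces", "none")) {
  validate_coupling(J)
  retain <- match.arg(retain)
  stopifnot(n_runs >= 1, length(grid) >= 1, all(grid > 0),
            !is.unsorted(grid, strictly = TRUE))
  nT <- length(grid)
  chi <- matrix(NA_real_, nrow = n_runs, ncol = nT)
  mam <- acc <- numeric(nT)
  fc_mean <- vector("list", nT)
  fc_runs <- if (retain != "none") vector("list", nT)
  traces <- if (retain == "traces") vector("list", nT)

  for (ti in seq_len(nT)) {
    run_fcs <- vector("list", n_runs)
    run_traces <- vector("list", n_runs)
    mam_t <- acc_t <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      p <- params
      p$temperature <- grid[ti]
      p$seed <- derive_seed(master_seed, subject_id, "sweep", ti, r)
      tr <- simulate_at_temperature(J, p)
      chi[r, ti] <- susceptibility(tr)
      mam_t[r] <- mean(abs(tr$magnetization))
      acc_t[r] <- tr$acceptance_rate
      if (retain != "none")
        run_fcs[[r]] <- pearson_correlation_matrix(tr$samples, kind = "simulated")
      if (retain == "traces") run_traces[[r]] <- tr
    }
    mam[ti] <- mean(mam_t)
    acc[ti] <- mean(acc_t)
    if (retain != "none") {
      fc_runs[[ti]] <- run_fcs
      fc_mean[[ti]] <- average_fc_over_runs(run_fcs)
    }
    if (retain == "traces") traces[[ti]] <- run_traces
  }
  structure(list(temperatures = grid,
                 chi_mean = colMeans(chi),
                 chi_per_run = chi,
                 n_runs = as.integer(n_runs),
                 mean_abs_m = mam,
                 acceptance_rate = acc,
                 fc_mean = if (retain != "none") fc_mean,
                 fc_runs = if (retain != "none") fc_runs,
                 traces = traces,
                 params = params,
                 master_seed = master_seed,
                 subject_id = subject_id),
            class = "susceptibility_curve")
}

#' @export
print.susceptibility_curve <- function(x, ...) {
  cat("Susceptibility curve:", length(x$temperatures), "temperatures in [",
      format(min(x$temperatures), digits = 4), ",",
      format(max(x$temperatures), digits = 4), "],", x$n_runs, "runs\n")
  pk <- which.max(x$chi_mean)
  cat("  peak chi =", format(x$chi_mean[pk], digits = 4), "at T =",
      format(x$temperatures[pk], digits = 4), "\n")
  invisible(x)
}

#' @export
plot.susceptibility_curve <- function(x, show_runs = TRUE, ...) {
  graphics::matplot(x$temperatures, t(x$chi_per_run), type = "l", lty = 3,
                    col = "grey60", xlab = "temperature T",
                    ylab = expression(chi), ...)
  graphics::lines(x$temperatures, x$chi_mean, lwd = 2)
  graphics::abline(v = x$temperatures[which.max(x$chi_mean)], lty = 2, col = 2)
  invisible(x)
}

#' Locate the critical temperature on a susceptibility curve
#'
#' The critical temperature is the grid point maximizing the (optionally
#' moving-average smoothed) run-averaged susceptibility; ties break toward
#' the lowest temperature. Alternatively `per_run = TRUE` locates a peak on
#' each run's curve and averages the peak temperatures.
#'
#' @param curve A `susceptibility_curve`.
#' @param smooth_window Odd moving-average window (default 1 = none).
#' @param per_run Average per-run peak locations instead of the peak of the
#'   averaged curve (default `FALSE`).
#' @return A list of class `criticality_result` with `Tc`, `chi_at_Tc`,
#'   `Tc_index` (`NA` when `per_run`), and `curve`.
#' @export
find_critical_temperature <- function(curve, smooth_window = 1L,
                                      per_run = FALSE) {
  stopifnot(inherits(curve, "susceptibility_curve"))
  grid <- curve$temperatures
  if (length(grid) < 3) stop("need at least 3 grid points")
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1 || smooth_window %% 2 == 0)
    stop("smooth_window must be a positive odd integer")
  if (smooth_window > length(grid)) stop("smooth_window larger than the grid")

  peak_of <- function(y) {
    if (smooth_window > 1) {
      k <- (smooth_window - 1L) %/% 2L
      y <- vapply(seq_along(y), function(i)
        mean(y[max(1, i - k):min(length(y), i + k)]), numeric(1))
    }
    which.max(y)  # which.max already breaks ties toward the first (lowest T)
  }
  if (per_run) {
    idx <- apply(curve$chi_per_run, 1L, peak_of)
    Tc <- mean(grid[idx])
    res <- list(Tc = Tc, Tc_index = NA_integer_,
                chi_at_Tc = NA_real_, per_run_Tc = grid[idx], curve = curve)
  } else {
    i <- peak_of(curve$chi_mean)
    res <- list(Tc = grid[i], Tc_index = i, chi_at_Tc = curve$chi_mean[i],
                per_run_Tc = NULL, curve = curve)
  }
  class(res) <- "criticality_result"
  res
}

#' @export
print.criticality_result <- function(x, ...) {
  cat("Critical temperature Tc =", format(x$Tc, digits = 5), "\n")
  invisible(x)
}
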