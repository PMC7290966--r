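#' Analysis configuration
#'
#' All tunable settings for a subject- or cohort-level analysis in one
#' serializable object. The defaults are the package's reference settings;
#' `n_grid`, `n_runs` and the simulation lengths are the main cost knobs.
#'
#' @param n_grid Temperature-grid points (default 30).
#' @param grid Explicit temperature grid (overrides `n_grid` when given).
#' @param sim Template [sim_params()].
#' @param n_runs Repeats per temperature (default 10, as in the protocol
#'   this package models).
#' @param smooth_window Susceptibility-peak smoothing window (odd; default
#'   1).
#' @param mantel_permutations Permutations for the Mantel p-value at the
#'   best-fit temperature (default 10000).
#' @param normalization Coupling normalization, `"max"` or `"mean"`.
#' @param distance_map Connectome-distance map, `"reciprocal"` or
#'   `"neglog"`.
#' @param n_bins,min_pairs_per_bin,eta Dimensionality settings.
#' @param fc_source FC source for dimensionality (default
#'   `"simulated_at_Tc"`).
#' @param master_seed Master seed; all sub-seeds derive from it.
#' @return List of class `gim_config`.
#' @export
gim_config <- function(n_grid = 30L, grid = NULL, sim = sim_params(),
                       n_runs = 10L, smooth_window = 1L,
                       mantel_permutations = 10000L,
                       normalization = c("max", "mean"),
                       distance_map = c("reciprocal", "neglog"),
                       n_bins = 12L, min_pairs_per_bin = 3L, eta = 0,
                       fc_source = c("simulated_at_Tc", "simulated_at_Tstar",
                                     "empirical"),
                       master_seed = 1L) {
  structure(list(n_grid = as.integer(n_grid), grid = grid, sim = sim,
                 n_runs = as.integer(n_runs),
                 smooth_window = as.integer(smooth_window),
                 mantel_permutations = as.integer(mantel_permutations),
                 normalization = match.arg(normalization),
                 distance_map = match.arg(distance_map),
                 n_bins = as.integer(n_bins),
                 min_pairs_per_bin = as.integer(min_pairs_per_bin),
                 eta = eta, fc_source = match.arg(fc_source),
                 master_seed = master_seed),
            class = "gim_config")
}

#' Fit the generalized Ising model to one subject
#'
#' The package's central fitting routine. Given a structural connectome
#' and one or two BOLD scans it (1) normalizes the connectome into a
#' coupling matrix, (2) sweeps a temperature grid with repeated Metropolis
#' simulations and locates the critical temperature at the run-averaged
#' susceptibility peak, (3) finds, per scan, the temperature whose
#' simulated functional connectivity best matches the empirical FC
#' (Mantel correlation), (4) selects the best-fitting scan and computes
#' the direct SC-FC baseline correlation, and (5) estimates the
#' connectome-distance power-law dimensionality.
#'
#' @param connectome Raw structural connectome (square, symmetric,
#'   non-negative matrix, e.g. streamline counts).
#' @param bold Named list of time-by-region matrices (names `t1`, `t2`) or
#'   a single matrix (taken as `t1`); `NULL` skips the FC-fitting stage.
#' @param config A [gim_config()].
#' @param subject_id Label used in sub-seed derivation and reports.
#' @param group Optional group label carried into cohort tables.
#' @return An object of class `gim_fit`; see [coef.gim_fit()],
#'   [summary.gim_fit()], [plot.gim_fit()], [simulate.gim_fit()].
#' @examples
#' \donttest{
#' counts <- geometric_connectome(n = 30, seed = 7)
#' cfg <- gim_config(n_grid = 12, n_runs = 2,
#'                   sim = sim_params(n_equil_sweeps = 200, n_samples = 200,
#'                                    sample_interval_sweeps = 1))
#' bold <- synth_bold(normalize_coupling(counts), T0 = 2, n_timepoints = 120,
#'                    seed = 11)
#' fit <- gim_fit(counts, bold = list(t1 = bold), config = cfg,
#'                subject_id = "demo")
#' coef(fit)
#' }
#' @export
gim_fit <- function(connectome, bold = NULL, config = gim_config(),
                    subject_id = "subject", group = NA_character_) {
  stopifnot(inherits(config, "gim_config"))
  J <- normalize_coupling(connectome, method = config$normalization)
  grid <- if (!is.null(config$grid)) config$grid
          else default_temperature_grid(J, config$n_grid)

  sweep <- temperature_sweep(J, grid = grid, params = config$sim,
                             n_runs = config$n_runs,
                             master_seed = config$master_seed,
                             subject_id = subject_id, retain = "fc")
  crit <- find_critical_temperature(sweep, smooth_window = config$smooth_window)

  if (!is.null(bold) && is.matrix(bold)) bold <- list(t1 = bold)
  scans <- list()
  empirical_fc <- list()
  if (length(bold)) {
    for (lab in names(bold)) {
      emp <- pearson_correlation_matrix(bold[[lab]], kind = "empirical")
      ts <- find_tstar(empirical = emp, sweep = sweep)
      mant <- mantel_test(sweep$fc_mean[[ts$T_star_index]], emp,
                          n_permutations = config$mantel_permutations,
                          seed = derive_seed(config$master_seed, subject_id,
                                             "mantel", lab))
      ts$p_at_tstar <- mant$p
      ts$r_at_tc <- ts$mantel_curve[crit$Tc_index]
      ts$direct_r <- direct_sc_fc_correlation(J, emp)
      scans[[lab]] <- ts
      empirical_fc[[lab]] <- emp
    }
  }
  best_scan <- if (length(scans)) select_best_scan(scans) else NA_character_

  dim_est <- tryCatch(
    subject_dimensionality(J, fc_source = config$fc_source, sweep = sweep,
                           criticality = crit,
                           tstar = if (length(scans)) scans[[best_scan]],
                           empirical = if (length(empirical_fc))
                             empirical_fc[[if (is.na(best_scan)) 1L else best_scan]],
                           map = config$distance_map, n_bins = config$n_bins,
                           min_pairs_per_bin = config$min_pairs_per_bin,
                           eta = config$eta),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "dimensionality_failure"))

  structure(list(subject_id = subject_id, group = group, J = J,
                 grid = grid, sweep = sweep, criticality = crit,
                 scans = scans, best_scan = best_scan,
                 empirical_fc = empirical_fc,
                 dimensionality = dim_est, config = config),
            class = "gim_fit")
}

#' Run the full analysis for one manifest record
#'
#' Thin wrapper over [gim_fit()] that loads a subject's files first.
#'
#' @param record A record from [read_manifest()].
#' @param config A [gim_config()].
#' @return A `gim_fit`.
#' @export
run_subject <- function(record, config = gim_config()) {
  if (is.null(record$connectome)) record <- load_subject(record)
  gim_fit(record$connectome, bold = record$bold, config = config,
          subject_id = record$subject_id, group = record$group)
}

#' @export
print.gim_fit <- function(x, ...) {
  cat("Generalized Ising model fit -- subject", x$subject_id)
  if (!is.na(x$group)) cat(" (", x$group, ")", sep = "")
  cat("\n  regions:", nrow(x$J),
      " grid: [", format(min(x$grid), digits = 4), ",",
      format(max(x$grid), digits = 4), "] x", length(x$grid),
      " runs:", x$sweep$n_runs, "\n")
  cat("  Tc =", format(x$criticality$Tc, digits = 5), "\n")
  for (lab in names(x$scans)) {
    s <- x$scans[[lab]]
    cat("  ", lab, ": T* = ", format(s$T_star, digits = 5),
        ", best Mantel r = ", format(s$best_r, digits = 4),
        " (p = ", format(s$p_at_tstar, digits = 3),
        "), direct SC-FC r = ", format(s$direct_r, digits = 4), "\n", sep = "")
  }
  if (!is.na(x$best_scan)) cat("  best scan:", x$best_scan, "\n")
  if (inherits(x$dimensionality, "dimensionality_estimate")) {
    cat("  ")
    print(x$dimensionality)
  }
  invisible(x)
}

#' Model parameters of a fitted subject
#'
#' @param object A `gim_fit`.
#' @param ... Unused.
#' @return Named numeric vector: `Tc`, and when scans were fitted
#'   `T_star`, `best_r`, `r_at_Tc`, `direct_r` (all for the best scan),
#'   plus `gamma` and `D` when the dimensionality fit succeeded.
#' @export
coef.gim_fit <- function(object, ...) {
  out <- c(Tc = object$criticality$Tc)
  if (!is.na(object$best_scan)) {
    s <- object$scans[[object$best_scan]]
    out <- c(out, T_star = s$T_star, best_r = s$best_r,
             r_at_Tc = s$r_at_tc, direct_r = s$direct_r)
  }
  if (inherits(object$dimensionality, "dimensionality_estimate"))
    out <- c(out, gamma = object$dimensionality$gamma,
             D = object$dimensionality$D)
  out
}

#' @export
summary.gim_fit <- function(object, ...) {
  structure(list(fit = object, coef = coef(object)), class = "summary.gim_fit")
}

#' @export
print.summary.gim_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameters:\n")
  print(round(x$coef, 5))
  invisible(x)
}

#' Plot a fitted subject
#'
#' Left: run-averaged susceptibility over temperature with the located
#' critical temperature. Right (when scans were fitted): Mantel
#' correlation curves per scan with `T*` marks.
#'
#' @param x A `gim_fit`.
#' @param ... Passed to the susceptibility panel.
#' @export
plot.gim_fit <- function(x, ...) {
  has_scans <- length(x$scans) > 0
  if (has_scans) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  plot(x$sweep, ...)
  if (has_scans) {
    cols <- seq_along(x$scans)
    ylim <- range(unlist(lapply(x$scans, `[[`, "mantel_curve")))
    graphics::plot(NA, xlim = range(x$grid), ylim = ylim,
                   xlab = "temperature T", ylab = "Mantel r")
    for (i in cols) {
      s <- x$scans[[i]]
      graphics::lines(s$temperatures, s$mantel_curve, col = i)
      graphics::abline(v = s$T_star, lty = 3, col = i)
    }
    graphics::legend("topright", legend = names(x$scans), col = cols,
                     lty = 1, bty = "n")
  }
  invisible(x)
}

#' Simulate spin dynamics from a fitted subject
#'
#' Re-runs the Metropolis engine on the fitted coupling matrix, by default
#' at the fitted critical temperature.
#'
#' @param object A `gim_fit`.
#' @param nsim Number of traces (default 1).
#' @param seed Integer seed (default the fit's master seed).
#' @param temperature Simulation temperature (default the fitted Tc).
#' @param ... Unused.
#' @return A `spin_trace` (`nsim = 1`) or list of traces.
#' @export
simulate.gim_fit <- function(object, nsim = 1, seed = NULL,
                             temperature = NULL, ...) {
  if (is.null(seed)) seed <- object$config$master_seed
  if (is.null(temperature)) temperature <- object$criticality$Tc
  traces <- lapply(seq_len(nsim), function(i) {
    p <- object$config$sim
    p$temperature <- temperature
    p$seed <- derive_seed(seed, object$subject_id, "simulate", i)
    simulate_at_temperature(object$J, p)
  })
  if (nsim == 1) traces[[1]] else traces
}

#' Residual structure-function mismatch of a fitted subject
#'
#' Difference between the empirical FC of the best scan and the simulated
#' FC at the best-fit temperature (upper-triangle entries).
#'
#' @param object A `gim_fit` with at least one fitted scan.
#' @param ... Unused.
#' @return Numeric vector of per-pair residuals (empirical minus
#'   simulated).
#' @export
residuals.gim_fit <- function(object, ...) {
  if (!length(object$scans)) stop("no scans were fitted")
  s <- object$scans[[object$best_scan]]
  emp <- object$empirical_fc[[object$best_scan]]
  sim <- object$sweep$fc_mean[[s$T_star_index]]
  upper_tri_vec(emp$r) - upper_tri_vec(sim$r)
}
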