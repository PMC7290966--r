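#' Connectome-defined distance
#'
#' Maps normalized couplings to a pairwise distance in which strongly
#' connected regions are close: `d_ij = 1 / J~_ij` (default) or
#' `d_ij = -log(J~_ij)` on pairs with positive coupling, where `J~` is the
#' matrix rescaled so its maximum is 1 (hence the minimum reciprocal
#' distance is exactly 1). Pairs with zero coupling have no defined
#' distance and are excluded.
#'
#' @param J Coupling matrix (any positive scale; rescaled internally).
#' @param map `"reciprocal"` (default) or `"neglog"`.
#' @return An object of class `connectome_distance`: `d` (N x N, `NA` on
#'   excluded pairs and the diagonal), `n_excluded_pairs` (unordered pairs
#'   with zero coupling), `map`.
#' @export
coupling_to_distance <- function(J, map = c("reciprocal", "neglog")) {
  map <- match.arg(map)
  validate_coupling(J)
  if (max(J) == 0) stop("no positive off-diagonal couplings")
  Jn <- J / max(J)
  d <- matrix(NA_real_, nrow(J), ncol(J), dimnames = dimnames(J))
  pos <- Jn > 0
  d[pos] <- switch(map,
                   reciprocal = 1 / Jn[pos],
                   neglog = -log(Jn[pos]))
  diag(d) <- NA_real_
  n_excl <- sum(!pos[upper.tri(pos)])
  structure(list(d = d, n_excluded_pairs = n_excl, map = map),
            class = "connectome_distance")
}

#' Correlation-decay curve over connectome distance
#'
#' Assigns region pairs to log-spaced distance bins and records each bin's
#' mean functional correlation, geometric bin centre and pair count; bins
#' with fewer than `min_pairs_per_bin` pairs are dropped. With the
#' `"neglog"` distance map (distances starting at 0) bins are spaced
#' linearly instead.
#'
#' @param fc `fc_matrix` or square matrix of correlations.
#' @param dist A `connectome_distance`.
#' @param n_bins Number of bins before filtering (>= 3, default 12).
#' @param min_pairs_per_bin Minimum pairs a bin must hold (default 3).
#' @return Object of class `decay_curve`: `bin_centers`,
#'   `mean_correlation`, `pair_counts`, `n_bins_dropped`, `n_pairs_used`.
#' @export
correlation_decay_curve <- function(fc, dist, n_bins = 12L,
                                    min_pairs_per_bin = 3L) {
  stopifnot(inherits(dist, "connectome_distance"),
            n_bins >= 3, min_pairs_per_bin >= 1)
  r <- as_square_matrix(fc)
  if (!all(dim(r) == dim(dist$d))) stop("FC and distance sizes differ")
  ut <- upper.tri(r)
  d <- dist$d[ut]
  c_ <- r[ut]
  keep <- is.finite(d)
  d <- d[keep]; c_ <- c_[keep]
  if (!length(d)) stop("no connected pairs")

  lo <- min(d); hi <- max(d)
  if (lo == hi) {
    edges <- c(lo - 0.5, hi + 0.5)
  } else if (dist$map == "reciprocal") {
    edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1L))
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  }
  idx <- findInterval(d, edges, rightmost.closed = TRUE, all.inside = TRUE)

  centers <- means <- counts <- numeric(0)
  dropped <- 0L
  for (b in sort(unique(idx))) {
    sel <- idx == b
    if (sum(sel) < min_pairs_per_bin) { dropped <- dropped + 1L; next }
    ctr <- if (dist$map == "reciprocal") exp(mean(log(d[sel]))) else mean(d[sel])
    centers <- c(centers, ctr)
    means <- c(means, mean(c_[sel]))
    counts <- c(counts, sum(sel))
  }
  if (!length(centers)) stop("all distance bins underfilled")
  structure(list(bin_centers = centers, mean_correlation = means,
                 pair_counts = as.integer(counts), n_bins_dropped = dropped,
                 n_pairs_used = sum(counts), map = dist$map),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat("Decay curve:", length(x$bin_centers), "bins,", x$n_pairs_used,
      "pairs (", x$n_bins_dropped, "bin(s) dropped )\n")
  invisible(x)
}

#' Fit the power-law decay exponent and dimensionality
#'
#' Ordinary least squares of `log(mean correlation)` on `log(distance)`
#' over the decay-curve bins with positive mean correlation. The decay
#' exponent is `gamma = -slope`, and the dimensionality is
#' `D = gamma + 2 - eta`; a flat curve (`gamma = 0`) therefore corresponds
#' to `D = 2` under the default `eta = 0`. Bins with non-positive mean
#' correlation cannot enter the log fit and are counted in
#' `n_bins_excluded`.
#'
#' @param curve A `decay_curve`.
#' @param eta Anomalous-exponent offset in the scaling relation (default
#'   0; reported alongside `gamma` so other conventions can be applied
#'   post hoc).
#' @return Object of class `dimensionality_estimate`: `gamma`, `D`, `eta`,
#'   `fit_r2`, `intercept`, `n_bins_used`, `n_bins_excluded`.
#' @export
fit_dimensionality <- function(curve, eta = 0) {
  stopifnot(inherits(curve, "decay_curve"))
  usable <- curve$mean_correlation > 0
  n_used <- sum(usable)
  if (n_used < 3)
    stop("need >= 3 bins with positive mean correlation for the fit (have ",
         n_used, " of ", length(usable), ")")
  x <- log(curve$bin_centers[usable])
  y <- log(curve$mean_correlation[usable])
  if (stats::sd(x) == 0) stop("all usable bins at one distance; cannot fit")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(gamma = -slope, D = -slope + 2 - eta, eta = eta,
                 fit_r2 = r2, intercept = unname(stats::coef(fit)[1]),
                 n_bins_used = n_used,
                 n_bins_excluded = sum(!usable)),
            class = "dimensionality_estimate")
}

#' @export
print.dimensionality_estimate <- function(x, ...) {
  cat("Dimensionality D =", format(x$D, digits = 4),
      "( gamma =", format(x$gamma, digits = 4),
      ", eta =", format(x$eta, digits = 3),
      ", R^2 =", format(x$fit_r2, digits = 3),
      ",", x$n_bins_used, "bins )\n")
  invisible(x)
}

#' Subject-level dimensionality
#'
#' Composes [coupling_to_distance()], [correlation_decay_curve()] and
#' [fit_dimensionality()] for one subject, using the requested FC source:
#' the run-averaged simulated FC at the critical temperature (default), at
#' the best-fit temperature, or the empirical FC.
#'
#' @param J Coupling matrix.
#' @param fc_source `"simulated_at_Tc"`, `"simulated_at_Tstar"` or
#'   `"empirical"`.
#' @param sweep A `susceptibility_curve` with retained FCs (required for
#'   the simulated sources).
#' @param criticality A `criticality_result` (required for
#'   `simulated_at_Tc`).
#' @param tstar A `tstar_result` (required for `simulated_at_Tstar`).
#' @param empirical Empirical `fc_matrix` (required for `empirical`).
#' @param map,n_bins,min_pairs_per_bin,eta Passed to the composed stages.
#' @return A `dimensionality_estimate` with attribute `fc_source`.
#' @export
subject_dimensionality <- function(J,
                                   fc_source = c("simulated_at_Tc",
                                                 "simulated_at_Tstar",
                                                 "empirical"),
                                   sweep = NULL, criticality = NULL,
                                   tstar = NULL, empirical = NULL,
                                   map = "reciprocal", n_bins = 12L,
                                   min_pairs_per_bin = 3L, eta = 0) {
  fc_source <- match.arg(fc_source)
  fc <- switch(fc_source,
    simulated_at_Tc = {
      if (is.null(sweep) || is.null(sweep$fc_mean) || is.null(criticality))
        stop("simulated_at_Tc needs a sweep with retained FCs and a criticality result")
      sweep$fc_mean[[criticality$Tc_index]]
    },
    simulated_at_Tstar = {
      if (is.null(sweep) || is.null(sweep$fc_mean) || is.null(tstar))
        stop("simulated_at_Tstar needs a sweep with retained FCs and a tstar result")
      sweep$fc_mean[[tstar$T_star_index]]
    },
    empirical = {
      if (is.null(empirical)) stop("empirical source needs the empirical FC")
      empirical
    })
  dist <- coupling_to_distance(J, map = map)
  curve <- correlation_decay_curve(fc, dist, n_bins = n_bins,
                                   min_pairs_per_bin = min_pairs_per_bin)
  est <- fit_dimensionality(curve, eta = eta)
  attr(est, "fc_source") <- fc_source
  est
}
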