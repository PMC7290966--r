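#' Pearson correlation matrix of a multivariate time series
#'
#' Pairwise Pearson correlation across time for every region pair. Regions
#' with zero variance (e.g. frozen spins at low temperature) are flagged in
#' `degenerate` and their off-diagonal correlations set to 0 rather than
#' propagated as NaN; the diagonal is always 1.
#'
#' @param series Numeric time-by-regions matrix with at least 3 rows.
#' @param kind `"empirical"` or `"simulated"` provenance tag.
#' @return An object of class `fc_matrix`: list with `r` (N x N), `kind`,
#'   `degenerate` (integer indices of zero-variance regions).
#' @export
pearson_correlation_matrix <- function(series,
                                       kind = c("empirical", "simulated")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(series), is.numeric(series))
  if (nrow(series) < 3) stop("need at least 3 time points")
  if (any(!is.finite(series))) stop("series has non-finite values")
  sds <- apply(series, 2L, stats::sd)
  degenerate <- which(sds == 0)
  r <- suppressWarnings(stats::cor(series))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  fc_matrix(r, kind = kind, degenerate = degenerate)
}

fc_matrix <- function(r, kind, degenerate = integer(0)) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  structure(list(r = r, kind = kind, degenerate = as.integer(degenerate)),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  ut <- upper_tri_vec(x$r)
  cat("FC matrix (", x$kind, "): ", nrow(x$r), " regions, mean off-diag r = ",
      format(mean(ut), digits = 4), sep = "")
  if (length(x$degenerate))
    cat(", ", length(x$degenerate), " degenerate region(s)", sep = "")
  cat("\n")
  invisible(x)
}

upper_tri_vec <- function(m) m[upper.tri(m)]

#' Average functional connectivity over runs
#'
#' Entrywise mean of a list of FC matrices from repeated simulations; the
#' diagonal is reset to 1 and degenerate flags are unioned.
#'
#' @param fcs Non-empty list of `fc_matrix` objects of equal size and kind.
#' @return An `fc_matrix`.
#' @export
average_fc_over_runs <- function(fcs) {
  if (!length(fcs)) stop("empty FC list")
  stopifnot(all(vapply(fcs, inherits, logical(1), "fc_matrix")))
  n <- nrow(fcs[[1]]$r)
  kind <- fcs[[1]]$kind
  for (f in fcs) {
    if (nrow(f$r) != n) stop("FC matrices differ in size")
    if (!identical(f$kind, kind)) stop("FC matrices differ in kind")
  }
  r <- Reduce(`+`, lapply(fcs, `[[`, "r")) / length(fcs)
  diag(r) <- 1
  fc_matrix(r, kind = kind,
            degenerate = sort(unique(unlist(lapply(fcs, `[[`, "degenerate")))))
}

as_square_matrix <- function(x) {
  if (inherits(x, "fc_matrix")) x$r
  else if (is.matrix(x) && nrow(x) == ncol(x)) x
  else stop("expected a square matrix or fc_matrix")
}

#' Mantel test between two square matrices
#'
#' Observed statistic: Pearson correlation of the strictly-upper-triangle
#' vectors. Null distribution: the same random node relabelling applied to
#' the rows and columns of `B`; one-tailed (greater) p-value
#' `(#{r_perm >= r_obs} + 1) / (n_permutations + 1)`.
#'
#' @param A,B Square matrices (or `fc_matrix` objects) of equal size
#'   `N >= 4`.
#' @param n_permutations Number of sampled node permutations (default
#'   10000).
#' @param seed Optional integer seed for the permutation draws.
#' @return List of class `mantel_result`: `r`, `p`, `n_permutations`,
#'   `degenerate` (`TRUE` when either upper triangle is constant, in which
#'   case `r = 0`, `p = 1`).
#' @export
mantel_test <- function(A, B, n_permutations = 10000L, seed = NULL) {
  A <- as_square_matrix(A); B <- as_square_matrix(B)
  n <- nrow(A)
  if (nrow(B) != n) stop("matrices differ in size")
  if (n < 4) stop("Mantel test needs N >= 4")
  stopifnot(n_permutations >= 1)
  a <- upper_tri_vec(A)
  if (stats::sd(a) == 0 || stats::sd(upper_tri_vec(B)) == 0) {
    return(structure(list(r = 0, p = 1,
                          n_permutations = as.integer(n_permutations),
                          degenerate = TRUE), class = "mantel_result"))
  }
  r_obs <- mantel_r(A, B)
  ut <- which(upper.tri(B))
  run <- function() {
    count <- 0L
    for (i in seq_len(n_permutations)) {
      p <- sample.int(n)
      rp <- stats::cor(a, B[p, p][ut])
      if (rp >= r_obs - 1e-12) count <- count + 1L
    }
    count
  }
  count <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(r = r_obs, p = (count + 1) / (n_permutations + 1),
                 n_permutations = as.integer(n_permutations),
                 degenerate = FALSE),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel r =", format(x$r, digits = 4), " p =", format(x$p, digits = 4),
      " (", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Mantel correlation statistic (no permutations)
#'
#' Pearson correlation of the strictly-upper-triangle vectors of two square
#' matrices; 0 when either triangle is constant.
#'
#' @param A,B Square matrices or `fc_matrix` objects.
#' @return Scalar in `[-1, 1]`.
#' @export
mantel_r <- function(A, B) {
  a <- upper_tri_vec(as_square_matrix(A))
  b <- upper_tri_vec(as_square_matrix(B))
  if (length(a) != length(b)) stop("matrices differ in size")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Find the best-fit temperature T*
#'
#' For each grid temperature, the simulated FC (averaged over `n_runs`
#' repeats) is compared with the empirical FC by the Mantel correlation;
#' `T*` is the grid temperature maximizing that curve (ties toward the
#' lowest temperature). A precomputed [temperature_sweep()] with retained
#' FCs can be passed to reuse its simulations.
#'
#' @param J Coupling matrix (ignored when `sweep` is given).
#' @param empirical Empirical `fc_matrix` (or square matrix).
#' @param grid Temperature grid (ignored when `sweep` is given).
#' @param params Template [sim_params()].
#' @param n_runs Repeats per temperature.
#' @param master_seed,subject_id Sub-seed context (must differ from the
#'   susceptibility sweep's unless the sweep itself is reused).
#' @param sweep Optional `susceptibility_curve` with retained FCs.
#' @return List of class `tstar_result`: `T_star`, `best_r`,
#'   `mantel_curve`, `temperatures`, `T_star_index`.
#' @export
find_tstar <- function(J = NULL, empirical, grid = NULL,
                       params = sim_params(), n_runs = 10L,
                       master_seed = 1L, subject_id = "subject",
                       sweep = NULL) {
  if (is.null(sweep)) {
    if (is.null(J) || is.null(grid)) stop("need J and grid, or a sweep")
    sweep <- temperature_sweep(J, grid = grid, params = params,
                               n_runs = n_runs, master_seed = master_seed,
                               subject_id = subject_id, retain = "fc")
  }
  if (is.null(sweep$fc_mean)) stop("sweep was run with retain = 'none'")
  emp <- as_square_matrix(empirical)
  curve <- vapply(sweep$fc_mean, function(fc) mantel_r(fc, emp), numeric(1))
  i <- which.max(curve)
  structure(list(T_star = sweep$temperatures[i], T_star_index = i,
                 best_r = curve[i], mantel_curve = curve,
                 temperatures = sweep$temperatures),
            class = "tstar_result")
}

#' @export
print.tstar_result <- function(x, ...) {
  cat("T* =", format(x$T_star, digits = 5),
      " (Mantel r =", format(x$best_r, digits = 4), ")\n")
  invisible(x)
}

#' Direct structure-function correlation baseline
#'
#' Pearson correlation between the strictly-upper-triangle entries of the
#' coupling matrix and an FC matrix — the no-model baseline against which
#' the spin model's best fit is compared.
#'
#' @param J Coupling matrix.
#' @param fc `fc_matrix` or square matrix.
#' @return Scalar correlation (0 if either triangle is constant).
#' @export
direct_sc_fc_correlation <- function(J, fc) {
  validate_coupling(J)
  mantel_r(J, fc)
}

#' Select the best scan by Mantel fit
#'
#' Given per-scan `tstar_result`s, returns the label of the scan with the
#' highest best-fit correlation; ties break toward `"t1"` (more generally,
#' toward the earliest label in list order).
#'
#' @param per_scan Named non-empty list of `tstar_result` objects.
#' @return Scan label (character).
#' @export
select_best_scan <- function(per_scan) {
  if (!length(per_scan)) stop("no scans supplied")
  stopifnot(!is.null(names(per_scan)))
  ord <- if ("t1" %in% names(per_scan))
    c("t1", setdiff(names(per_scan), "t1")) else names(per_scan)
  rs <- vapply(per_scan[ord], `[[`, numeric(1), "best_r")
  ord[which.max(rs)]
}
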