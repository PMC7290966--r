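#' Validate a coupling matrix
#'
#' Checks the invariants every coupling matrix must satisfy: square,
#' symmetric, non-negative, zero diagonal, at least two regions.
#'
#' @param J Numeric matrix.
#' @param tol Symmetry tolerance.
#' @return `J`, invisibly, or an error.
#' @keywords internal
validate_coupling <- function(J, tol = 1e-8) {
  stopifnot(is.matrix(J), is.numeric(J))
  if (nrow(J) != ncol(J)) stop("coupling matrix must be square")
  if (nrow(J) < 2) stop("coupling matrix needs at least 2 regions")
  if (any(!is.finite(J))) stop("coupling matrix has non-finite entries")
  if (min(J) < 0) stop("coupling matrix has negative entries")
  if (max(abs(J - t(J))) > tol) stop("coupling matrix is not symmetric")
  if (any(diag(J) != 0)) stop("coupling matrix diagonal must be zero")
  invisible(J)
}

#' Normalize a streamline-count matrix into a coupling matrix
#'
#' Turns a raw structural connectome (e.g. tractography streamline counts)
#' into the coupling matrix used by the spin model: the diagonal is zeroed,
#' small asymmetries are averaged away, and the matrix is divided by its
#' maximum entry so the strongest connection has coupling 1. Scaling by the
#' maximum puts all subjects on a comparable temperature axis. Setting
#' `method = "mean"` instead fixes the mean off-diagonal coupling to 1
#' (total coupling mass held constant); this alternative is provided for
#' sensitivity analyses of how normalization interacts with sparsity.
#'
#' @param raw_counts Square, symmetric (within `tol`), non-negative matrix.
#' @param method `"max"` (default, maximum entry becomes 1) or `"mean"`
#'   (mean off-diagonal entry becomes 1).
#' @param tol Symmetry tolerance; asymmetry within it is averaged.
#' @return A normalized coupling matrix (attribute `normalization` records
#'   the method).
#' @examples
#' normalize_coupling(matrix(c(0, 4, 4, 0), 2))
#' @export
normalize_coupling <- function(raw_counts, method = c("max", "mean"),
                               tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(is.matrix(raw_counts), is.numeric(raw_counts))
  if (nrow(raw_counts) != ncol(raw_counts)) stop("connectome must be square")
  if (any(!is.finite(raw_counts))) stop("connectome has non-finite entries")
  if (min(raw_counts) < 0) stop("connectome has negative entries")
  scale_ref <- max(abs(raw_counts))
  if (scale_ref > 0 &&
      max(abs(raw_counts - t(raw_counts))) > tol * scale_ref)
    stop("connectome asymmetry exceeds tolerance")
  J <- (raw_counts + t(raw_counts)) / 2
  diag(J) <- 0
  if (max(J) == 0) stop("connectome has no positive off-diagonal entries")
  J <- switch(method,
              max = J / max(J),
              mean = J / (sum(J) / (nrow(J) * (nrow(J) - 1))))
  attr(J, "normalization") <- method
  validate_coupling(J)
  J
}

#' Mean-field critical temperature anchor
#'
#' Mean over regions of the doubled coupling row sum, the mean-field
#' estimate of the ordering temperature under the double-sum energy
#' convention. Used to anchor the default temperature grid.
#'
#' @param J Coupling matrix.
#' @return Positive scalar.
#' @export
mean_field_tc <- function(J) {
  validate_coupling(J)
  if (max(J) == 0) stop("all-zero coupling matrix")
  mean(2 * rowSums(J))
}
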