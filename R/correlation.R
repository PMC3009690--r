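# Cross-correlation and graph-delayed correlation estimators.

#' Center the rows of a data matrix
#'
#' @param X numeric matrix (observations x features).
#' @return list with `x` (the centered matrix) and `means` (the removed row
#'   means, one per observation).
#' @export
center_rows <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("data matrix contains non-finite entries")
  mu <- rowMeans(X)
  list(x = X - mu, means = mu)
}

# Row means must vanish relative to row scale before correlation estimates
# are meaningful; constant rows are centered exactly so tolerate absolute 0.
.check_centered <- function(X, tol = 1e-8) {
  mu <- abs(rowMeans(X))
  s <- apply(X, 1L, stats::sd)
  ok <- mu <= tol * pmax(s, .Machine$double.eps)
  all(ok)
}

.require_centered <- function(X, auto_center) {
  if (.check_centered(X)) return(X)
  if (auto_center) return(center_rows(X)$x)
  stop("rows of X are not centered (pass auto_center = TRUE to center)")
}

#' Cross-correlation matrix of centered data
#'
#' The unbiased second-moment estimator `X %*% t(X) / (l - 1)` over the
#' l feature columns. Rows of `X` must be centered.
#'
#' @param X centered numeric matrix, m observations x l features, l >= 2.
#' @param auto_center center rows silently instead of erroring when row
#'   means are nonzero.
#' @return symmetric positive semidefinite m x m matrix.
#' @export
cross_correlation <- function(X, auto_center = FALSE) {
  X <- as.matrix(X)
  l <- ncol(X)
  if (l < 2L) stop("need at least 2 feature columns to estimate correlation")
  X <- .require_centered(X, auto_center)
  tcrossprod(X) / (l - 1)
}

#' Graph-delayed correlation
#'
#' Correlation between the data and its G-shifted copy:
#' `(X %*% W^tau %*% t(X)) / (l - 1)` for `tau >= 0`, with the transposed
#' propagator for negative shifts. At `tau = 0` this reduces to
#' [cross_correlation()]. Off-diagonal entries measure network-lagged
#' co-variation between observations; the matrix is generally asymmetric
#' because regulatory graphs are directed.
#'
#' @inheritParams cross_correlation
#' @param W weight matrix (l x l).
#' @param tau integer shift.
#' @return a `delayed_correlation`: the m x m matrix with attributes `tau`
#'   and `symmetrized = FALSE`.
#' @export
graph_delayed_correlation <- function(X, W, tau, auto_center = FALSE) {
  X <- as.matrix(X)
  l <- ncol(X)
  if (l < 2L) stop("need at least 2 feature columns to estimate correlation")
  X <- .require_centered(X, auto_center)
  C <- tcrossprod(g_shift(X, W, tau), X) / (l - 1)
  structure(C, tau = as.integer(tau), symmetrized = FALSE,
            class = c("delayed_correlation", "matrix", "array"))
}

#' Symmetrize a delayed correlation matrix
#'
#' Returns `(C + t(C)) / 2`. The symmetrized graph-delayed correlation has a
#' well-defined eigendecomposition, which is what the factorization
#' diagonalizes; symmetrization also stabilizes the estimate.
#'
#' @param C square numeric matrix (typically a `delayed_correlation`).
#' @return symmetric matrix with attribute `symmetrized = TRUE`; `tau` is
#'   carried over when present.
#' @export
symmetrize <- function(C) {
  if (nrow(C) != ncol(C)) stop("cannot symmetrize a non-square matrix")
  S <- (unclass(C) + t(unclass(C))) / 2
  structure(as.matrix(S), tau = attr(C, "tau"), symmetrized = TRUE,
            class = c("delayed_correlation", "matrix", "array"))
}
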