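# Core factorization: whitening and diagonalization of the symmetrized
# graph-delayed correlation.

#' Whiten centered data
#'
#' Eigendecomposes the zero-shift correlation `C(0) = cross_correlation(X)`
#' and rescales the leading eigendirections to unit variance:
#' `Z = D_r^{-1/2} E_r^T X`. When fewer components than observations are
#' retained, the discarded eigenvalues estimate the variance of additive
#' white noise; that estimate is subtracted from the retained eigenvalues
#' before inversion, whitening the noise-free part of the data. With no
#' dimension reduction the noise variance is taken as 0.
#'
#' @param X centered numeric matrix, m x l.
#' @param n_components number of components to retain; `NULL` (default)
#'   retains all eigenvalues above the rank tolerance.
#' @param sigma2 noise variance; `NULL` (default) estimates it as the mean
#'   of the discarded eigenvalues when `n_components < m`, else 0.
#' @param rank_tol eigenvalues below `rank_tol * max(eigenvalue)` are
#'   treated as null space and refused for whitening.
#' @return object of class `whitening_result`: list with `z` (n x l whitened
#'   data), `whitening` (n x m), `dewhitening` (m x n), `eigenvalues`
#'   (all m eigenvalues of C(0)), `retained` (indices kept), `sigma2`.
#' @export
whiten <- function(X, n_components = NULL, sigma2 = NULL, rank_tol = 1e-10) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (!.check_centered(X)) stop("whiten() expects row-centered data")
  C0 <- symmetrize(cross_correlation(X))
  eg <- eigen(unclass(C0), symmetric = TRUE)
  d <- eg$values
  E <- eg$vectors
  d_max <- max(abs(d))
  if (d_max <= 0) stop("zero covariance: no component can be whitened")
  rank_ok <- which(d > rank_tol * d_max)
  n <- if (is.null(n_components)) length(rank_ok) else as.integer(n_components)
  if (n < 1L || n > m) stop(sprintf("n_components must be in 1..%d", m))
  if (n > length(rank_ok)) {
    stop(sprintf(
      "component %d is rank deficient: eigenvalue %.3e below tolerance %.3e",
      length(rank_ok) + 1L, d[length(rank_ok) + 1L], rank_tol * d_max))
  }
  if (is.null(sigma2)) {
    sigma2 <- if (n < m) max(0, mean(d[(n + 1L):m])) else 0
  }
  d_r <- d[seq_len(n)] - sigma2
  bad <- which(d_r <= rank_tol * d_max)
  if (length(bad) > 0L) {
    stop(sprintf(
      "component %d has retained eigenvalue %.3e <= noise floor sigma2 = %.3e",
      bad[1L], d[bad[1L]], sigma2))
  }
  E_r <- E[, seq_len(n), drop = FALSE]
  Kw <- diag(1 / sqrt(d_r), n) %*% t(E_r)   # whitening, n x m
  Dw <- E_r %*% diag(sqrt(d_r), n)          # dewhitening, m x n
  structure(list(z = Kw %*% X, whitening = Kw, dewhitening = Dw,
                 eigenvalues = d, retained = seq_len(n), sigma2 = sigma2),
            class = "whitening_result")
}

#' Graph-decorrelation factorization of an expression matrix
#'
#' Decomposes an observations-by-genes matrix X into `X = A %*% S` (plus
#' residual), where the source rows of S are zero-mean, unit-variance
#' patterns over genes whose symmetrized graph-delayed cross-correlations
#' vanish: after whitening, the sources are the eigenvectors of the single
#' symmetric matrix `symmetrize(graph_delayed_correlation(Z, W, tau))`, and
#' the mixing matrix A holds each source's activity per observation.
#' The graph supplies the ordering that time supplies in classic
#' second-order source separation; `tau = 0` carries no separation
#' information and is rejected.
#'
#' Sources are defined up to permutation and sign only; see
#' [order_and_sign()] for the conventions applied. Identifiability requires
#' pairwise distinct eigenvalues of the delayed correlation: near-ties are
#' recorded as a warning in the result.
#'
#' @param X numeric matrix, m observations x l genes (column names are kept
#'   as the gene index). Rows are centered internally.
#' @param W weight matrix (l x l) aligned with the columns of `X`.
#' @param tau nonzero integer shift (default 1, the minimal informative
#'   shift).
#' @param n_sources number of sources; `NULL` retains every component above
#'   the whitening rank tolerance (at most m).
#' @param sigma2 noise variance passed to [whiten()].
#' @param tie_tol relative eigenvalue gap below which a tie warning is
#'   recorded.
#' @return object of class `grade_result`: list with `A` (m x n mixing
#'   matrix), `S` (n x l sources), `eigenvalues` (signed, one per source,
#'   ordered by decreasing magnitude), `tau`, `whitening`
#'   (a `whitening_result`), `genes`, `row_means`, `ties` (logical).
#' @export
grade <- function(X, W, tau = 1L, n_sources = NULL, sigma2 = NULL,
                  tie_tol = 1e-6) {
  X <- as.matrix(X)
  if (tau == 0) {
    stop("tau = 0 carries no separation information; use a nonzero shift")
  }
  if (ncol(X) != nrow(W)) {
    stop(sprintf("X has %d gene columns but W is %d x %d",
                 ncol(X), nrow(W), ncol(W)))
  }
  if (ncol(X) <= nrow(X)) {
    warning("fewer genes than observations; correlation estimates are weak")
  }
  genes <- colnames(X)
  cc <- center_rows(X)
  wh <- whiten(cc$x, n_components = n_sources, sigma2 = sigma2)
  Ct <- symmetrize(graph_delayed_correlation(wh$z, W, tau))
  eg <- eigen(unclass(Ct), symmetric = TRUE)
  lam <- eg$values
  V <- eg$vectors
  gaps <- abs(diff(sort(lam)))
  scale <- max(abs(lam), .Machine$double.eps)
  ties <- any(gaps < tie_tol * scale)
  if (ties) {
    warning("near-equal eigenvalues of the delayed correlation: ",
            "sources are not uniquely identifiable")
  }
  S <- t(V) %*% wh$z
  A <- wh$dewhitening %*% V
  colnames(S) <- genes
  res <- structure(list(A = A, S = S, eigenvalues = lam, tau = as.integer(tau),
                        whitening = wh, genes = genes, row_means = cc$means,
                        ties = ties),
                   class = "grade_result")
  order_and_sign(res)
}

#' Apply ordering and sign conventions to a factorization
#'
#' Sources are sorted by decreasing eigenvalue magnitude (eigenvalues of the
#' symmetrized delayed correlation may be negative) and each source's sign
#' is flipped so that the largest-magnitude entry of its mixing column is
#' positive. `A %*% S` is unchanged.
#'
#' @param result a `grade_result`.
#' @return the result with conventions applied (idempotent).
#' @export
order_and_sign <- function(result) {
  stopifnot(inherits(result, "grade_result"))
  ord <- order(abs(result$eigenvalues), decreasing = TRUE)
  A <- result$A[, ord, drop = FALSE]
  S <- result$S[ord, , drop = FALSE]
  lam <- result$eigenvalues[ord]
  for (k in seq_len(ncol(A))) {
    peak <- which.max(abs(A[, k]))
    if (A[peak, k] < 0) {
      A[, k] <- -A[, k]
      S[k, ] <- -S[k, ]
    }
  }
  result$A <- A
  result$S <- S
  result$eigenvalues <- lam
  result
}

#' @export
print.grade_result <- function(x, ...) {
  cat(sprintf("grade_result: %d observations, %d genes, %d sources (tau = %d)\n",
              nrow(x$A), ncol(x$S), nrow(x$S), x$tau))
  cat("eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  cat(sprintf("noise variance sigma2 = %g\n", x$whitening$sigma2))
  if (isTRUE(x$ties)) cat("warning: near-tied eigenvalues recorded\n")
  invisible(x)
}

#' Reconstruction A %*% S of a factorization
#' @param result a `grade_result`.
#' @return m x l matrix approximating the centered input.
#' @export
reconstruct <- function(result) {
  result$A %*% result$S
}

#' Average replicate observations into condition means
#'
#' @param X matrix, samples x genes.
#' @param design factor or character vector, one condition label per row of
#'   `X`; conditions keep their order of first appearance.
#' @return matrix, conditions x genes.
#' @export
average_replicates <- function(X, design) {
  X <- as.matrix(X)
  stopifnot(length(design) == nrow(X))
  design <- factor(design, levels = unique(as.character(design)))
  out <- t(vapply(levels(design), function(lv) {
    colMeans(X[design == lv, , drop = FALSE])
  }, numeric(ncol(X))))
  colnames(out) <- colnames(X)
  out
}
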