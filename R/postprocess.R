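# Source post-processing: submodes, gene-set over-representation, the
# pathway enrichment index, and PCA / k-means baselines.

#' Extract signed submodes from a source matrix
#'
#' Each unit-variance source is split into a positive submode (genes with
#' source value >= threshold) and a negative submode (genes with value
#' <= -threshold); the threshold is in standard-deviation units.
#'
#' @param S source matrix, sources x genes (column names used as gene ids).
#' @param threshold cutoff in SD units (default 2).
#' @return list of `submode` objects, two per source (positive first), each
#'   with fields `source`, `sign`, `genes`, `threshold`.
#' @export
extract_submodes <- function(S, threshold = 2) {
  S <- as.matrix(S)
  genes <- colnames(S) %||% paste0("g", seq_len(ncol(S)))
  v <- apply(S, 1L, function(r) sum(r^2) / (length(r) - 1))
  if (any(abs(v - 1) > 0.01)) {
    warning("source rows are not unit variance; ",
            "the threshold loses its SD-unit meaning")
  }
  out <- list()
  for (k in seq_len(nrow(S))) {
    out[[length(out) + 1L]] <- structure(
      list(source = k, sign = "positive",
           genes = genes[S[k, ] >= threshold], threshold = threshold),
      class = "submode")
    out[[length(out) + 1L]] <- structure(
      list(source = k, sign = "negative",
           genes = genes[S[k, ] <= -threshold], threshold = threshold),
      class = "submode")
  }
  out
}

#' @export
print.submode <- function(x, ...) {
  cat(sprintf("submode: source %d, %s, %d genes (|threshold| = %g)\n",
              x$source, x$sign, length(x$genes), x$threshold))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, capped at 1 and mapped
#' back to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) > 0L && (any(!is.finite(p)) || any(p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation test
#'
#' For each annotation set, tests whether the query gene list overlaps the
#' set more than expected when drawing |query| genes from the universe
#' without replacement: p = P(overlap >= observed) under the
#' hypergeometric distribution. P-values are BH-adjusted across sets.
#'
#' @param query character vector of genes of interest (subset of universe).
#' @param universe character vector of all assayed genes.
#' @param annotation named list: set name -> character vector of genes.
#' @param min_set_size sets with fewer genes in the universe are not tested
#'   (default 2).
#' @return data.frame with columns `set`, `overlap`, `set_size`,
#'   `query_size`, `p`, `p_adjusted`, sorted by `p_adjusted`.
#' @export
hypergeometric_enrichment <- function(query, universe, annotation,
                                      min_set_size = 2L) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (length(universe) == 0L) stop("empty gene universe")
  if (length(query) == 0L) stop("empty query gene set")
  if (!all(query %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5L), collapse = ", "))
  }
  if (length(annotation) == 0L) {
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      p = numeric(), p_adjusted = numeric()))
  }
  N <- length(universe)
  n <- length(query)
  sets <- lapply(annotation, function(g) intersect(unique(g), universe))
  keep <- vapply(sets, length, 1L) >= min_set_size
  sets <- sets[keep]
  K <- vapply(sets, length, 1L)
  k <- vapply(sets, function(g) length(intersect(g, query)), 1L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set = names(sets), overlap = k, set_size = K,
                    query_size = n, p = p, p_adjusted = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_adjusted, out$p, out$set), , drop = FALSE]
}

#' Pathway enrichment index
#'
#' Runs the hypergeometric test for every submode gene list (BH-adjusted
#' within each submode's table), marks a pathway significant if its
#' adjusted p falls below `alpha` in at least one submode, and reports the
#' fraction of pathways so captured. The denominator is the number of
#' annotation sets with at least one gene in the universe.
#'
#' @param submodes list of gene-id character vectors (or `submode`
#'   objects).
#' @param universe all assayed genes.
#' @param annotation named list of gene sets.
#' @param alpha significance level (default 0.05).
#' @param min_set_size minimum in-universe set size to test (default 2).
#' @return object of class `pei_result`: list with `pei`, `significant`
#'   (character vector, union over submodes), `n_tested` (denominator),
#'   `per_submode` (list of significant sets per submode).
#' @export
pathway_enrichment_index <- function(submodes, universe, annotation,
                                     alpha = 0.05, min_set_size = 2L) {
  universe <- unique(as.character(universe))
  in_universe <- vapply(annotation, function(g) {
    length(intersect(unique(g), universe)) > 0L
  }, logical(1))
  if (!any(in_universe)) {
    stop("no annotation set intersects the universe: PEI undefined")
  }
  gene_lists <- lapply(submodes, function(s) {
    if (inherits(s, "submode")) s$genes else as.character(s)
  })
  per_submode <- lapply(gene_lists, function(g) {
    g <- intersect(g, universe)
    if (length(g) == 0L) return(character())
    tab <- hypergeometric_enrichment(g, universe, annotation, min_set_size)
    tab$set[tab$p_adjusted < alpha]
  })
  sig <- unique(unlist(per_submode))
  structure(list(pei = length(sig) / sum(in_universe), significant = sig,
                 n_tested = sum(in_universe), per_submode = per_submode),
            class = "pei_result")
}

#' @export
print.pei_result <- function(x, ...) {
  cat(sprintf("PEI = %.3f (%d of %d pathways enriched in >= 1 submode)\n",
              x$pei, length(x$significant), x$n_tested))
  invisible(x)
}

#' PCA baseline factorization
#'
#' Eigendecomposition of the zero-shift covariance of row-centered data,
#' shaped like the graph-decorrelation result: unit-variance component
#' rows, mixing matrix columns ordered by explained variance, signs fixed
#' as in [order_and_sign()]. Submodes are thresholded at +/- `threshold`
#' standard deviations.
#'
#' @param X matrix, observations x genes.
#' @param n_components number of components (default: all above rank
#'   tolerance).
#' @param threshold submode cutoff in SD units.
#' @return list with `A`, `S`, `eigenvalues`, `explained_variance`
#'   (fractions over all positive eigenvalues), `submodes`.
#' @export
pca_baseline <- function(X, n_components = NULL, threshold = 2) {
  X <- as.matrix(X)
  cc <- center_rows(X)
  wh <- whiten(cc$x, n_components = n_components, sigma2 = 0)
  n <- length(wh$retained)
  S <- wh$z                      # unit-variance principal directions
  A <- wh$dewhitening
  colnames(S) <- colnames(X)
  res <- structure(list(A = A, S = S,
                        eigenvalues = wh$eigenvalues[seq_len(n)],
                        tau = NA_integer_, whitening = wh,
                        genes = colnames(X), row_means = cc$means,
                        ties = FALSE),
                   class = "grade_result")
  for (k in seq_len(n)) {
    peak <- which.max(abs(res$A[, k]))
    if (res$A[peak, k] < 0) {
      res$A[, k] <- -res$A[, k]
      res$S[k, ] <- -res$S[k, ]
    }
  }
  ev <- wh$eigenvalues[wh$eigenvalues > 0]
  list(A = res$A, S = res$S, eigenvalues = res$eigenvalues,
       explained_variance = res$eigenvalues / sum(ev),
       submodes = extract_submodes(res$S, threshold))
}

#' k-means clustering baseline
#'
#' Ranks genes by expression variance across samples, keeps the top
#' fraction, and clusters them with k-means (multiple restarts, fixed
#' seed).
#'
#' @param X matrix, genes x samples.
#' @param k number of clusters (default 8).
#' @param top_frac fraction of most-variable genes to keep (default 0.15).
#' @param seed integer seed.
#' @param nstart k-means restarts (default 25).
#' @return list with `cluster` (named integer vector), `centers`
#'   (k x samples), `genes` (those kept).
#' @export
kmeans_baseline <- function(X, k = 8L, top_frac = 0.15, seed = 1L,
                            nstart = 25L) {
  X <- as.matrix(X)
  v <- apply(X, 1L, stats::var)
  n_keep <- max(k, ceiling(top_frac * nrow(X)))
  if (n_keep > nrow(X)) n_keep <- nrow(X)
  keep <- order(v, decreasing = TRUE)[seq_len(n_keep)]
  Xk <- X[sort(keep), , drop = FALSE]
  if (k > nrow(Xk)) {
    stop(sprintf("k = %d exceeds the %d genes kept by the variance filter",
                 k, nrow(Xk)))
  }
  withr::local_seed(as.integer(seed))
  km <- stats::kmeans(Xk, centers = k, nstart = nstart, iter.max = 100L)
  list(cluster = stats::setNames(km$cluster, rownames(Xk)),
       centers = km$centers, genes = rownames(Xk))
}
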