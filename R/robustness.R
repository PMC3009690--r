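# Robustness protocol: network perturbations, replicate subsampling,
# Amari-index scoring and empirical p-values.

.amari_from_P <- function(P, normalized = FALSE) {
  P <- abs(as.matrix(P))
  if (any(apply(P, 1L, max) == 0) || any(apply(P, 2L, max) == 0)) {
    stop("degenerate cross-talk matrix: zero row or column")
  }
  rows <- sum(rowSums(P) / apply(P, 1L, max) - 1)
  cols <- sum(colSums(P) / apply(P, 2L, max) - 1)
  idx <- rows + cols
  if (normalized) {
    n <- nrow(P)
    idx <- idx / (2 * n * (n - 1))
  }
  idx
}

#' Amari index between two mixing matrices
#'
#' Permutation- and scaling-invariant distance: with
#' `P = pinv(A_hat) %*% A_ref`, sums the row-wise and column-wise excess
#' `sum(|P|) / max(|P|) - 1`. The index is 0 exactly when `A_hat` equals
#' `A_ref` up to column permutation and nonzero scaling, and grows as the
#' cross-talk between mismatched sources grows. The default is the
#' unnormalized form (maximum `2n(n-1)` for n sources); `normalized = TRUE`
#' rescales to \[0, 1\].
#'
#' @param A_hat,A_ref mixing matrices of identical shape; `A_ref` must have
#'   full column rank.
#' @param normalized divide by `2n(n-1)`.
#' @return nonnegative scalar.
#' @export
amari_index <- function(A_hat, A_ref, normalized = FALSE) {
  A_hat <- as.matrix(A_hat); A_ref <- as.matrix(A_ref)
  if (!all(dim(A_hat) == dim(A_ref))) {
    stop("mixing matrices must have identical shape")
  }
  if (qr(A_ref)$rank < ncol(A_ref)) stop("A_ref is rank deficient")
  .amari_from_P(MASS::ginv(A_hat) %*% A_ref, normalized)
}

.bipartite_parts <- function(graph) {
  list(regulators = unique(graph$edges$source),
       targets = unique(graph$edges$target))
}

#' Degree-preserving edge rewiring
#'
#' Interprets the network as a weighted bipartite graph (regulators vs
#' regulated genes) and performs `ceiling(fraction * |E|)` edge-pair swaps
#' `(a->b, c->d) => (a->d, c->b)`, rejecting swaps that would duplicate an
#' existing edge. Every regulator keeps its out-degree, every target its
#' in-degree; weights travel with their source endpoint.
#'
#' @param graph a `regulatory_graph`.
#' @param fraction fraction of edges to rewire, in \[0, 1\].
#' @param seed integer seed.
#' @return perturbed `regulatory_graph` (same node set, same edge count).
#' @export
rewire_network <- function(graph, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  e <- graph$edges
  n_e <- nrow(e)
  if (fraction == 0) return(graph)
  if (n_e < 2L) stop("graph too small to rewire: need at least 2 edges")
  n_swaps <- ceiling(fraction * n_e)
  withr::local_seed(as.integer(seed))
  key <- function(s, t) paste0(s, "\r", t)
  existing <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(e$source, e$target)) assign(k, TRUE, envir = existing)
  done <- 0L
  attempts <- 0L
  max_attempts <- 200L * n_swaps + 1000L
  while (done < n_swaps) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("rewiring stalled: graph admits too few degree-preserving swaps")
    }
    ij <- sample.int(n_e, 2L)
    a <- e$source[ij[1L]]; b <- e$target[ij[1L]]
    cc <- e$source[ij[2L]]; d <- e$target[ij[2L]]
    if (b == d || a == cc) next
    if (exists(key(a, d), envir = existing) ||
        exists(key(cc, b), envir = existing)) next
    rm(list = c(key(a, b), key(cc, d)), envir = existing)
    assign(key(a, d), TRUE, envir = existing)
    assign(key(cc, b), TRUE, envir = existing)
    e$target[ij[1L]] <- d
    e$target[ij[2L]] <- b
    done <- done + 1L
  }
  regulatory_graph(e, nodes = graph$nodes)
}

#' Add random edges to a network
#'
#' Adds `ceiling(fraction * |E|)` edges between uniformly sampled
#' non-adjacent (regulator, target) pairs, with weights drawn from the
#' empirical multiset of existing weights. Original edges are untouched.
#'
#' @param graph a `regulatory_graph`.
#' @param fraction new edges as a fraction of the current edge count.
#' @param seed integer seed.
#' @return augmented `regulatory_graph`.
#' @export
add_random_edges <- function(graph, fraction, seed = 1L) {
  if (fraction < 0) stop("fraction must be nonnegative")
  e <- graph$edges
  n_e <- nrow(e)
  if (fraction == 0 || n_e == 0L) return(graph)
  n_add <- ceiling(fraction * n_e)
  parts <- .bipartite_parts(graph)
  R <- parts$regulators; Tg <- parts$targets
  existing <- paste0(e$source, "\r", e$target)
  withr::local_seed(as.integer(seed))
  all_pairs <- expand.grid(source = R, target = Tg,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
  pair_key <- paste0(all_pairs$source, "\r", all_pairs$target)
  candidates <- which(!pair_key %in% existing)
  if (length(candidates) < n_add) {
    stop(sprintf("only %d absent regulator-target pairs, need %d",
                 length(candidates), n_add))
  }
  pick <- sample(candidates, n_add)
  new_edges <- data.frame(source = all_pairs$source[pick],
                          target = all_pairs$target[pick],
                          weight = sample(e$weight, n_add, replace = TRUE),
                          stringsAsFactors = FALSE)
  regulatory_graph(rbind(e, new_edges), nodes = graph$nodes)
}

#' Randomly subsample replicates and average per condition
#'
#' For each condition, draws r uniformly from 1..(number of replicates),
#' chooses r replicates without replacement and averages them into one
#' observation row. Emulates the replicate-level noise seen when only part
#' of the replicates is available.
#'
#' @param X matrix, samples x genes.
#' @param design condition label per row of `X`.
#' @param seed integer seed.
#' @return matrix, conditions x genes (order of first appearance).
#' @export
subsample_replicates <- function(X, design, seed = 1L) {
  X <- as.matrix(X)
  design <- as.character(design)
  stopifnot(length(design) == nrow(X))
  lv <- unique(design)
  withr::local_seed(as.integer(seed))
  out <- matrix(NA_real_, length(lv), ncol(X),
                dimnames = list(lv, colnames(X)))
  for (cond in lv) {
    rows <- which(design == cond)
    if (length(rows) == 0L) stop("empty condition: ", cond)
    r <- sample.int(length(rows), 1L)
    chosen <- if (length(rows) == 1L) rows else sample(rows, r)
    out[cond, ] <- colMeans(X[chosen, , drop = FALSE])
  }
  out
}

#' Empirical p-value of an observed quantile against a null sample
#'
#' `p = (1 + #(null <= q)) / (1 + #null)`: the (add-one) fraction of the
#' null distribution at or below the observed value. Small p means the
#' perturbed separations stay significantly closer to the reference than
#' random separating matrices do.
#'
#' @param observed_quantile observed summary (e.g. a 95% Amari quantile).
#' @param null_samples numeric vector of null Amari indices.
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed_quantile, null_samples) {
  if (length(null_samples) == 0L) stop("empty null sample")
  (1 + sum(null_samples <= observed_quantile)) / (1 + length(null_samples))
}

# Null Amari indices: random normal separating matrices applied to the
# reference mixing matrix.
.null_amari <- function(A_ref, n_null, seed, normalized = FALSE) {
  withr::local_seed(as.integer(seed))
  n <- ncol(A_ref); m <- nrow(A_ref)
  vapply(seq_len(n_null), function(i) {
    B <- matrix(stats::rnorm(n * m), n, m)
    .amari_from_P(B %*% A_ref, normalized)
  }, numeric(1))
}

#' Robustness scan of the factorization
#'
#' Computes a reference factorization from the unperturbed inputs, then
#' repeatedly perturbs the network (degree-preserving rewiring or random
#' edge addition) or the data (replicate subsampling) and scores each
#' perturbed mixing matrix against the reference with the Amari index.
#' Per perturbation fraction the 95% quantile of the Amari distribution is
#' compared with a null of random separating matrices via
#' [empirical_pvalue()].
#'
#' @param X observation matrix, m x l (for `kind = "replicate_subsample"`,
#'   the replicate-level samples x genes matrix; otherwise one row per
#'   observation).
#' @param graph the prior network (`regulatory_graph`).
#' @param kind `"rewire"`, `"add_edges"` or `"replicate_subsample"`.
#' @param fractions perturbation fractions (ignored for replicate
#'   subsampling, where a single sweep is reported as fraction `NA`).
#' @param n_repeats perturbed factorizations per fraction (default 100).
#' @param n_null size of the random-matrix null sample (default 1000).
#' @param seed master seed; per-repeat substreams are derived from it.
#' @param tau shift passed to [grade()].
#' @param design condition labels (required for replicate subsampling).
#' @param normalized use the normalized Amari index.
#' @return object of class `robustness_report`: list with `kind`,
#'   `fractions`, `amari` (list of numeric vectors), `q95`, `p`, `null`,
#'   `reference` (the reference `grade_result`).
#' @export
robustness_scan <- function(X, graph, kind = c("rewire", "add_edges",
                                               "replicate_subsample"),
                            fractions = c(0.001, 0.01, 0.03, 0.05, 0.1,
                                          0.2, 0.5, 1.0),
                            n_repeats = 100L, n_null = 1000L, seed = 1L,
                            tau = 1L, design = NULL, normalized = FALSE) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  genes <- colnames(X)
  if (is.null(genes)) stop("X needs gene column names to align the network")
  W_ref <- to_weight_matrix(graph, genes, drop_missing = TRUE)
  X_ref <- if (kind == "replicate_subsample") {
    if (is.null(design)) stop("replicate subsampling needs a design")
    average_replicates(X, design)
  } else X
  ref <- grade(X_ref, W_ref, tau = tau)
  A_ref <- ref$A
  withr::local_seed(as.integer(seed))
  null_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  if (kind == "replicate_subsample") fractions <- NA_real_
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(fractions) * n_repeats),
                      length(fractions), n_repeats)
  amari <- vector("list", length(fractions))
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    amari[[fi]] <- vapply(seq_len(n_repeats), function(r) {
      s <- sub_seeds[fi, r]
      Xp <- X_ref
      Wp <- W_ref
      if (kind == "rewire") {
        Wp <- to_weight_matrix(rewire_network(graph, f, seed = s), genes,
                               drop_missing = TRUE)
      } else if (kind == "add_edges") {
        Wp <- to_weight_matrix(add_random_edges(graph, f, seed = s), genes,
                               drop_missing = TRUE)
      } else {
        Xp <- subsample_replicates(X, design, seed = s)
      }
      fit <- suppressWarnings(grade(Xp, Wp, tau = tau))
      amari_index(fit$A, A_ref, normalized = normalized)
    }, numeric(1))
  }
  nul <- .null_amari(A_ref, n_null, null_seed, normalized)
  q95 <- vapply(amari, stats::quantile, numeric(1), probs = 0.95, names = FALSE)
  p <- vapply(q95, empirical_pvalue, numeric(1), null_samples = nul)
  structure(list(kind = kind, fractions = fractions, amari = amari,
                 q95 = q95, p = p, null = nul, reference = ref),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness_report (%s): %d fraction(s), %d repeats each\n",
              x$kind, length(x$fractions), length(x$amari[[1L]])))
  med <- vapply(x$amari, stats::median, numeric(1))
  for (i in seq_along(x$fractions)) {
    cat(sprintf("  fraction %-6s median Amari %.3f  q95 %.3f  p %.4g\n",
                format(x$fractions[i]), med[i], x$q95[i], x$p[i]))
  }
  invisible(x)
}

#' Summarize a robustness report as data frames
#'
#' @param object a `robustness_report`.
#' @param ... unused.
#' @return list with `samples` (fraction, repeat, amari) and `summary`
#'   (fraction, median, q95, p), both data frames ready for TSV export.
#' @export
summary.robustness_report <- function(object, ...) {
  samples <- do.call(rbind, lapply(seq_along(object$fractions), function(i) {
    data.frame(fraction = object$fractions[i],
               repetition = seq_along(object$amari[[i]]),
               amari = object$amari[[i]])
  }))
  summary <- data.frame(fraction = object$fractions,
                        median = vapply(object$amari, stats::median,
                                        numeric(1)),
                        q95 = object$q95, p = object$p)
  list(samples = samples, summary = summary)
}
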