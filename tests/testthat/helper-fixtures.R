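# Shared fixtures and independent oracles, built in code.

# Line graph 1 -> 2 -> ... -> l with unit weights: the graph whose shift
# reproduces the classic time lag.
make_line_graph <- function(l) {
  genes <- paste0("g", seq_len(l))
  graph <- regulatory_graph(data.frame(source = genes[-l], target = genes[-1],
                                       weight = 1, stringsAsFactors = FALSE))
  list(graph = graph, genes = genes,
       W = to_weight_matrix(graph, genes))
}

# Hand-rolled lag operator: shift columns right by k, zero-fill.
lag_columns <- function(X, k) {
  l <- ncol(X)
  if (k == 0) return(X)
  cbind(matrix(0, nrow(X), k), X[, seq_len(l - k), drop = FALSE])
}

# Brute-force lag-k correlation estimator: explicit sums over
# E(x_i(t + k) x_j(t))-style products, no matrix shortcuts.
lag_correlation_bruteforce <- function(X, k) {
  m <- nrow(X); l <- ncol(X)
  C <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      acc <- 0
      for (t in seq_len(l)) {
        tp <- t - k                     # activity arriving from k steps back
        if (tp >= 1 && tp <= l) acc <- acc + X[i, tp] * X[j, t]
      }
      C[i, j] <- acc / (l - 1)
    }
  }
  C
}

# Element-by-element evaluation of the Amari formula, independent of the
# packaged implementation (explicit loops, solve() for the inverse).
amari_bruteforce <- function(A_hat, A_ref) {
  P <- abs(solve(A_hat) %*% A_ref)
  n <- nrow(P)
  total <- 0
  for (i in seq_len(n)) {
    row_max <- max(P[i, ])
    total <- total + sum(P[i, ]) / row_max - 1
  }
  for (j in seq_len(n)) {
    col_max <- max(P[, j])
    total <- total + sum(P[, j]) / col_max - 1
  }
  total
}

# Exhaustive hypergeometric upper-tail probability by enumeration of all
# achievable overlap counts.
hyper_tail_bruteforce <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Small random bipartite regulator -> target graph.
make_bipartite_graph <- function(n_reg, n_tgt, n_edges, seed = 1L) {
  withr::local_seed(seed)
  regs <- paste0("r", seq_len(n_reg))
  tgts <- paste0("t", seq_len(n_tgt))
  pairs <- expand.grid(source = regs, target = tgts,
                       stringsAsFactors = FALSE)
  pick <- sample.int(nrow(pairs), n_edges)
  regulatory_graph(data.frame(pairs[pick, ],
                              weight = sample(c(-1, 1), n_edges, TRUE)))
}

# Degree multisets of a graph, for rewiring invariance checks.
degree_multisets <- function(graph) {
  list(out = sort(table(graph$edges$source)),
       inn = sort(table(graph$edges$target)))
}
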