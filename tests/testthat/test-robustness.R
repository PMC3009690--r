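test_that("Amari index vanishes exactly on scaled permutations", {
  set.seed(51)
  A <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(amari_index(A, A), 0, tolerance = 1e-12)
  P <- diag(4)[, c(3, 1, 4, 2)]
  D <- diag(c(2, -3, 0.5, 10))
  expect_equal(amari_index(A %*% P %*% D, A), 0, tolerance = 1e-10)
  expect_gt(amari_index(matrix(rnorm(16), 4, 4), A), 0.1)
  expect_error(amari_index(A, matrix(0, 4, 4)), "rank")
  expect_error(amari_index(A, A[, 1:2]), "shape")
  # normalized variant rescales by 2n(n-1)
  B <- matrix(rnorm(16), 4, 4)
  expect_equal(amari_index(B, A, normalized = TRUE),
               amari_index(B, A) / 24)
})

test_that("Amari index matches an independent element-by-element
           evaluation", {
  for (s in 1:5) {
    set.seed(100 + s)
    A1 <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    A2 <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    expect_equal(amari_index(A1, A2), amari_bruteforce(A1, A2),
                 tolerance = 1e-12)
  }
})

test_that("degree-preserving rewiring keeps degrees and edge count", {
  g <- make_bipartite_graph(10, 12, 100, seed = 61)
  expect_identical(rewire_network(g, 0, seed = 1), g)

  for (f in c(0.1, 0.5, 1.0)) {
    r <- rewire_network(g, f, seed = 62)
    expect_equal(n_edges(r), 100L)
    expect_equal(degree_multisets(r), degree_multisets(g))
    expect_false(anyDuplicated(paste(r$edges$source, r$edges$target)) > 0)
    # weights still drawn from the original multiset per source endpoint
    expect_equal(sort(r$edges$weight), sort(g$edges$weight))
  }
  full <- rewire_network(g, 1.0, seed = 63)
  expect_gt(length(setdiff(paste(full$edges$source, full$edges$target),
                           paste(g$edges$source, g$edges$target))), 0L)
  expect_error(rewire_network(g, 1.5, seed = 1), "fraction")
  expect_error(rewire_network(regulatory_graph(
    data.frame(source = "a", target = "b", weight = 1)), 0.5, seed = 1),
    "too small")
})

test_that("random edge addition augments without touching original edges", {
  g <- make_bipartite_graph(10, 30, 100, seed = 71)
  expect_identical(add_random_edges(g, 0, seed = 1), g)
  a <- add_random_edges(g, 0.5, seed = 72)
  expect_equal(n_edges(a), 150L)
  key <- function(gr) paste(gr$edges$source, gr$edges$target)
  expect_true(all(key(g) %in% key(a)))
  expect_false(anyDuplicated(key(a)) > 0)
  expect_true(all(a$edges$weight %in% g$edges$weight))
  # determinism
  expect_identical(add_random_edges(g, 0.5, seed = 72)$edges, a$edges)
  # asking for more pairs than exist
  small <- regulatory_graph(data.frame(source = c("r1", "r1"),
                                       target = c("t1", "t2"), weight = 1))
  expect_error(add_random_edges(small, 1.0, seed = 1), "absent")
})

test_that("replicate subsampling averages a seeded draw per condition", {
  set.seed(81)
  X <- matrix(rnorm(6 * 10), 6, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  design <- rep(c("0h", "1h"), each = 3)
  s1 <- subsample_replicates(X, design, seed = 9)
  expect_equal(dim(s1), c(2L, 10L))
  expect_identical(subsample_replicates(X, design, seed = 9), s1)
  # single replicate per condition: output equals input
  X1 <- X[c(1, 4), , drop = FALSE]
  expect_equal(unname(subsample_replicates(X1, c("0h", "1h"), seed = 2)),
               unname(X1))
  # every subsampled row is an average of a subset of that condition's rows
  for (cond in c("0h", "1h")) {
    rows <- X[design == cond, , drop = FALSE]
    subsets <- unlist(lapply(1:3, function(r)
      utils::combn(3, r, simplify = FALSE)), recursive = FALSE)
    means <- t(vapply(subsets, function(ix) colMeans(rows[ix, , drop = FALSE]),
                      numeric(10)))
    expect_true(min(apply(means, 1, function(mu)
      max(abs(mu - s1[cond, ])))) < 1e-12)
  }
})

test_that("empirical p-values count the null mass at or below the observed
           quantile", {
  expect_equal(empirical_pvalue(0.5, 1:9), 1 / 10)
  expect_equal(empirical_pvalue(100, 1:9), 1)
  expect_equal(empirical_pvalue(4.5, 1:9), 5 / 10)
  expect_error(empirical_pvalue(1, numeric()), "empty")
})

test_that("robustness scan: zero perturbation reproduces the reference
           exactly", {
  net <- random_network(80, density = 0.05, seed = 91)
  mix <- synthetic_mixture(4, 4, 80, net$W, seed = 92)
  rep0 <- robustness_scan(mix$X, net$graph, kind = "rewire",
                          fractions = c(0, 0.5), n_repeats = 5L,
                          n_null = 50L, seed = 93)
  expect_equal(rep0$amari[[1]], rep(0, 5), tolerance = 1e-8)
  expect_equal(rep0$p[1], 1 / 51)
  expect_length(rep0$fractions, 2L)
  expect_length(rep0$null, 50L)
  expect_gt(median(rep0$amari[[2]]), median(rep0$amari[[1]]))
  sm <- summary(rep0)
  expect_equal(nrow(sm$samples), 10L)
  expect_equal(nrow(sm$summary), 2L)
})

test_that("robustness scan supports replicate subsampling", {
  net <- random_network(60, density = 0.06, seed = 94)
  mix <- synthetic_mixture(3, 3, 60, net$W, seed = 95)
  # replicate-level samples: 3 conditions x 2 replicates with mild noise
  design <- rep(c("c1", "c2", "c3"), each = 2)
  Xrep <- mix$X[rep(1:3, each = 2), ] +
    matrix(rnorm(6 * 60, sd = 0.02), 6, 60)
  colnames(Xrep) <- colnames(mix$X)
  rep1 <- robustness_scan(Xrep, net$graph, kind = "replicate_subsample",
                          design = design, n_repeats = 8L, n_null = 50L,
                          seed = 96)
  expect_length(rep1$amari, 1L)
  expect_length(rep1$amari[[1]], 8L)
  expect_true(all(rep1$amari[[1]] >= 0))
  expect_error(robustness_scan(Xrep, net$graph,
                               kind = "replicate_subsample", seed = 1),
               "design")
})
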