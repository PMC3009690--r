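test_that("submodes split each source at the signed threshold", {
  S <- matrix(0.1, 2, 6, dimnames = list(NULL, paste0("g", 1:6)))
  S[1, 1] <- 3.0; S[1, 2] <- -2.5; S[2, 3] <- 2.0   # boundary included
  sub <- suppressWarnings(extract_submodes(S, threshold = 2))
  expect_length(sub, 4L)
  expect_equal(sub[[1]]$genes, "g1")
  expect_equal(sub[[2]]$genes, "g2")
  expect_equal(sub[[3]]$genes, "g3")                # >= 2 is inclusive
  expect_length(sub[[4]]$genes, 0L)
  # positive and negative submodes are disjoint by construction
  expect_length(intersect(sub[[1]]$genes, sub[[2]]$genes), 0L)
  expect_warning(extract_submodes(S * 3), "unit variance")
})

test_that("hypergeometric p-values match the worked combinatorial example", {
  universe <- paste0("u", 1:10)
  annotation <- list(path = universe[1:5])
  tab <- hypergeometric_enrichment(universe[1:4], universe, annotation)
  expect_equal(tab$p, 5 / 210, tolerance = 1e-12)   # C(5,4)C(5,0)/C(10,4)
  expect_equal(tab$overlap, 4L)

  # zero overlap: upper tail is certain
  tab0 <- hypergeometric_enrichment(universe[6:9], universe,
                                    list(path = universe[1:5]))
  expect_equal(tab0$p, 1)
  # query = universe: every achievable overlap is the full set
  tabU <- hypergeometric_enrichment(universe, universe,
                                    list(path = universe[1:5]))
  expect_equal(tabU$p, 1)

  expect_error(hypergeometric_enrichment(character(), universe, annotation),
               "empty query")
  expect_error(hypergeometric_enrichment("zz", universe, annotation),
               "outside the universe")
  empty <- hypergeometric_enrichment(universe[1:2], universe, list())
  expect_equal(nrow(empty), 0L)
})

test_that("hypergeometric p-values equal exhaustive enumeration on small
           universes", {
  for (N in c(5L, 9L, 12L)) {
    universe <- paste0("u", seq_len(N))
    for (n in seq_len(N)) {
      query <- universe[seq_len(n)]
      sets <- list()
      for (K in 2:N) {
        for (k in max(0L, n + K - N):min(K, n)) {
          if (K - k > N - n) next
          sets[[sprintf("K%d_k%d", K, k)]] <-
            c(utils::head(query, k),
              utils::head(setdiff(universe, query), K - k))
        }
      }
      tab <- hypergeometric_enrichment(query, universe, sets)
      for (r in seq_len(nrow(tab))) {
        kk <- as.integer(sub(".*_k", "", tab$set[r]))
        KK <- as.integer(sub("K(\\d+)_.*", "\\1", tab$set[r]))
        expect_equal(tab$p[r], hyper_tail_bruteforce(N, KK, n, kk),
                     tolerance = 1e-12)
        expect_equal(tab$overlap[r], kk)
      }
    }
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  # hand-computed staircase: p * n / rank, cumulative minimum from the top
  expect_equal(bh_adjust(c(0.001, 0.01, 0.9, 0.04)),
               c(0.004, 0.02, 0.9, 0.04 * 4 / 3))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # monotone in raw-p rank
  set.seed(44)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("BH keeps the false-discovery proportion near its level on null
           simulations", {
  set.seed(45)
  fdp <- replicate(300, {
    mean(bh_adjust(runif(100)) < 0.05) > 0
  })
  # under the complete null FDP is 0/1; its mean estimates FDR <= alpha
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 300))
})

test_that("pathway enrichment index counts pathways hit by any submode", {
  universe <- paste0("u", 1:40)
  annotation <- list(hit = universe[1:8],
                     miss1 = universe[9:16],
                     miss2 = universe[17:24])
  # one submode concentrated in 'hit', one diffuse
  pei <- pathway_enrichment_index(list(universe[1:6], universe[c(30, 35)]),
                                  universe, annotation)
  expect_equal(pei$pei, 1 / 3)
  expect_equal(pei$significant, "hit")
  expect_equal(pei$n_tested, 3L)

  # all-significant and none-significant extremes
  expect_equal(pathway_enrichment_index(list(universe[1:8], universe[9:16],
                                             universe[17:24]),
                                        universe, annotation)$pei, 1)
  expect_equal(pathway_enrichment_index(list(universe[c(1, 9, 17, 25, 33)]),
                                        universe, annotation)$pei, 0)

  # monotone nondecreasing when submodes are added
  p1 <- pathway_enrichment_index(list(universe[1:6]), universe, annotation)
  p2 <- pathway_enrichment_index(list(universe[1:6], universe[9:14]),
                                 universe, annotation)
  expect_gte(p2$pei, p1$pei)

  expect_error(pathway_enrichment_index(list("u1"), universe,
                                        list(far = "zz")), "undefined")
})

test_that("PCA baseline recovers dominant directions with unit-variance
           components", {
  set.seed(46)
  strong <- center_rows(matrix(rnorm(300), 1, 300))$x
  X <- rbind(10 * strong + rnorm(300, sd = 0.01),
             rnorm(300), rnorm(300))
  res <- pca_baseline(X)
  expect_gt(res$explained_variance[1], 0.95)
  expect_equal(sum(res$explained_variance), 1, tolerance = 1e-8)
  expect_equal(diag(cross_correlation(res$S)),
               rep(1, nrow(res$S)), tolerance = 1e-8)
  expect_length(res$submodes, 2L * nrow(res$S))

  # near-white data spread variance nearly uniformly
  Xw <- center_rows(matrix(rnorm(4 * 2000), 4, 2000))$x
  resw <- pca_baseline(Xw)
  expect_lt(max(resw$explained_variance), 0.35)
})

test_that("k-means baseline separates well-separated gene groups", {
  set.seed(47)
  X <- rbind(matrix(rnorm(40 * 4, mean = 8), 40, 4),
             matrix(rnorm(40 * 4, mean = -8), 40, 4))
  rownames(X) <- paste0("g", 1:80)
  res <- kmeans_baseline(X, k = 2, top_frac = 1.0, seed = 5)
  expect_length(res$cluster, 80L)                  # top_frac = 1 keeps all
  truth <- rep(1:2, each = 40)
  agreement <- max(mean(res$cluster == truth), mean(res$cluster == 3 - truth))
  expect_equal(agreement, 1)
  expect_identical(kmeans_baseline(X, k = 2, top_frac = 1, seed = 5)$cluster,
                   res$cluster)
  expect_error(kmeans_baseline(X[1:5, ], k = 8, top_frac = 1), "exceeds")
})

test_that("GMT gene sets round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\t-\tg2\tg9"), path)
  gmt <- read_gmt(path)
  expect_equal(gmt, list(setA = c("g1", "g2", "g3"), setB = c("g2", "g9")))
  writeLines("broken\tonly-two-fields", path)
  expect_error(read_gmt(path), "fewer than 3")
})
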