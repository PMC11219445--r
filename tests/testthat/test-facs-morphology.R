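test_that("one-hot encoding produces paired present/absent dummies", {
  oh <- one_hot_encode(list(c("AU25+26"), character(0), c("AU25+26")))
  expect_equal(ncol(oh), 24L)
  expect_true(all(rowSums(oh) == 12))
  expect_equal(oh[1, "AU25+26=present"], c("AU25+26=present" = 1))
  expect_equal(sum(oh[1, grepl("absent", colnames(oh))]), 11)
  expect_equal(sum(oh[2, grepl("absent", colnames(oh))]), 12)
  expect_equal(oh[1, ], oh[3, ])  # determinism
  expect_error(one_hot_encode(list("AU99")), "unknown AU code")
})

test_that("MCA separates a two-block design and matches the eigen oracle", {
  blocks <- c(rep(list(c("AU25+26", "AU43")), 5L),
              rep(list(c("AU25+27", "AU12", "EAD3")), 5L))
  oh <- one_hot_encode(blocks)
  res <- project_mixed_pca(oh)
  d1 <- res$coords[, 1L]
  expect_true(all(sign(d1[1:5]) == sign(d1[1])))
  expect_true(all(sign(d1[6:10]) == -sign(d1[1])))
  expect_lt(abs(sum(d1 * rowSums(oh) / sum(oh))), 1e-10)  # mass-centered
  # variance fractions: non-increasing, sum to 1 over non-null dims
  expect_true(all(diff(res$var_frac) <= 1e-12))
  expect_equal(sum(res$var_frac), 1)
  # duplication invariance
  res2 <- project_mixed_pca(oh[rep(seq_len(10L), each = 2L), ])
  expect_equal(res2$var_frac, res$var_frac, tolerance = 1e-10)
  # independent eigendecomposition oracle on 6 hand-built configurations
  cfgs <- list(c("AU25+26"), c("AU25+26", "AU43"), c("AU25+26", "AU8"),
               c("AU25+27", "AU12"), c("AU25+27", "AU12", "EAD3"),
               c("AU25+27", "AU45"))
  oh6 <- one_hot_encode(cfgs)
  got <- project_mixed_pca(oh6)
  want <- mca_oracle(oh6)
  expect_equal(got$values, want$values, tolerance = 1e-10)
  for (j in seq_len(min(3L, ncol(want$coords))))
    expect_equal(abs(got$coords[, j]), abs(want$coords[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(project_mixed_pca(matrix(1, 5, 4)), "degenerate_input")
})

test_that("k-means matches exhaustive minimum-SSE enumeration", {
  # 10 points on a line in two tight groups of 5
  x <- matrix(c(0, 0.1, 0.2, 0.15, 0.05, 10, 10.1, 10.2, 10.15, 10.05), ncol = 1)
  oracle <- kmeans_oracle_2(x)
  labs <- cluster_kmeans(x, k = 2, seed = 4)
  expect_equal(cluster_purity(labs, oracle$labels), 100)
  expect_equal(attr(labs, "fit")$tot.withinss, oracle$sse, tolerance = 1e-9)
  # two-block binary matrix: perfect split, stable across seeds
  xb <- rbind(matrix(0, 6, 8), matrix(1, 7, 8))
  truth <- rep(0:1, c(6, 7))
  for (s in c(1, 99))
    expect_equal(cluster_purity(cluster_kmeans(xb, 2, seed = s), truth), 100)
  expect_error(cluster_kmeans(matrix(1, 4, 2), k = 2),
               "insufficient_distinct_points")
})

test_that("purity is mapping- and permutation-invariant", {
  ap <- rep(c("CT", "UCT"), c(4, 6))
  labs <- rep(c(0, 1), c(4, 6))
  expect_equal(cluster_purity(labs, ap), 100)
  expect_equal(cluster_purity(1 - labs, ap), 100)
  labs[1] <- 1
  expect_equal(cluster_purity(labs, ap), 90)
  perm <- sample(10)
  expect_equal(cluster_purity(labs[perm], ap[perm]), 90)
  expect_error(cluster_purity(labs, ap[-1]), "length mismatch")
})

test_that("AU contrast table reproduces the printed per-AU tests", {
  fx <- fixture_table3(seed = 2)
  tab <- au_contrast_table(fx$au_string[fx$apriori_label == "CT"],
                           fx$au_string[fx$apriori_label == "UCT"])
  expect_equal(tab$n_ct, c(2, 2, 7, 0, 0, 0, 25, 0, 4, 0, 0, 0))
  expect_equal(tab$n_uct, c(0, 35, 0, 39, 39, 39, 0, 39, 5, 24, 31, 39))
  getp <- function(au) tab$p_value[tab$au == au]
  expect_equal(round(getp("AU1/2"), 3), 0.149)
  expect_equal(round(getp("AU43"), 3), 0.728)
  expect_lt(getp("AU6"), 0.001)
  expect_lt(getp("AU8"), 0.001)
  expect_equal(tab$pct_ct[tab$au == "AU8"], 28)
  expect_equal(tab$pct_uct[tab$au == "AU45"], 61.54)
  # an AU absent from both groups is uninformative
  expect_equal(getp("EAD3") == getp("EAD3"), TRUE)
  expect_equal(fisher_exact_2x2(0, 25, 0, 39), 1)
})

test_that("a fully separating AU forces 100% purity for every seed", {
  # AU25+26 (and the mouth-stretch block) are deterministic separators
  for (fs in 1:3) {
    fx <- fixture_table3(seed = fs)
    oh <- one_hot_encode(fx)
    for (s in 1:5)
      expect_equal(cluster_purity(cluster_kmeans(oh, 2, seed = s),
                                  fx$apriori_label), 100)
  }
})
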