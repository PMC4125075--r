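# Clustering, Davies-Bouldin scoring, period choice, misclassification.

test_that("davies_bouldin matches hand computations and basic invariances", {
  f <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
  expect_equal(davies_bouldin(f, c(1, 1, 2, 2)), 0.2)
  expect_equal(davies_bouldin(rbind(c(0, 0), c(5, 5)), 1:2), 0)
  expect_equal(davies_bouldin(f + 100, c(1, 1, 2, 2)), 0.2)
  # coincident centroids
  g <- rbind(c(0, 0), c(0, 0), c(0, 1), c(0, -1))
  expect_equal(davies_bouldin(g, c(1, 1, 2, 2)), Inf)
  expect_error(davies_bouldin(f, rep(1, 4)), "2 clusters")
})

test_that("davies_bouldin equals a from-definition reimplementation", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(6:15, 1); d <- sample(1:4, 1); k <- sample(2:4, 1)
    f <- matrix(rnorm(n * d), n, d)
    labs <- sample(rep(seq_len(k), length.out = n))
    expect_equal(davies_bouldin(f, labs), db_brute(f, labs),
                 tolerance = 1e-12)
  }
})

test_that("average-linkage clustering recovers planted structure", {
  r <- hcluster(cbind(c(0, 1, 10, 11)), 2)
  expect_equal(misclassification_count(r$labels, c(1, 1, 2, 2)), 0)

  dup <- rbind(c(0, 0), c(0, 0), c(0, 0), c(9, 9), c(9, 9), c(9, 9))
  rd <- hcluster(dup, 2)
  expect_equal(misclassification_count(rd$labels, rep(1:2, each = 3)), 0)
  expect_equal(sort(rd$hclust$height)[1:4], rep(0, 4))

  expect_true(all(hcluster(dup, 1)$labels == 1))
  expect_error(hcluster(dup, 7), "k")
})

test_that("clustering is invariant to row order up to relabeling", {
  set.seed(12)
  f <- rbind(matrix(rnorm(12, 0), 4), matrix(rnorm(12, 6), 4),
             matrix(rnorm(12, 12), 4))
  truth <- rep(1:3, each = 4)
  perm <- sample(12)
  a <- hcluster(f, 3)$labels
  b <- hcluster(f[perm, ], 3)$labels
  expect_equal(misclassification_count(a, truth), 0)
  expect_equal(misclassification_count(b, truth[perm]), 0)
})

test_that("misclassification count equals the exhaustive permutation minimum", {
  expect_equal(misclassification_count(c(2, 2, 1, 1), c(1, 1, 2, 2)), 0)
  expect_equal(misclassification_count(c(1, 1, 1, 2, 2), c(1, 1, 2, 2, 2)), 1)
  set.seed(13)
  for (i in 1:10) {
    pred <- sample(1:4, 20, replace = TRUE)
    true <- rep(1:4, each = 5)
    expect_equal(misclassification_count(pred, true),
                 misclass_brute(pred, true))
  }
})

test_that("choose_period scans the shared grid and finds a planted period", {
  dt <- 1 / 6
  tt <- seq(0, 40, by = dt)
  set.seed(14)
  sigs <- list(); groups <- c()
  for (g in 1:2) for (r in 1:3) {
    # groups differ only in the phase/amplitude of a 24 h component
    amp <- if (g == 1) 1 else -1
    x <- amp * sin(2 * pi * tt / 24) + 0.5 * sin(2 * pi * tt / 3) +
      0.05 * rnorm(length(tt))
    sigs[[length(sigs) + 1]] <- wavelet_transform(x, dt = dt)
    groups <- c(groups, g)
  }
  sel <- choose_period(sigs, groups)
  expect_false(sel$degenerate)
  expect_gt(sel$period, 12)   # long-period rows separate the groups

  zeros <- lapply(1:4, function(i) wavelet_transform(numeric(100), dt = dt))
  selz <- choose_period(zeros, c(1, 1, 2, 2))
  expect_true(selz$degenerate)
  expect_true(all(!is.finite(selz$db_by_period)))
})

test_that("choose_period honours a period-exclusion mask", {
  dt <- 1 / 6
  tt <- seq(0, 40, by = dt)
  set.seed(15)
  sigs <- lapply(1:4, function(i)
    wavelet_transform(sin(2 * pi * tt / (8 + 4 * (i > 2))) + 0.1 * rnorm(length(tt)),
                      dt = dt))
  groups <- c(1, 1, 2, 2)
  sel <- choose_period(sigs, groups)
  mask <- sigs[[1]]$periods >= sel$period * 0.99 &
          sigs[[1]]$periods <= sel$period * 1.01
  sel2 <- choose_period(sigs, groups, exclude = mask)
  expect_false(isTRUE(all.equal(sel2$period, sel$period)))
})

test_that("leave-one-out analysis counts every run and flags overlap", {
  set.seed(16)
  sep <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 8, 0.1), 5))
  groups <- rep(1:2, each = 5)
  b <- bootstrap_misclassification(sep, groups)
  expect_length(b$counts, 10)
  expect_true(all(b$counts == 0))
  expect_equal(sum(b$histogram), 10)

  overlap <- rbind(matrix(rnorm(20, 0, 2), 10), matrix(rnorm(20, 0, 2), 10))
  bo <- bootstrap_misclassification(overlap, rep(1:2, each = 10))
  expect_gt(sum(bo$counts), 0)

  expect_error(bootstrap_misclassification(sep, c(1, rep(2, 9))), "members")
})

test_that("dendrograms export to Newick and parse back to the same topology", {
  r2 <- hcluster(rbind(a = c(0, 0), b = c(4, 0)), 2)
  nwk2 <- export_dendrogram(r2)
  expect_match(nwk2, "a:2")
  expect_match(nwk2, "b:2")

  f <- rbind(a = c(0, 0), b = c(0, 1), c = c(5, 5), d = c(5, 6), e = c(20, 0))
  r <- hcluster(f, 2)
  phy <- ape::read.tree(text = export_dendrogram(r))
  expect_setequal(phy$tip.label, rownames(f))
  # (a,b) and (c,d) are cherries in the merge tree
  pairs <- ape::prop.part(phy)
  pair_sets <- lapply(pairs, function(p) sort(attr(pairs, "labels")[p]))
  expect_true(any(vapply(pair_sets, identical, logical(1), c("a", "b"))))
  expect_true(any(vapply(pair_sets, identical, logical(1), c("c", "d"))))
})

test_that("separation ratio grows with between-group distance", {
  set.seed(17)
  base <- matrix(rnorm(20), 10, 2)
  near <- base + rep(c(0, 2), each = 5)
  far <- base + rep(c(0, 10), each = 5)
  g <- rep(1:2, each = 5)
  expect_gt(separation_ratio(far, g), separation_ratio(near, g))
})
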