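test_that("score-to-rank conversion sorts descending with index tie-breaks", {
  expect_equal(scores_to_ranking(c(0.9, 0.1, 0.5))$rank, c(1L, 3L, 2L))
  expect_equal(scores_to_ranking(rep(1, 5))$rank, 1:5)
  expect_equal(scores_to_ranking(c(0.5, 0.5, 0.1))$rank, c(1L, 2L, 3L))
  expect_error(scores_to_ranking(c(a = 1, b = NaN)), "'b'")
})

test_that("Pearson ranking follows point-biserial correlation strength", {
  y <- c(0, 0, 0, 1, 1, 1)
  tab <- toy_table(list(f1 = 1:6, f2 = c(1, 1, 2, 1, 2, 2)), y)
  r <- rank_pearson(tab)
  # frozen oracle: cov/sd products give |cor(f1,y)| = 0.9/(1.870829*0.5477226)
  # = 0.8783101, |cor(f2,y)| = 0.1/(0.5477226^2) = 0.3333333
  expect_equal(r$score, c(0.8783101, 0.3333333), tolerance = 1e-6)
  expect_equal(r$rank, c(1L, 2L))

  tab2 <- toy_table(list(label_copy = y, noise = c(2, 5, 1, 4, 3, 6),
                         const = rep(7, 6)), y)
  r2 <- rank_pearson(tab2)
  expect_equal(r2$rank[r2$feature == "label_copy"], 1L)
  expect_equal(r2$rank[r2$feature == "const"], 3L) # zero variance -> last

  expect_error(rank_pearson(toy_table(list(f1 = 1:4), rep(1, 4))),
               "both classes")
})

test_that("ReliefF matches a brute-force neighbour computation at M = 4", {
  # two samples per class, one informative binary feature, one noise
  vals <- list(inf = c(0, 0, 1, 1), noise = c(0.1, 0.9, 0.35, 0.65))
  y <- c(0, 0, 1, 1)
  tab <- toy_table(vals, y)
  r <- rank_relief(tab, n_neighbors = 1)

  # independent oracle: exhaustive neighbour enumeration
  X <- cbind(vals$inf, vals$noise)
  rng <- apply(X, 2, function(v) diff(range(v)))
  Xn <- sweep(X, 2, rng, "/")
  W <- c(0, 0)
  for (i in 1:4) {
    d <- apply(Xn, 1, function(row) sum(abs(row - Xn[i, ])))
    hits <- setdiff(which(y == y[i]), i)
    misses <- which(y != y[i])
    h <- hits[which.min(d[hits])]
    m <- misses[which.min(d[misses])]
    W <- W + abs(Xn[m, ] - Xn[i, ]) - abs(Xn[h, ] - Xn[i, ])
  }
  W <- W / 4
  expect_equal(r$score, unname(W), tolerance = 1e-12)
  expect_gt(W[1], W[2])
  expect_equal(r$rank[r$feature == "inf"], 1L)
})

test_that("ReliefF finds a label-aligned feature and scores duplicates equally", {
  hit <- 0L
  for (s in 1:20) {
    set.seed(s)
    M <- 200
    y <- rbinom(M, 1, 0.5)
    df <- data.frame(sig = y, matrix(rnorm(M * 5), M, 5))
    tab <- feature_table(cbind(df, class = y))
    r <- rank_relief(tab, n_neighbors = 10)
    if (r$rank[r$feature == "sig"] == 1L) hit <- hit + 1L
  }
  expect_gte(hit, 19L)

  set.seed(7)
  df <- data.frame(a = rnorm(60), b = rnorm(60))
  df$dup <- df$a
  y <- rbinom(60, 1, plogis(df$a))
  tab <- feature_table(cbind(df, class = y))
  r <- rank_relief(tab, n_neighbors = 3)
  expect_lt(abs(r$score[r$feature == "a"] - r$score[r$feature == "dup"]), 1e-12)

  expect_error(rank_relief(small_signal_table(M = 8), n_neighbors = 10),
               "n_neighbors")
})

test_that("SVM-RFE keeps the separating feature and honours the step rule", {
  hit <- 0L
  for (s in 1:20) {
    set.seed(s)
    M <- 200
    y <- rep(0:1, each = M / 2)
    df <- data.frame(f1 = y * 3 + rnorm(M, sd = 0.3), f2 = rnorm(M))
    tab <- feature_table(cbind(df, class = y))
    if (rank_svm_rfe(tab)$rank[1] == 1L) hit <- hit + 1L
  }
  expect_gte(hit, 19L)

  # step = p: one elimination round, equal to the one-shot w^2 ordering
  tab <- small_signal_table(M = 150, p = 8, seed = 3)
  r_one <- rank_svm_rfe(tab, step = 8)
  X <- scale(as.matrix(tab[feature_names(tab)]))
  fit <- e1071::svm(X, tab$class, kernel = "linear", cost = 1, scale = FALSE)
  w2 <- as.vector(t(fit$coefs) %*% fit$SV)^2
  expect_equal(order(r_one$rank), order(-w2))
})

test_that("a duplicated informative column is redundant for prediction", {
  set.seed(11)
  M <- 200
  x1 <- rnorm(M)
  y <- rbinom(M, 1, plogis(2 * x1))
  df <- data.frame(a = x1, dup = x1, n1 = rnorm(M), n2 = rnorm(M))
  tab <- feature_table(cbind(df, class = y))
  r <- rank_svm_rfe(tab)
  keep_best <- r$feature[r$rank == 1]
  other_copy <- setdiff(c("a", "dup"), keep_best)
  expect_true(all(c("a", "dup") %in% r$feature))
  spec <- classifier_spec("logistic")
  cv_with <- crossval_auc(tab, c(keep_best, "n1", "n2"), spec, folds = 5)
  cv_other <- crossval_auc(tab, c(other_copy, "n1", "n2"), spec, folds = 5)
  expect_lt(abs(cv_with$mean_auc - cv_other$mean_auc),
            cv_with$sd_auc + cv_other$sd_auc)
})

test_that("random-forest ranking is seeded and finds planted signal", {
  hit <- 0L
  no_worse <- 0L
  for (s in 1:20) {
    set.seed(s)
    M <- 500
    y <- rbinom(M, 1, 0.5)
    df <- data.frame(sig = y * 1 + rnorm(M, sd = 0.6),
                     matrix(rnorm(M * 6), M, 6))
    tab <- feature_table(cbind(df, class = y))
    r500 <- rank_rf(tab, n_trees = 500, seed = s)
    r1 <- rank_rf(tab, n_trees = 1, seed = s)
    if (r500$rank[r500$feature == "sig"] == 1L) hit <- hit + 1L
    if (r500$rank[r500$feature == "sig"] <= r1$rank[r1$feature == "sig"]) {
      no_worse <- no_worse + 1L
    }
  }
  expect_gte(hit, 19L)
  expect_gte(no_worse, 18L)

  tab <- small_signal_table(M = 100, p = 5, seed = 2)
  expect_identical(rank_rf(tab, seed = 42)$rank, rank_rf(tab, seed = 42)$rank)
})

test_that("the AUC-guided wrapper eliminates the separating feature last", {
  set.seed(5)
  M <- 90
  y <- rep(0:1, each = M / 2)
  df <- data.frame(sep = y + rnorm(M, sd = 0.05), n1 = rnorm(M), n2 = rnorm(M))
  tab <- feature_table(cbind(df, class = y))
  r <- rank_wrapper(tab, base = "logistic", folds = 3, seed = 1)
  expect_equal(r$rank[r$feature == "sep"], 1L)
  r_svm <- rank_wrapper(tab, base = "svm", folds = 3, seed = 1)
  expect_equal(r_svm$rank[r_svm$feature == "sep"], 1L)

  # single feature: no fit needed
  one <- feature_table(data.frame(f = rnorm(20), class = rep(0:1, 10)))
  expect_equal(rank_wrapper(one, base = "logistic")$rank, 1L)
})

test_that("wrappers on pure noise are unstable across subsamples", {
  set.seed(21)
  M <- 120
  df <- data.frame(matrix(rnorm(M * 15), M, 15))
  tab <- feature_table(cbind(df, class = rbinom(M, 1, 0.5)))
  s1 <- subsample_table(tab, 0.7, seed = 1)
  s2 <- subsample_table(tab, 0.7, seed = 2)
  r1 <- rank_wrapper(s1, base = "logistic", folds = 3, max_fits = 2000)
  r2 <- rank_wrapper(s2, base = "logistic", folds = 3, max_fits = 2000)
  ji <- jaccard_similarity(top_k(r1, 10), top_k(r2, 10))
  expect_lt(ji, 1)
})

test_that("the K-run protocol yields seeded permutation columns", {
  tab <- small_signal_table(M = 100, p = 7, seed = 4)
  A <- run_protocol(tab, "pearson", K = 7, fraction = 0.7, seed = 3)
  runs <- as.matrix(A[grep("^run_", names(A))])
  expect_equal(ncol(runs), 7)
  for (j in 1:7) expect_setequal(runs[, j], 1:7)
  A2 <- run_protocol(tab, "pearson", K = 7, fraction = 0.7, seed = 3)
  expect_identical(as.data.frame(A), as.data.frame(A2))

  # fraction 1 with a deterministic ranker: no resampling variance
  Af <- run_protocol(tab, "pearson", K = 3, fraction = 1, seed = 1)
  rf_ <- as.matrix(Af[grep("^run_", names(Af))])
  expect_true(all(rf_[, 1] == rf_[, 2] & rf_[, 2] == rf_[, 3]))

  A2r <- run_protocol(tab, "pearson", K = 2, fraction = 0.7, seed = 1)
  rep2 <- average_pairwise_stability(A2r, "spearman")
  expect_equal(nrow(rep2$pairwise), 1L)
})

test_that("rank aggregation averages per feature with documented tie-breaks", {
  m <- cbind(c(1, 2, 3), c(1, 2, 3))
  rownames(m) <- c("a", "b", "c")
  agg <- aggregate_rankings(fake_rank_matrix(m), "mean")
  expect_equal(agg$rank, c(1L, 2L, 3L))
  expect_equal(agg$aggregate, c(1, 2, 3))

  m2 <- cbind(c(1, 2), c(2, 1))
  rownames(m2) <- c("a", "b")
  agg2 <- aggregate_rankings(fake_rank_matrix(m2), "mean")
  expect_equal(agg2$rank, c(1L, 2L)) # tie -> feature order

  m3 <- cbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3))
  rownames(m3) <- c("a", "b", "c")
  agg3 <- aggregate_rankings(fake_rank_matrix(m3), "median")
  expect_equal(agg3$aggregate, c(1, 2, 3))
  expect_equal(agg3$rank, c(1L, 2L, 3L))
})

test_that("top-k selection reads straight off the ranking", {
  r <- scores_to_ranking(c(a = 0.2, b = 0.9, c = 0.1)) # ranks (2,1,3)
  expect_equal(top_k(r, 2)$selected, c(1L, 1L, 0L))
  expect_equal(sum(top_k(r, 1)$selected), 1)
  expect_equal(top_k(r, 1)$feature[top_k(r, 1)$selected == 1], "b")
  expect_equal(sum(top_k(r, 3)$selected), 3)
  expect_error(top_k(r, 0), "k must")
  expect_error(top_k(r, 4), "k must")
})

test_that("deterministic rankers are column-order and scale invariant", {
  tab <- small_signal_table(M = 120, p = 6, seed = 9)
  perm <- c(4, 1, 6, 2, 5, 3)
  df <- as.data.frame(tab)[c("sample_id", "class", sprintf("f%d", perm))]
  tabp <- feature_table(df)
  for (ranker in list(rank_pearson,
                      function(x) rank_relief(x, n_neighbors = 5),
                      rank_svm_rfe)) {
    r <- ranker(tab)
    rp <- ranker(tabp)
    expect_equal(
      r$rank[match(rp$feature, r$feature)], rp$rank,
      tolerance = 0
    )
  }
  # affine rescaling of a continuous feature
  tabs <- tab
  tabs$f2 <- tabs$f2 * 40 - 7
  expect_identical(rank_pearson(tab)$rank, rank_pearson(tabs)$rank)
  expect_identical(rank_svm_rfe(tab)$rank, rank_svm_rfe(tabs)$rank)
})
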