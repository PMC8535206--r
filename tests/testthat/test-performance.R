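test_that("cross-validated AUC is calibrated on null and separable data", {
  # permutation null: mean CV AUC near 1/2
  means <- vapply(1:5, function(s) {
    set.seed(s)
    M <- 300
    df <- data.frame(matrix(rnorm(M * 10), M, 10))
    tab <- feature_table(cbind(df, class = rbinom(M, 1, 0.5)))
    crossval_auc(tab, NULL, classifier_spec("logistic"), folds = 7,
                 seed = s)$mean_auc
  }, numeric(1))
  expect_true(mean(means) >= 0.45 && mean(means) <= 0.55)

  # perfectly separating feature
  set.seed(1)
  y <- rep(0:1, each = 40)
  tab <- feature_table(data.frame(sep = y * 10 + rnorm(80, sd = 0.01),
                                  noise = rnorm(80), class = y))
  cv <- crossval_auc(tab, NULL, classifier_spec("logistic"), folds = 5)
  expect_gte(cv$mean_auc, 0.99)
})

test_that("stratified folds balance sizes and class ratios", {
  tab <- default_table(seed = 1)
  fold_of <- rankstab:::make_folds(tab$class, 7, seed = 3)
  sizes <- table(fold_of)
  expect_lte(max(sizes) - min(sizes), 1)
  case_counts <- table(fold_of[tab$class == "case"])
  expect_lte(max(case_counts) - min(case_counts), 1)
})

test_that("unknown subset features fail by name", {
  tab <- small_signal_table(M = 60, p = 4)
  expect_error(crossval_auc(tab, c("f1", "ghost"), classifier_spec("logistic")),
               "ghost")
})

test_that("the internal AUC is monotone-transform invariant and matches pROC", {
  set.seed(2)
  y <- factor(sample(c("control", "case"), 100, TRUE),
              levels = c("control", "case"))
  s <- rnorm(100)
  a0 <- rankstab:::auc_case(y, s)
  expect_equal(rankstab:::auc_case(y, exp(s)), a0, tolerance = 1e-12)
  expect_equal(rankstab:::auc_case(y, 3 * s - 10), a0, tolerance = 1e-12)
  expect_equal(a0, oracle_auc(as.numeric(y == "case"), s), tolerance = 1e-12)
  expect_equal(a0, as.numeric(pROC::auc(response = y, predictor = s,
                                        levels = c("control", "case"),
                                        direction = "<", quiet = TRUE)),
               tolerance = 1e-12)
})

test_that("train-fold-only standardization does not leak held-out labels", {
  set.seed(4)
  M <- 210
  y <- rbinom(M, 1, 0.5)
  df <- data.frame(matrix(rnorm(M * 5), M, 5))
  base_tab <- feature_table(cbind(df, class = y))
  seed <- 11
  folds <- 7
  base_auc <- crossval_auc(base_tab, NULL, classifier_spec("logistic"),
                           folds = folds, seed = seed)$mean_auc
  # canary: equals the label exactly on fold-1 rows, pure noise elsewhere;
  # a leak-free pipeline cannot exploit it when fold 1 is held out
  fold_of <- rankstab:::make_folds(base_tab$class, folds, seed = seed)
  canary <- rnorm(M)
  canary[fold_of == 1] <- y[fold_of == 1]
  df2 <- cbind(df, canary = canary)
  tab2 <- feature_table(cbind(df2, class = y))
  auc2 <- crossval_auc(tab2, NULL, classifier_spec("logistic"),
                       folds = folds, seed = seed)$mean_auc
  expect_lte(auc2 - base_auc, 0.05)
})

test_that("AUC-vs-cardinality curves nest and reproduce the full baseline", {
  tab <- small_signal_table(M = 150, p = 10, seed = 5)
  r <- rank_pearson(tab)
  spec <- classifier_spec("logistic")
  curve <- performance_vs_cardinality(tab, r, spec, ks = c(1, 3, 5, 10),
                                      folds = 5, seed = 7)
  expect_equal(nrow(curve), 4L)
  expect_true(all(curve$mean_auc >= 0 & curve$mean_auc <= 1))
  full <- crossval_auc(tab, NULL, spec, folds = 5, seed = 7)
  expect_identical(curve$mean_auc[curve$k == 10], full$mean_auc)
  expect_identical(curve$sd_auc[curve$k == 10], full$sd_auc)

  const <- feature_table(data.frame(f1 = rnorm(20), class = rep(1, 20)))
  expect_error(performance_vs_cardinality(const, scores_to_ranking(c(f1 = 1)),
                                          spec, folds = 2),
               "both classes")
})

test_that("pruning an informative ranking beats the full set on planted data", {
  tab <- small_signal_table(M = 200, p = 20, seed = 31, beta = 1.5)
  r <- rank_pearson(tab)
  spec <- classifier_spec("logistic")
  curve <- performance_vs_cardinality(tab, r, spec, ks = c(2, 5, 10, 20),
                                      folds = 5, seed = 3)
  expect_gte(max(curve$mean_auc[curve$k < 20]),
             curve$mean_auc[curve$k == 20])
})

test_that("best-subset reports respect caps, ordering and ties", {
  curves <- tibble::tibble(
    ranker = "toy", classifier = rep(c("lr", "svm"), each = 5),
    k = rep(c(10, 20, 40, 70, 100), 2),
    mean_auc = c(0.58, 0.62, 0.60, 0.59, 0.57,
                 0.55, 0.62, 0.62, 0.56, 0.55),
    sd_auc = 0.02
  )
  rep3 <- best_subsets_report(curves, caps = c(30, 60, 90), top_n = 3)
  best_lr <- rep3[rep3$classifier == "lr", ]
  # optimum below every cap: the best row is identical across caps
  expect_equal(best_lr$k[best_lr$cap == 30][1], 20)
  expect_equal(best_lr$k[best_lr$cap == 60][1], 20)
  expect_equal(best_lr$k[best_lr$cap == 90][1], 20)
  expect_true(all(rep3$k[rep3$cap == 30] <= 30))
  # AUC tie at k = 20 and k = 40 for svm: smaller k wins
  best_svm <- rep3[rep3$classifier == "svm" & rep3$cap == 60, ]
  expect_equal(best_svm$k[1], 20)
  rep1 <- best_subsets_report(curves, caps = c(30, 60), top_n = 1)
  expect_equal(nrow(rep1), 4L) # 2 classifiers x 2 caps
})

test_that("full baselines cover every classifier deterministically", {
  tab <- generate_dataset(small_cohort_config(seed = 3, n_cases = 120,
                                              n_controls = 120))
  specs <- list(
    logistic = classifier_spec("logistic"),
    knn = classifier_spec("knn", k = 11),
    svm_rbf = classifier_spec("svm_rbf"),
    boosted_stumps = classifier_spec("boosted_stumps", n_estimators = 40),
    mlp = classifier_spec("mlp", hidden = 10, max_iter = 200, seed = 5)
  )
  b1 <- full_baseline(tab, specs, folds = 5, seed = 2)
  expect_equal(nrow(b1), 5L)
  expect_setequal(b1$classifier,
                  c("logistic", "knn", "svm_rbf", "boosted_stumps", "mlp"))
  expect_true(all(b1$mean_auc > 0.4 & b1$mean_auc < 0.9))
  b2 <- full_baseline(tab, specs, folds = 5, seed = 2)
  expect_identical(b1, b2)
})

test_that("feature-set comparison resolves names and set algebra", {
  set.seed(6)
  feats <- c("Age", "BMI", "Smoker (ever)", "rs123", "rs456", "Iron")
  M <- 80
  df <- as.data.frame(matrix(rnorm(M * 6), M, 6))
  names(df) <- feats
  tab <- feature_table(cbind(df, class = rbinom(M, 1, 0.5)))
  sets <- list(experts = c("Age", "Smoker", "RS-123"),
               auto = c("Age", "BMI", "rs456", "Iron"))
  out <- compare_feature_sets(
    tab, sets, specs = list(lr = classifier_spec("logistic")), folds = 3,
    seed = 1, name_map = c("Smoker" = "Smoker (ever)")
  )
  expect_equal(out$cardinality[out$feature_set == "experts"], 3L)
  expect_equal(out$cardinality[out$feature_set == "union"], 6L)
  expect_equal(out$cardinality[out$feature_set == "intersection"], 1L)
  # A with A: union and intersection both equal A
  idem <- compare_feature_sets(
    tab, list(a = sets$auto, b = sets$auto),
    specs = list(lr = classifier_spec("logistic")), folds = 3, seed = 1
  )
  expect_equal(idem$cardinality, rep(4L, 4))
  expect_error(
    compare_feature_sets(tab, list(bad = c("Age", "ghost")),
                         specs = list(lr = classifier_spec("logistic"))),
    "ghost"
  )
})
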