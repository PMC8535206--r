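#' Convert relevance scores to a ranking
#'
#' Higher score means more relevant; rank 1 is the most relevant feature.
#' Ties are broken by ascending feature position (stable and deterministic),
#' so equal-scored features keep their input order.
#'
#' @param scores numeric vector of finite relevance scores.
#' @param features feature names aligned with `scores`; taken from
#'   `names(scores)` when omitted.
#' @param method optional tag recorded on the result.
#' @return a `feature_ranking` tibble with columns `feature`, `score`,
#'   `rank` (a permutation of `1..p`).
#' @export
#' @examples
#' scores_to_ranking(c(a = 0.9, b = 0.1, c = 0.5))
scores_to_ranking <- function(scores, features = NULL, method = NULL) {
  features <- features %||% names(scores)
  if (is.null(features)) features <- sprintf("f%d", seq_along(scores))
  if (length(features) != length(scores)) {
    abort("features and scores lengths differ")
  }
  bad <- which(!is.finite(scores))
  if (length(bad) > 0) {
    abort(sprintf("non-finite score for feature '%s'", features[bad[1]]))
  }
  p <- length(scores)
  ord <- order(-scores, seq_len(p))
  rk <- integer(p)
  rk[ord] <- seq_len(p)
  out <- tibble(feature = features, score = as.numeric(scores), rank = rk)
  attr(out, "method") <- method
  class(out) <- c("feature_ranking", class(out))
  out
}

# accept a feature_ranking tibble or a bare rank permutation
ranking_ranks <- function(r) {
  if (inherits(r, "feature_ranking") ||
      (is.data.frame(r) && all(c("feature", "rank") %in% names(r)))) {
    setNames(as.integer(r$rank), r$feature)
  } else {
    rk <- as.integer(r)
    setNames(rk, names(r) %||% sprintf("f%d", seq_along(rk)))
  }
}

assert_permutation <- function(rk) {
  if (!identical(sort(unname(rk)), seq_along(rk))) {
    abort("ranks must be a permutation of 1..p")
  }
}

check_two_classes <- function(x) {
  if (length(unique(x$class)) < 2) {
    abort("both classes must be present in the table")
  }
}

#' Rank features by absolute Pearson correlation with the class label
#'
#' The point-biserial form: each feature is correlated with the 0/1 label
#' and ranked by `|r|`. Zero-variance features score 0 and fall to the
#' bottom. Scale-invariant by construction.
#'
#' @param x a `feature_table`.
#' @return a `feature_ranking`.
#' @export
rank_pearson <- function(x) {
  check_two_classes(x)
  X <- feature_matrix(x)
  y <- as.numeric(x$class == "case")
  s <- suppressWarnings(abs(as.vector(cor(X, y))))
  s[!is.finite(s)] <- 0
  scores_to_ranking(s, colnames(X), method = "pearson")
}

#' Rank features with ReliefF
#'
#' Instance-based feature weighting: for each (sampled) instance, the
#' `n_neighbors` nearest same-class neighbours ("hits") and nearest
#' other-class neighbours ("misses") are found under a range-normalized
#' Manhattan distance; a feature's weight decreases by its mean value
#' difference to hits and increases by its mean difference to misses,
#' normalized by the number of sampled instances. Binary features contribute
#' 0/1 mismatch differences (which coincides with the normalized Manhattan
#' difference); genotypes enter on the additive 0/1/2 scale.
#'
#' @param x a `feature_table`.
#' @param n_neighbors neighbours per class (default 10, the common choice).
#' @param n_sampled number of instances to sample as anchors; `NULL` uses
#'   every instance (deterministic).
#' @param seed seed for anchor sampling (only used when `n_sampled` is set).
#' @return a `feature_ranking`.
#' @export
rank_relief <- function(x, n_neighbors = 10, n_sampled = NULL, seed = 1) {
  check_two_classes(x)
  X <- feature_matrix(x)
  y <- x$class
  M <- nrow(X)
  cls_n <- table(y)
  if (any(cls_n < n_neighbors + 1)) {
    abort(sprintf(
      "each class needs at least n_neighbors + 1 = %d members (have %d, %d)",
      n_neighbors + 1, cls_n[1], cls_n[2]
    ))
  }
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  Xn <- sweep(X, 2, rng, "/")
  Dm <- as.matrix(dist(Xn, method = "manhattan"))
  anchors <- seq_len(M)
  if (!is.null(n_sampled) && n_sampled < M) {
    set.seed(seed)
    anchors <- sample(M, n_sampled)
  }
  W <- numeric(ncol(X))
  for (i in anchors) {
    same <- which(y == y[i])
    same <- same[same != i]
    diff_cl <- which(y != y[i])
    hits <- same[order(Dm[i, same])][seq_len(n_neighbors)]
    misses <- diff_cl[order(Dm[i, diff_cl])][seq_len(n_neighbors)]
    dh <- abs(sweep(Xn[hits, , drop = FALSE], 2, Xn[i, ], "-"))
    dm <- abs(sweep(Xn[misses, , drop = FALSE], 2, Xn[i, ], "-"))
    W <- W + (colSums(dm) - colSums(dh)) / n_neighbors
  }
  W <- W / length(anchors)
  scores_to_ranking(W, colnames(X), method = "relief")
}

#' Rank features by SVM recursive feature elimination
#'
#' Fits a soft-margin linear SVM (cost `C = 1`) on the surviving features,
#' scores each feature by its squared weight \eqn{w_j^2}, removes the lowest
#' scoring batch and repeats until no feature remains. Ranks are the reverse
#' elimination order (last survivor = rank 1); features removed in the same
#' batch are ordered by their within-batch importance. Features are
#' standardized internally, so the ranking is invariant to affine rescaling.
#'
#' @param x a `feature_table`.
#' @param step features removed per round: an integer count, or a fraction
#'   in (0, 1) of the surviving set (at least one). `step = 0.5`, the usual
#'   halving schedule, cuts cost from p to about log2(p) fits for wide
#'   tables.
#' @param cost soft-margin cost of the linear SVM.
#' @return a `feature_ranking` (scores are the negated elimination ranks).
#' @export
rank_svm_rfe <- function(x, step = 1, cost = 1) {
  check_two_classes(x)
  X <- feature_matrix(x)
  st <- fit_standardizer(X)
  X <- apply_standardizer(X, st)
  y <- x$class
  p <- ncol(X)
  surviving <- seq_len(p)
  elim_rank <- integer(p) # final rank per feature
  next_worst <- p
  while (length(surviving) > 1) {
    fit <- tryCatch(
      e1071::svm(X[, surviving, drop = FALSE], y, kernel = "linear",
                 cost = cost, scale = FALSE),
      error = function(e) {
        abort(sprintf(
          "linear SVM failed with %d surviving features: %s",
          length(surviving), conditionMessage(e)
        ))
      }
    )
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    imp <- w^2
    n_rem <- if (step >= 1) min(as.integer(step), length(surviving) - 1L)
             else max(1L, min(floor(step * length(surviving)),
                              length(surviving) - 1L))
    ord <- order(imp, seq_along(imp)) # least important first
    drop_local <- ord[seq_len(n_rem)]
    # least important of the batch gets the worst remaining rank
    for (d in drop_local) {
      elim_rank[surviving[d]] <- next_worst
      next_worst <- next_worst - 1L
    }
    surviving <- surviving[-drop_local]
  }
  elim_rank[surviving] <- 1L
  scores_to_ranking(-elim_rank, colnames(X), method = "svm_rfe")
}

#' Rank features by random-forest impurity importance
#'
#' An ensemble of randomized classification trees (bootstrap rows, random
#' feature subsets at each split); the score is the mean decrease in node
#' impurity (Gini) attributable to each feature.
#'
#' @param x a `feature_table`.
#' @param n_trees ensemble size (default 500).
#' @param seed forest seed; identical seeds give identical rankings.
#' @param ... passed to [ranger::ranger()].
#' @return a `feature_ranking`.
#' @export
rank_rf <- function(x, n_trees = 500, seed = 1, ...) {
  check_two_classes(x)
  X <- feature_matrix(x)
  fit <- ranger::ranger(
    x = as.data.frame(X), y = x$class, num.trees = n_trees,
    importance = "impurity", num.threads = 1, seed = seed, ...
  )
  scores_to_ranking(fit$variable.importance[colnames(X)], colnames(X),
                    method = "rf")
}

#' Rank features by AUC-guided sequential backward elimination
#'
#' A wrapper: at each step the feature whose removal yields the highest
#' cross-validated AUC of the base classifier is dropped; ranks are the
#' reverse removal order. The exhaustive search costs O(p^2) model fits, so
#' a `max_fits` budget caps it: once exceeded, the remainder of the
#' elimination falls back to dropping the smallest-|coefficient| feature of
#' a single fit per round (a message reports the switch, and the result
#' carries a `budget_exceeded` attribute).
#'
#' @param x a `feature_table`.
#' @param base base classifier, `"logistic"` or `"svm"` (linear, cost 1).
#' @param folds cross-validation folds for the guiding AUC.
#' @param seed fold seed.
#' @param max_fits budget of individual fold-level model fits for the greedy
#'   phase.
#' @return a `feature_ranking`.
#' @export
rank_wrapper <- function(x, base = c("logistic", "svm"), folds = 7, seed = 1,
                         max_fits = 5000) {
  base <- match.arg(base)
  check_two_classes(x)
  if (folds < 2) abort("folds must be >= 2")
  X <- feature_matrix(x)
  st <- fit_standardizer(X)
  X <- apply_standardizer(X, st)
  y <- x$class
  p <- ncol(X)
  if (p == 1) {
    return(scores_to_ranking(setNames(0, colnames(X)), method = paste0(base, "_wrapper")))
  }
  fold_of <- make_folds(y, folds, seed)

  fit_fun <- switch(base,
    logistic = function(Xtr, ytr, Xte) {
      df <- data.frame(y = ytr, Xtr)
      fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      predict(fit, newdata = data.frame(Xte), type = "link")
    },
    svm = function(Xtr, ytr, Xte) {
      fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = 1, scale = FALSE)
      dv <- drop(attr(predict(fit, Xte, decision.values = TRUE),
                      "decision.values"))
      # libsvm orients decision values toward the first training label
      if (fit$labels[1] == which(levels(ytr) == "case")) dv else -dv
    }
  )
  coef_fun <- switch(base,
    logistic = function(Xs, ys) {
      df <- data.frame(y = ys, Xs)
      fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      cf <- coef(fit)[-1]
      cf[is.na(cf)] <- 0
      abs(cf)
    },
    svm = function(Xs, ys) {
      fit <- e1071::svm(Xs, ys, kernel = "linear", cost = 1, scale = FALSE)
      abs(as.vector(t(fit$coefs) %*% fit$SV))
    }
  )

  cv_auc_of <- function(cols) {
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold_of != f
      sc <- fit_fun(X[tr, cols, drop = FALSE], y[tr], X[!tr, cols, drop = FALSE])
      auc_case(y[!tr], sc)
    }, numeric(1))
    mean(aucs)
  }

  surviving <- seq_len(p)
  elim_rank <- integer(p)
  next_worst <- p
  fits_used <- 0
  budget_hit <- FALSE
  while (length(surviving) > 1) {
    if (!budget_hit &&
        fits_used + length(surviving) * folds > max_fits) {
      budget_hit <- TRUE
      inform(sprintf(
        "wrapper fit budget (%d) reached with %d features left; switching to coefficient-based elimination",
        max_fits, length(surviving)
      ))
    }
    if (!budget_hit) {
      aucs <- vapply(seq_along(surviving), function(j) {
        cv_auc_of(surviving[-j])
      }, numeric(1))
      fits_used <- fits_used + length(surviving) * folds
      drop_j <- which.max(aucs) # ties: first (lowest feature index)
    } else {
      cf <- coef_fun(X[, surviving, drop = FALSE], y)
      drop_j <- which.min(cf)
    }
    elim_rank[surviving[drop_j]] <- next_worst
    next_worst <- next_worst - 1L
    surviving <- surviving[-drop_j]
  }
  elim_rank[surviving] <- 1L
  out <- scores_to_ranking(-elim_rank, colnames(X),
                           method = paste0(base, "_wrapper"))
  attr(out, "budget_exceeded") <- budget_hit
  out
}

# Wilcoxon/rank form of the ROC AUC for case scores (ties share ranks)
auc_case <- function(y, score) {
  pos <- score[y == "case"]
  neg <- score[y == "control"]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("AUC undefined: a class is absent")
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

ranker_registry <- function() {
  list(
    pearson = rank_pearson,
    relief = rank_relief,
    svm_rfe = rank_svm_rfe,
    rf = rank_rf,
    svm_wrapper = function(x, ...) rank_wrapper(x, base = "svm", ...),
    lr_wrapper = function(x, ...) rank_wrapper(x, base = "logistic", ...)
  )
}

#' Run the K-run subsampling ranking protocol
#'
#' Draws `K` random subsamples of `fraction` of the rows (per-run seeds
#' derived from the master seed), ranks the features on each, and assembles
#' the p-by-K rank matrix whose column j is the ranking from run j.
#'
#' @param x a `feature_table`.
#' @param method ranker name (`"pearson"`, `"relief"`, `"svm_rfe"`, `"rf"`,
#'   `"svm_wrapper"`, `"lr_wrapper"`) or a function `feature_table ->
#'   feature_ranking`.
#' @param K number of runs (default 7).
#' @param fraction row fraction per run (default 0.7).
#' @param seed master seed; run j uses `derive_seed(seed, stage, j)`.
#' @param ... passed to the ranker.
#' @return a `rank_matrix` tibble: column `feature` plus `run_1..run_K`,
#'   each run column a permutation of `1..p`.
#' @export
run_protocol <- function(x, method, K = 7, fraction = 0.7, seed = 1, ...) {
  if (K < 2) abort("K must be >= 2")
  method_name <- if (is.character(method)) method else "custom"
  ranker <- if (is.character(method)) {
    reg <- ranker_registry()
    if (!method %in% names(reg)) {
      abort(sprintf("unknown ranker '%s'; available: %s",
                    method, paste(names(reg), collapse = ", ")))
    }
    reg[[method]]
  } else {
    match.fun(method)
  }
  stage <- paste0("protocol_", method_name)
  seeds <- vapply(seq_len(K), function(j) derive_seed(seed, stage, j),
                  integer(1))
  runs <- map(seq_len(K), function(j) {
    sub <- subsample_table(x, fraction, seed = seeds[j])
    extra <- list(...)
    extra <- extra[!vapply(extra, is.null, logical(1))]
    # seeded rankers get a per-run seed unless the caller pinned one
    if (!"seed" %in% names(extra) &&
        method_name %in% c("rf", "svm_wrapper", "lr_wrapper", "relief")) {
      extra$seed <- derive_seed(seed, paste0(stage, "_fit"), j)
    }
    r <- do.call(ranker, c(list(sub), extra))
    rk <- ranking_ranks(r)
    assert_permutation(rk)
    rk[feature_names(x)]
  })
  out <- tibble(feature = feature_names(x))
  for (j in seq_len(K)) out[[sprintf("run_%d", j)]] <- as.integer(runs[[j]])
  attr(out, "method") <- method_name
  attr(out, "run_seeds") <- seeds
  class(out) <- c("rank_matrix", class(out))
  out
}

# internal: p x K integer matrix from a rank_matrix tibble
rank_matrix_entries <- function(A) {
  runs <- grep("^run_", names(A), value = TRUE)
  if (length(runs) == 0) abort("rank matrix has no run columns")
  m <- as.matrix(A[runs])
  rownames(m) <- A$feature
  storage.mode(m) <- "integer"
  apply(m, 2, assert_permutation)
  m
}

#' Aggregate a rank matrix into a consensus ranking
#'
#' Per-feature mean (or median) rank across the K runs, converted to a
#' permutation (lower aggregate = more relevant, ties by feature position).
#' The raw aggregate — the "median rank position" of partition reports — is
#' kept in the `aggregate` column.
#'
#' @param A a `rank_matrix`.
#' @param method `"mean"` (default) or `"median"`; the median resists the
#'   extreme rank excursions that single unstable runs produce.
#' @return a `feature_ranking` with an extra `aggregate` column.
#' @export
aggregate_rankings <- function(A, method = c("mean", "median")) {
  method <- match.arg(method)
  m <- rank_matrix_entries(A)
  agg <- switch(method,
    mean = rowMeans(m),
    median = apply(m, 1, median)
  )
  out <- scores_to_ranking(-agg, rownames(m),
                           method = paste0(attr(A, "method") %||% "agg", "_", method))
  out$aggregate <- as.numeric(agg)
  out$score <- NULL
  out
}

#' Top-k selection vector of a ranking
#'
#' @param r a `feature_ranking` (or named rank permutation).
#' @param k cardinality, `1 <= k <= p`.
#' @return a `feature_selection` tibble with columns `feature` and
#'   `selected` (0/1, summing to `k`).
#' @export
top_k <- function(r, k) {
  rk <- ranking_ranks(r)
  p <- length(rk)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > p) {
    abort(sprintf("k must be in [1, %d]", p))
  }
  out <- tibble(feature = names(rk), selected = as.integer(rk <= k))
  attr(out, "k") <- as.integer(k)
  class(out) <- c("feature_selection", class(out))
  out
}

selection_set <- function(s) {
  if (inherits(s, "feature_selection") ||
      (is.data.frame(s) && all(c("feature", "selected") %in% names(s)))) {
    s$feature[s$selected == 1]
  } else if (is.character(s)) {
    s
  } else {
    abort("expected a feature_selection or character vector of names")
  }
}
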