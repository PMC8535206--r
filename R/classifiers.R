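#' Specify a classifier for AUC evaluation
#'
#' Five classifier families are supported, with defaults mirroring the
#' grid-search winners of the study protocol:
#'
#' * `logistic` — L2-penalised logistic regression, `C = 1` (ridge penalty
#'   `lambda = 1/(C * n)`), iteration cap 1000.
#' * `knn` — k-nearest neighbours, `k = 21`, Euclidean (Minkowski, order 2)
#'   distance on standardized inputs.
#' * `svm_rbf` — support vector machine with a radial-basis kernel trained
#'   by sequential minimal optimization; `C = 1`, kernel width
#'   `gamma = 1/(p * pooled variance)` of the (standardized) inputs.
#' * `boosted_stumps` — AdaBoost-SAMME over depth-1 decision stumps,
#'   learning rate 1, up to 500 estimators.
#' * `mlp` — single-hidden-layer perceptron, 200 logistic-sigmoid units,
#'   iteration cap 5000, small L2 weight decay.
#'
#' Tree-based classifiers skip standardization (scale-invariant); all
#' others standardize on the training fold only.
#'
#' @param classifier one of `"logistic"`, `"knn"`, `"svm_rbf"`,
#'   `"boosted_stumps"`, `"mlp"`. (The argument is named `classifier` rather
#'   than `kind` so that the knn hyperparameter `k` cannot partially match
#'   it.)
#' @param ... hyperparameter overrides (see Details above for names:
#'   `C`, `max_iter`, `k`, `gamma`, `n_estimators`, `learning_rate`,
#'   `hidden`, `decay`).
#' @param seed seed for stochastic fits (MLP initialisation).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(classifier = c("logistic", "knn", "svm_rbf",
                                           "boosted_stumps", "mlp"),
                            ..., seed = 1) {
  kind <- match.arg(classifier)
  defaults <- switch(kind,
    logistic = list(C = 1, max_iter = 1000, standardize = TRUE),
    knn = list(k = 21, standardize = TRUE),
    svm_rbf = list(C = 1, gamma = NULL, standardize = TRUE),
    boosted_stumps = list(n_estimators = 500, learning_rate = 1,
                          standardize = FALSE),
    mlp = list(hidden = 200, max_iter = 5000, decay = 1e-4,
               standardize = TRUE)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown hyperparameter for %s: %s", kind, unknown[1]))
  }
  structure(c(list(kind = kind, seed = as.integer(seed)),
              modifyList(defaults, over)),
            class = "classifier_spec")
}

#' Default specification for each of the five classifiers
#' @param seed shared seed for stochastic fits.
#' @return named list of `classifier_spec`s.
#' @export
default_classifier_specs <- function(seed = 1) {
  kinds <- c("logistic", "knn", "svm_rbf", "boosted_stumps", "mlp")
  setNames(lapply(kinds, classifier_spec, seed = seed), kinds)
}

# fit on training data, return a scoring closure for new data
fit_classifier <- function(spec, X, y) {
  set.seed(spec$seed)
  switch(spec$kind,
    logistic = fit_logistic(spec, X, y),
    knn = fit_knn(spec, X, y),
    svm_rbf = fit_svm_rbf(spec, X, y),
    boosted_stumps = fit_samme_stumps(spec, X, y),
    mlp = fit_mlp(spec, X, y)
  )
}

fit_logistic <- function(spec, X, y) {
  n <- nrow(X)
  if (ncol(X) >= 2) {
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = 1 / (spec$C * n), maxit = spec$max_iter,
                          standardize = FALSE)
    function(Xn) as.vector(predict(fit, Xn))
  } else {
    df <- data.frame(y = y, x1 = X[, 1])
    fit <- suppressWarnings(glm(y ~ x1, data = df, family = binomial()))
    function(Xn) predict(fit, newdata = data.frame(x1 = Xn[, 1]), type = "link")
  }
}

fit_knn <- function(spec, X, y) {
  k <- min(spec$k, nrow(X))
  fit <- caret::knn3(X, y, k = k)
  function(Xn) predict(fit, Xn, type = "prob")[, "case"]
}

fit_svm_rbf <- function(spec, X, y) {
  gamma <- spec$gamma %||% (1 / (ncol(X) * max(mean(apply(X, 2, var)),
                                               .Machine$double.eps)))
  fit <- e1071::svm(X, y, kernel = "radial", cost = spec$C, gamma = gamma,
                    scale = FALSE)
  # libsvm orients decision values toward the first label seen in training
  pos_first <- fit$labels[1] == which(levels(y) == "case")
  function(Xn) {
    dv <- drop(attr(predict(fit, Xn, decision.values = TRUE),
                    "decision.values"))
    if (pos_first) dv else -dv
  }
}

# AdaBoost-SAMME with depth-1 rpart stumps; for two classes SAMME reduces
# to discrete AdaBoost.M1. The score is the weighted vote margin for "case".
fit_samme_stumps <- function(spec, X, y) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- as.data.frame(X)
  yy <- factor(y, levels = c("control", "case"))
  stumps <- list()
  alphas <- numeric(0)
  for (t in seq_len(spec$n_estimators)) {
    fit <- rpart::rpart(
      yy ~ ., data = cbind(df, yy = yy), weights = w,
      method = "class",
      control = rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                                     minbucket = 1, xval = 0)
    )
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != yy))
    if (err <= 1e-10) { # perfect stump: dominate and stop
      stumps[[t]] <- fit
      alphas[t] <- 10
      break
    }
    if (err >= 0.5) break # no better than chance under current weights
    alpha <- spec$learning_rate * log((1 - err) / err)
    stumps[[t]] <- fit
    alphas[t] <- alpha
    w <- w * exp(alpha * (pred != yy))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) { # degenerate: constant score
    return(function(Xn) rep(0, nrow(Xn)))
  }
  function(Xn) {
    dfn <- as.data.frame(Xn)
    s <- numeric(nrow(dfn))
    for (t in seq_along(stumps)) {
      pr <- predict(stumps[[t]], dfn, type = "class")
      s <- s + alphas[t] * ifelse(pr == "case", 1, -1)
    }
    s
  }
}

fit_mlp <- function(spec, X, y) {
  target <- as.numeric(y == "case")
  nw <- (ncol(X) + 1) * spec$hidden + (spec$hidden + 1)
  fit <- nnet::nnet(X, target, size = spec$hidden, decay = spec$decay,
                    maxit = spec$max_iter, MaxNWts = nw + 10,
                    entropy = TRUE, trace = FALSE)
  function(Xn) as.vector(predict(fit, Xn))
}
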