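#' Cross-validated AUC of a classifier on a feature subset
#'
#' Stratified k-fold cross-validation: folds preserve the case/control ratio
#' to within one sample and overall fold sizes differ by at most one. Any
#' standardization is fitted on the training folds only and applied to the
#' held-out fold, so no information leaks from test rows. The per-fold ROC
#' AUC of the held-out case scores (positive class = `case`) is summarised
#' as mean and standard deviation.
#'
#' @param x a `feature_table`.
#' @param subset features to use: a character vector, a `feature_selection`,
#'   or `NULL` for all features.
#' @param spec a [classifier_spec()].
#' @param folds number of folds (default 7).
#' @param seed fold-assignment seed.
#' @return a `cv_auc` tibble (one row: `classifier`, `mean_auc`, `sd_auc`,
#'   `n_folds`) carrying the per-fold AUCs as attribute `fold_aucs`.
#' @export
crossval_auc <- function(x, subset = NULL, spec = classifier_spec("logistic"),
                         folds = 7, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (folds < 2) abort("folds must be >= 2")
  check_two_classes(x)
  feats <- if (is.null(subset)) feature_names(x) else selection_set(subset)
  unknown <- setdiff(feats, feature_names(x))
  if (length(unknown) > 0) {
    abort(sprintf("unknown feature(s) in subset: %s",
                  paste(unknown, collapse = ", ")))
  }
  X <- feature_matrix(x, feats)
  y <- x$class
  fold_of <- make_folds(y, folds, seed)
  fold_aucs <- vapply(seq_len(folds), function(f) {
    tr <- fold_of != f
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    if (isTRUE(spec$standardize)) {
      st <- fit_standardizer(Xtr)
      Xtr <- apply_standardizer(Xtr, st)
      Xte <- apply_standardizer(Xte, st)
    }
    score <- fit_classifier(spec, Xtr, y[tr])
    sc <- score(Xte)
    as.numeric(pROC::auc(response = y[!tr], predictor = sc,
                         levels = c("control", "case"), direction = "<",
                         quiet = TRUE))
  }, numeric(1))
  out <- tibble(classifier = spec$kind, mean_auc = mean(fold_aucs),
                sd_auc = sd(fold_aucs), n_folds = as.integer(folds))
  attr(out, "fold_aucs") <- fold_aucs
  class(out) <- c("cv_auc", class(out))
  out
}

#' AUC as a function of top-k cardinality
#'
#' Evaluates [crossval_auc()] on the nested top-k subsets of a ranking for
#' each cardinality in `ks`, under identical fold seeds — so the `k = p`
#' entry reproduces the full-set baseline bit for bit.
#'
#' @param x a `feature_table`.
#' @param ranking a `feature_ranking` over the table's features.
#' @param spec a [classifier_spec()].
#' @param ks cardinalities to evaluate (default `1..p`; a coarser grid is
#'   usually enough and proportionally cheaper).
#' @param folds,seed as in [crossval_auc()].
#' @return a `performance_curve` tibble: `ranker`, `classifier`, `k`,
#'   `mean_auc`, `sd_auc`.
#' @export
performance_vs_cardinality <- function(x, ranking, spec, ks = NULL,
                                       folds = 7, seed = 1) {
  rk <- ranking_ranks(ranking)
  if (!setequal(names(rk), feature_names(x))) {
    abort("ranking does not match the table's features")
  }
  check_two_classes(x)
  p <- length(rk)
  ks <- sort(unique(as.integer(ks %||% seq_len(p))))
  if (any(ks < 1 | ks > p)) abort(sprintf("ks must lie in [1, %d]", p))
  ranker <- attr(ranking, "method") %||% "ranking"
  rows <- map(ks, function(k) {
    sel <- names(rk)[rk <= k]
    cv <- crossval_auc(x, subset = sel, spec = spec, folds = folds,
                       seed = seed)
    tibble(ranker = ranker, classifier = spec$kind, k = k,
           mean_auc = cv$mean_auc, sd_auc = cv$sd_auc)
  })
  out <- bind_rows(rows)
  class(out) <- c("performance_curve", class(out))
  out
}

#' Best feature subsets per classifier under cardinality caps
#'
#' For each classifier and each cap, the `top_n` (k, ranker) entries with
#' `k <= cap`, sorted by mean AUC (descending) with ties going to the
#' smaller subset.
#'
#' @param curves one `performance_curve` or a list / row-bound tibble of
#'   them (columns `ranker`, `classifier`, `k`, `mean_auc`, `sd_auc`).
#' @param caps cardinality caps (default `c(30, 60, 90)`).
#' @param top_n rows reported per classifier and cap (default 3).
#' @return tibble `classifier`, `cap`, `k`, `ranker`, `mean_auc`, `sd_auc`.
#' @export
best_subsets_report <- function(curves, caps = c(30, 60, 90), top_n = 3) {
  if (inherits(curves, "performance_curve") || is.data.frame(curves)) {
    curves <- list(curves)
  }
  all_rows <- bind_rows(lapply(curves, as_tibble))
  if (nrow(all_rows) == 0) abort("no performance curves supplied")
  out <- map(caps, function(cap) {
    all_rows |>
      filter(.data$k <= cap) |>
      group_by(.data$classifier) |>
      arrange(desc(.data$mean_auc), .data$k, .by_group = TRUE) |>
      slice_head(n = top_n) |>
      ungroup() |>
      mutate(cap = cap)
  })
  bind_rows(out) |>
    select("classifier", "cap", "k", "ranker", "mean_auc", "sd_auc") |>
    arrange(.data$classifier, .data$cap)
}

#' Full-feature-set AUC baselines
#'
#' Cross-validated AUC of every supplied classifier on the complete feature
#' set — the no-selection reference row.
#'
#' @param x a `feature_table`.
#' @param specs named list of [classifier_spec()]s (default all five).
#' @param folds,seed as in [crossval_auc()].
#' @return tibble `classifier`, `mean_auc`, `sd_auc`, `n_folds`.
#' @export
full_baseline <- function(x, specs = default_classifier_specs(),
                          folds = 7, seed = 1) {
  bind_rows(lapply(specs, function(sp) {
    as_tibble(crossval_auc(x, NULL, sp, folds = folds, seed = seed))
  }))
}

#' Compare named feature sets across classifiers
#'
#' Evaluates each feature set (plus, optionally, the union and intersection
#' of all supplied sets) with each classifier, mirroring a
#' sets-by-classifiers AUC table. Set membership is resolved against the
#' table's features after name normalization.
#'
#' @param x a `feature_table`.
#' @param sets named list of character vectors of feature names.
#' @param specs named list of [classifier_spec()]s.
#' @param folds,seed as in [crossval_auc()].
#' @param include_derived add `union` and `intersection` rows when two or
#'   more sets are supplied (default TRUE).
#' @param name_map optional alias-to-canonical map applied by
#'   [normalize_feature_names()] before matching.
#' @return tibble `feature_set`, `cardinality`, then one `mean`/`sd` column
#'   pair per classifier.
#' @export
compare_feature_sets <- function(x, sets, specs = default_classifier_specs(),
                                 folds = 7, seed = 1, include_derived = TRUE,
                                 name_map = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets))) names(sets) <- sprintf("set_%d", seq_along(sets))
  table_feats <- feature_names(x)
  canon_table <- normalize_feature_names(table_feats, name_map)
  resolve <- function(members) {
    canon <- unique(normalize_feature_names(members, name_map))
    hit <- match(canon, canon_table)
    if (anyNA(hit)) {
      abort(sprintf("feature set members not found in table: %s",
                    paste(members[is.na(hit)], collapse = ", ")))
    }
    table_feats[hit]
  }
  resolved <- lapply(sets, resolve)
  if (include_derived && length(resolved) >= 2) {
    resolved$union <- Reduce(union, resolved)
    resolved$intersection <- Reduce(intersect, resolved[names(sets)])
  }
  rows <- imap(resolved, function(members, nm) {
    if (length(members) == 0) {
      abort(sprintf("feature set '%s' is empty after normalization", nm))
    }
    row <- tibble(feature_set = nm, cardinality = length(members))
    for (sp_name in names(specs)) {
      cv <- crossval_auc(x, members, specs[[sp_name]], folds = folds,
                         seed = seed)
      row[[paste0(sp_name, "_mean")]] <- cv$mean_auc
      row[[paste0(sp_name, "_sd")]] <- cv$sd_auc
    }
    row
  })
  bind_rows(rows)
}

#' Normalize feature names for set algebra
#'
#' Canonical form: lower case with all non-alphanumeric characters removed
#' (so `RS-71310379`, `rs71310379` and `Rs 71310379` coincide), after
#' applying an optional alias map (`c("Contraceptives" = "Oral
#' contraceptives")`). Aliases are matched on their own canonical form.
#'
#' @param x character vector of feature names.
#' @param map optional named character vector, alias -> canonical name.
#' @return character vector of canonical tokens.
#' @export
normalize_feature_names <- function(x, map = NULL) {
  canon <- function(v) gsub("[^a-z0-9]", "", tolower(v))
  out <- canon(x)
  if (!is.null(map)) {
    hit <- match(out, canon(names(map)))
    out[!is.na(hit)] <- canon(unname(map))[hit[!is.na(hit)]]
  }
  out
}

#' Read a newline-delimited feature set
#' @param path text file, one feature name per line (blank lines and `#`
#'   comments ignored).
#' @return character vector of names.
#' @export
read_feature_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a two-column alias map
#' @param path tab-separated file with columns `alias`, `canonical`.
#' @return named character vector suitable for `normalize_feature_names()`.
#' @export
read_name_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("alias", "canonical") %in% names(df)))
  setNames(df$canonical, df$alias)
}

#' @exportS3Method
tidy.performance_curve <- function(x, ...) as_tibble(x)

#' @exportS3Method
glance.performance_curve <- function(x, ...) {
  best <- x[which.max(x$mean_auc), ]
  tibble(ranker = best$ranker, classifier = best$classifier,
         best_k = best$k, best_auc = best$mean_auc,
         full_set_auc = x$mean_auc[which.max(x$k)], n_k = nrow(x))
}

#' @exportS3Method
tidy.cv_auc <- function(x, ...) {
  tibble(fold = seq_along(attr(x, "fold_aucs")), auc = attr(x, "fold_aucs"))
}

#' @exportS3Method
glance.cv_auc <- function(x, ...) as_tibble(x)
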