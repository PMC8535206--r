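# shared fixtures, all built in code at test time

# memoised default-config cohorts (generation is the expensive part)
.table_cache <- new.env(parent = emptyenv())
default_table <- function(seed = 1, config = NULL) {
  key <- paste0("t", seed, "_", if (is.null(config)) "default" else "custom")
  if (is.null(.table_cache[[key]])) {
    cfg <- config %||% generator_config(seed = seed)
    cfg$seed <- as.integer(seed)
    .table_cache[[key]] <- generate_dataset(cfg)
  }
  .table_cache[[key]]
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# small planted-signal table: one strongly informative feature among noise
small_signal_table <- function(M = 120, p = 6, seed = 1, beta = 2) {
  set.seed(seed)
  X <- matrix(rnorm(M * p), M, p, dimnames = list(NULL, sprintf("f%d", 1:p)))
  eta <- beta * X[, 1]
  y <- rbinom(M, 1, plogis(eta))
  feature_table(data.frame(X, class = y))
}

# deterministic toy table from explicit values
toy_table <- function(values, labels) {
  df <- as.data.frame(values)
  df$class <- labels
  feature_table(df)
}

# build a rank_matrix from an explicit p x K matrix of ranks
fake_rank_matrix <- function(m, method = "toy") {
  p <- nrow(m)
  out <- tibble::tibble(feature = rownames(m) %||% sprintf("f%d", 1:p))
  for (j in seq_len(ncol(m))) out[[sprintf("run_%d", j)]] <- as.integer(m[, j])
  attr(out, "method") <- method
  class(out) <- c("rank_matrix", class(out))
  out
}

# reduced generator for cheap end-to-end runs
small_cohort_config <- function(seed = 1, n_cases = 100, n_controls = 100,
                                with_menopause = TRUE) {
  generator_config(
    n_cases = n_cases, n_controls = n_controls,
    n_env = 12, n_snp = 10, n_other = 4,
    menopause_margins = if (with_menopause) {
      c(pre_cases = round(0.6 * n_cases), pre_controls = round(0.7 * n_controls),
        post_cases = n_cases - round(0.6 * n_cases),
        post_controls = n_controls - round(0.7 * n_controls))
    },
    seed = seed
  )
}

# independent Wilcoxon-statistic AUC oracle (mean over all case-control
# pairs, ties counted half)
oracle_auc <- function(y01, score) {
  pos <- score[y01 == 1]
  neg <- score[y01 == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
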