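#' @exportS3Method
tidy.feature_ranking <- function(x, ...) as_tibble(x)

#' @exportS3Method
tidy.rank_matrix <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(dplyr::starts_with("run_"), names_to = "run",
                        names_prefix = "run_", values_to = "rank") |>
    mutate(run = as.integer(.data$run))
}

#' @exportS3Method
glance.rank_matrix <- function(x, ...) {
  m <- rank_matrix_entries(x)
  sp <- average_pairwise_stability(x, "spearman")
  tibble(method = attr(x, "method") %||% NA_character_,
         p = nrow(m), K = ncol(m), spearman_stability = sp$mean)
}
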