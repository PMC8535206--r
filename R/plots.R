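#' @exportS3Method
autoplot.performance_curve <- function(object, ...) {
  full <- object$mean_auc[which.max(object$k)]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$mean_auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_auc - .data$sd_auc,
                                      ymax = .data$mean_auc + .data$sd_auc),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = full, linetype = "dashed") +
    ggplot2::labs(
      x = "top-k cardinality", y = "cross-validated AUC",
      title = sprintf("%s classifier, %s ranking",
                      object$classifier[1], object$ranker[1]),
      subtitle = "dashed line: full feature set"
    )
}

#' @exportS3Method
autoplot.mds_embedding <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$ranker)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "MDS 1", y = "MDS 2", colour = "ranker",
      title = "Ranking runs in dissimilarity space",
      subtitle = sprintf("normalized stress = %.4f", object$stress)
    )
}

#' Plot Jaccard stability curves for several rankers
#'
#' @param summary a [stability_summary()] tibble.
#' @return a ggplot: mean pairwise top-k Jaccard index against k, one line
#'   per ranker.
#' @export
plot_stability_curves <- function(summary) {
  long <- summary |>
    select("ranker", dplyr::starts_with("jaccard_k")) |>
    tidyr::pivot_longer(-"ranker", names_to = "k", names_prefix = "jaccard_k",
                        values_to = "mean_jaccard") |>
    mutate(k = as.integer(.data$k))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$mean_jaccard,
                                     colour = .data$ranker)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "top-k cardinality", y = "mean pairwise Jaccard index",
                  colour = "ranker", title = "Feature-selection stability")
}
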