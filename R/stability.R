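#' Spearman rank-correlation similarity of two full rankings
#'
#' The closed form for two permutations of `1..p`:
#' \deqn{SR(r, r') = 1 - \frac{6 \sum_i (r_i - r'_i)^2}{p (p^2 - 1)}}
#' 1 for identical rankings, -1 for exact reversals.
#'
#' @param r,r2 `feature_ranking`s or named rank permutations of equal length
#'   (aligned by feature name when names are present).
#' @return a number in \[-1, 1\].
#' @export
#' @examples
#' spearman_similarity(c(1, 2, 3), c(3, 2, 1)) # -1
spearman_similarity <- function(r, r2) {
  a <- ranking_ranks(r)
  b <- ranking_ranks(r2)
  if (length(a) != length(b)) abort("rankings have different lengths")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) abort("rankings cover different features")
    b <- b[names(a)]
  }
  assert_permutation(a)
  assert_permutation(b)
  p <- length(a)
  if (p < 2) abort("need at least two features")
  1 - 6 * sum((as.numeric(a) - as.numeric(b))^2) / (p * (p^2 - 1))
}

#' Jaccard similarity of two feature selections
#'
#' Intersection size over union size of the two selected sets.
#'
#' @param s,s2 `feature_selection`s (or character vectors of names) over the
#'   same universe.
#' @return a number in \[0, 1\].
#' @export
jaccard_similarity <- function(s, s2) {
  a <- selection_set(s)
  b <- selection_set(s2)
  if (length(a) == 0 && length(b) == 0) {
    abort("Jaccard undefined for two empty selections (k must be >= 1)")
  }
  length(intersect(a, b)) / length(union(a, b))
}

new_stability_report <- function(metric, pairwise, mean_value, k = NULL,
                                 curve = NULL, grand_mean = NULL,
                                 method = NULL) {
  structure(
    list(metric = metric, k = k, pairwise = pairwise, mean = mean_value,
         curve = curve, grand_mean = grand_mean, method = method),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> metric = %s%s, %d pairwise values, mean = %.4f\n",
              x$metric, if (!is.null(x$k)) sprintf(" (k = %d)", x$k) else "",
              nrow(x$pairwise), x$mean))
  if (!is.null(x$curve)) {
    cat(sprintf("  Jaccard curve over %d cardinalities, grand mean (k = 1..p) = %.4f\n",
                nrow(x$curve), x$grand_mean))
  }
  invisible(x)
}

#' Averaged pairwise stability of a rank matrix
#'
#' Computes all `K(K-1)/2` pairwise similarities between the K run rankings
#' and averages them:
#' \deqn{S(A) = \frac{2}{K(K-1)} \sum_{i<j} SM(r_i, r_j)}
#' with `SM` either the Spearman rank correlation on the full rankings or
#' the Jaccard index on their top-k selections.
#'
#' @param A a `rank_matrix` with `K >= 2` run columns.
#' @param metric `"spearman"` or `"jaccard"`.
#' @param k top-list cardinality, required for the Jaccard metric.
#' @return a `stability_report`: `$pairwise` (tibble `run_i`, `run_j`,
#'   `value`, and overlap counts for Jaccard), `$mean` = S(A).
#' @export
average_pairwise_stability <- function(A, metric = c("spearman", "jaccard"),
                                       k = NULL) {
  metric <- match.arg(metric)
  m <- rank_matrix_entries(A)
  K <- ncol(m)
  if (K < 2) abort("stability needs at least K = 2 runs")
  pairs <- which(upper.tri(diag(K)), arr.ind = TRUE)
  if (metric == "spearman") {
    vals <- apply(pairs, 1, function(ij) {
      spearman_similarity(m[, ij[1]], m[, ij[2]])
    })
    pw <- tibble(run_i = pairs[, 1], run_j = pairs[, 2], value = vals)
  } else {
    if (is.null(k)) abort("the Jaccard metric needs a cardinality k")
    sets <- lapply(seq_len(K), function(j) rownames(m)[m[, j] <= k])
    res <- apply(pairs, 1, function(ij) {
      a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
      ncom <- length(intersect(a, b))
      nuni <- length(union(a, b))
      c(ncom / nuni, ncom, nuni)
    })
    pw <- tibble(run_i = pairs[, 1], run_j = pairs[, 2],
                 value = res[1, ], n_common = as.integer(res[2, ]),
                 n_union = as.integer(res[3, ]))
  }
  new_stability_report(metric, pw, mean(pw$value), k = k,
                       method = attr(A, "method"))
}

# mean pairwise top-k Jaccard for every k in 1..p, computed incrementally:
# walking k upward, each list gains one feature and the intersection count
# updates in O(1) amortized per pair
jaccard_all_k <- function(m) {
  p <- nrow(m)
  K <- ncol(m)
  by_rank <- apply(m, 2, order) # by_rank[k, j] = feature index at rank k
  pairs <- which(upper.tri(diag(K)), arr.ind = TRUE)
  acc <- numeric(p)
  for (q in seq_len(nrow(pairs))) {
    a <- by_rank[, pairs[q, 1]]
    b <- by_rank[, pairs[q, 2]]
    pos_a <- integer(p); pos_a[a] <- seq_len(p)
    pos_b <- integer(p); pos_b[b] <- seq_len(p)
    common <- 0L
    ji <- numeric(p)
    for (k in seq_len(p)) {
      fa <- a[k]; fb <- b[k]
      if (pos_b[fa] <= k) common <- common + 1L
      if (fb != fa && pos_a[fb] <= k) common <- common + 1L
      ji[k] <- common / (2L * k - common)
    }
    acc <- acc + ji
  }
  acc / nrow(pairs)
}

#' Jaccard stability curve over top-k cardinalities
#'
#' Mean pairwise Jaccard index of the K top-k lists, per cardinality, plus
#' the grand mean over every `k = 1..p` (the "average over all k" summary
#' row).
#'
#' @param A a `rank_matrix`.
#' @param ks cardinalities to tabulate; the default is the decade grid
#'   `10, 20, ..., p` capped at `p` (plus `p` itself).
#' @return a `stability_report` with `$curve` (tibble `k`, `mean_jaccard`)
#'   and `$grand_mean`.
#' @export
jaccard_stability_curve <- function(A, ks = NULL) {
  m <- rank_matrix_entries(A)
  p <- nrow(m)
  ks <- ks %||% unique(c(seq(10, p, by = 10), p))
  ks <- ks[ks >= 1 & ks <= p]
  if (length(ks) == 0) abort("no valid cardinality in ks")
  all_k <- jaccard_all_k(m)
  curve <- tibble(k = as.integer(sort(unique(ks))),
                  mean_jaccard = all_k[sort(unique(ks))])
  new_stability_report("jaccard_curve", pairwise = tibble(), k = NULL,
                       mean_value = mean(curve$mean_jaccard),
                       curve = curve, grand_mean = mean(all_k),
                       method = attr(A, "method"))
}

#' Stability summary across rankers
#'
#' One row per ranker: averaged pairwise Spearman correlation of the full
#' rankings, the mean top-k Jaccard index at each grid cardinality, and the
#' grand mean Jaccard over all `k = 1..p` — the machine-readable twin of a
#' per-ranker stability table.
#'
#' @param matrices named list of `rank_matrix` objects (names = rankers).
#' @param ks Jaccard cardinality grid (default as in
#'   [jaccard_stability_curve()]).
#' @return a tibble with columns `ranker`, `spearman`, `jaccard_k<k>`...,
#'   `jaccard_grand_mean`.
#' @export
stability_summary <- function(matrices, ks = NULL) {
  if (length(matrices) < 1) abort("need at least one rank matrix")
  if (is.null(names(matrices))) {
    names(matrices) <- vapply(matrices, function(A) {
      attr(A, "method") %||% "ranker"
    }, character(1))
  }
  rows <- imap(matrices, function(A, nm) {
    sp <- average_pairwise_stability(A, "spearman")
    jc <- jaccard_stability_curve(A, ks = ks)
    row <- tibble(ranker = nm, spearman = sp$mean)
    for (i in seq_len(nrow(jc$curve))) {
      row[[sprintf("jaccard_k%d", jc$curve$k[i])]] <- jc$curve$mean_jaccard[i]
    }
    row$jaccard_grand_mean <- jc$grand_mean
    row
  })
  bind_rows(rows)
}

#' @exportS3Method
tidy.stability_report <- function(x, ...) {
  if (!is.null(x$curve)) x$curve else x$pairwise
}

#' @exportS3Method
glance.stability_report <- function(x, ...) {
  tibble(metric = x$metric, k = x$k %||% NA_integer_, mean = x$mean,
         grand_mean = x$grand_mean %||% NA_real_,
         n_pairs = nrow(x$pairwise))
}
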