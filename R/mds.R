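#' Two-dimensional MDS embedding of ranking runs
#'
#' Projects a collection of rankings (typically K runs of each of several
#' rankers) into the plane so that inter-point distances approximate the
#' rank-list dissimilarities \eqn{d_{ij} = 1 - SR(r_i, r_j)} (in \[0, 2\]).
#' The embedding is fitted by iterative stress majorization (SMACOF): the
#' normalized stress \eqn{\sum_{i<j} (d_{ij} - \hat d_{ij})^2 / \sum_{i<j}
#' d_{ij}^2} is non-increasing across Guttman-transform iterations. Several
#' seeded random initialisations are tried and the lowest-stress solution
#' kept.
#'
#' A fully degenerate input (all rankings identical, zero dissimilarity) is
#' flagged, not failed: all points collapse at the origin with stress 0.
#'
#' @param rankings a named list of `rank_matrix` objects (points are tagged
#'   by ranker and run), a single `rank_matrix`, or a list of
#'   `feature_ranking`s.
#' @param seed master seed for the random initialisations.
#' @param n_init number of restarts (default 4).
#' @param max_iter iteration cap per restart (default 300).
#' @param tol relative stress-change convergence threshold (default 1e-6).
#' @return an `mds_embedding`: `$points` (tibble `ranker`, `run`, `x`, `y`),
#'   `$stress`, `$stress_path` of the winning restart, `$degenerate`.
#' @export
mds_embed <- function(rankings, seed = 1, n_init = 4, max_iter = 300,
                      tol = 1e-6) {
  cols <- list()
  tags <- list()
  add_matrix <- function(A, nm) {
    m <- rank_matrix_entries(A)
    for (j in seq_len(ncol(m))) {
      cols[[length(cols) + 1]] <<- m[, j]
      tags[[length(tags) + 1]] <<- tibble(ranker = nm, run = j)
    }
  }
  if (inherits(rankings, "rank_matrix")) {
    add_matrix(rankings, attr(rankings, "method") %||% "ranker")
  } else if (is.list(rankings) && all(vapply(rankings, inherits,
                                             logical(1), "rank_matrix"))) {
    nms <- names(rankings) %||% vapply(rankings, function(A) {
      attr(A, "method") %||% "ranker"
    }, character(1))
    for (i in seq_along(rankings)) add_matrix(rankings[[i]], nms[i])
  } else if (is.list(rankings)) {
    nms <- names(rankings) %||% sprintf("r%d", seq_along(rankings))
    for (i in seq_along(rankings)) {
      rk <- ranking_ranks(rankings[[i]])
      assert_permutation(rk)
      cols[[length(cols) + 1]] <- rk
      tags[[length(tags) + 1]] <- tibble(ranker = nms[i], run = 1L)
    }
  } else {
    abort("rankings must be rank matrices or a list of rankings")
  }
  n <- length(cols)
  if (n < 3) abort("MDS needs at least 3 rankings")
  feats <- names(cols[[1]])
  R <- vapply(cols, function(rk) as.numeric(rk[feats]), numeric(length(feats)))

  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- 1 - spearman_similarity(R[, i], R[, j])
    }
  }

  fit <- smacof_fit(D, seed = seed, n_init = n_init, max_iter = max_iter,
                    tol = tol)
  pts <- bind_rows(tags)
  pts$x <- fit$X[, 1]
  pts$y <- fit$X[, 2]
  structure(list(points = pts, stress = fit$stress,
                 stress_path = fit$path, degenerate = fit$degenerate,
                 dissimilarity = D),
            class = "mds_embedding")
}

# 2-D metric MDS by SMACOF stress majorization on a dissimilarity matrix.
# Objects with identical dissimilarity rows (zero mutual dissimilarity)
# share an initial position; their Guttman updates then coincide forever,
# so exact duplicates remain exactly collapsed in the embedding.
smacof_fit <- function(D, seed = 1, n_init = 4, max_iter = 300, tol = 1e-6) {
  n <- nrow(D)
  denom <- sum(D[upper.tri(D)]^2)
  if (denom == 0) {
    return(list(X = matrix(0, n, 2), stress = 0, path = 0, degenerate = TRUE))
  }
  grp <- match(apply(D, 1, paste, collapse = ","),
               unique(apply(D, 1, paste, collapse = ",")))
  smacof_once <- function(init_seed) {
    set.seed(init_seed)
    Xu <- matrix(rnorm(max(grp) * 2), max(grp), 2)
    X <- Xu[grp, , drop = FALSE]
    ed <- function(X) as.matrix(dist(X))
    stress_of <- function(dh) {
      sum((D[upper.tri(D)] - dh[upper.tri(dh)])^2) / denom
    }
    dh <- ed(X)
    s_prev <- stress_of(dh)
    path <- s_prev
    for (it in seq_len(max_iter)) {
      ratio <- ifelse(dh > 0, D / dh, 0)
      B <- -ratio
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
      dh <- ed(X)
      s <- stress_of(dh)
      path <- c(path, s)
      if (abs(s_prev - s) < tol * max(s_prev, .Machine$double.eps)) {
        s_prev <- s
        break
      }
      s_prev <- s
    }
    list(X = X, stress = s_prev, path = path)
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    cand <- smacof_once(derive_seed(seed, "mds_init", r))
    if (is.null(best) || cand$stress < best$stress) best <- cand
  }
  list(X = scale(best$X, scale = FALSE), stress = best$stress,
       path = best$path, degenerate = FALSE)
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d points, normalized stress = %.6f%s\n",
              nrow(x$points), x$stress,
              if (x$degenerate) " (degenerate: identical rankings)" else ""))
  invisible(x)
}

#' @exportS3Method
tidy.mds_embedding <- function(x, ...) x$points

#' @exportS3Method
glance.mds_embedding <- function(x, ...) {
  tibble(n_points = nrow(x$points), stress = x$stress,
         iterations = length(x$stress_path) - 1L, degenerate = x$degenerate)
}
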