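#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed. Stages and run
#' indices get their own sub-streams through this deterministic rule, so the
#' K-run subsampling protocol, classifier initialisations and the synthetic
#' generator are individually reproducible without sharing state.
#'
#' The rule hashes the stage label into an integer, combines it linearly with
#' the master seed and the run index, and reduces modulo 2^31 - 1 (a Mersenne
#' prime, keeping the result a valid 32-bit R integer).
#'
#' @param master integer master seed.
#' @param stage character label of the pipeline stage (e.g. "protocol_rf").
#' @param index non-negative run index within the stage.
#' @return a single integer seed in [1, 2^31 - 2].
#' @export
#' @examples
#' derive_seed(1, "protocol_pearson", 3)
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1
  chars <- utf8ToInt(stage)
  h <- 0
  for (ch in chars) h <- (h * 131 + ch) %% m
  val <- (abs(master) %% m)
  val <- (val * 48271) %% m
  val <- (val + h * 9973 + index * 101) %% m
  as.integer(val %% (m - 2L) + 1L)
}

# stratified fold assignment: within-class round-robin with a rotating
# remainder offset so overall fold sizes differ by at most one sample
make_folds <- function(y, folds, seed) {
  stopifnot(folds >= 2)
  classes <- unique(y)
  fold_of <- integer(length(y))
  offset <- 0L
  set.seed(seed)
  fold_perm <- sample(folds) # which folds absorb remainders first
  for (cl in classes) {
    idx <- which(y == cl)
    if (length(idx) < folds) {
      abort(sprintf(
        "class '%s' has %d samples; cannot build %d stratified folds",
        cl, length(idx), folds
      ))
    }
    idx <- sample(idx)
    base <- length(idx) %/% folds
    rem <- length(idx) %% folds
    sizes <- rep(base, folds)
    if (rem > 0) {
      take <- fold_perm[((offset + seq_len(rem) - 1L) %% folds) + 1L]
      sizes[take] <- sizes[take] + 1L
      offset <- offset + rem
    }
    fold_of[idx] <- rep.int(seq_len(folds), sizes)
  }
  fold_of
}

# column-wise z-scoring with train-derived location/scale; constant columns
# are left centred only (scale 1) so they stay finite
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mu = mu, s = s)
}

apply_standardizer <- function(X, st) {
  sweep(sweep(X, 2, st$mu, "-"), 2, st$s, "/")
}

first_duplicate <- function(x) x[duplicated(x)][1]
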