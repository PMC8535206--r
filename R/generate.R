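#' Configuration for the synthetic case-control generator
#'
#' The defaults emulate the structure of a breast-cancer case-control cohort:
#' 1865 individuals (946 controls, 919 cases) described by 124 features — 50
#' continuous environmental exposures, 64 SNP genotypes and 10 mixed-type
#' covariates including age and a menopausal indicator that splits the cohort
#' into 1233 pre-menopausal (569 cases / 664 controls) and 632 postmenopausal
#' (350 cases / 282 controls) individuals.
#'
#' Disease status follows a weak-signal logistic model
#' \eqn{\mathrm{logit}\,P(\mathrm{case}\mid x) = \beta_0 + \sum_j \beta_j x_j}
#' over the `informative` features (continuous features enter z-scored,
#' genotypes as 0/1/2 allele counts). The default effects are small by design
#' so that the full-set cross-validated AUC of a logistic classifier lands
#' near 0.55-0.62 — the regime in which feature-selection stability is an
#' interesting question at all.
#'
#' @param n_cases,n_controls cohort margins (exact, by construction).
#' @param n_env number of environmental features: multivariate normal in
#'   correlated blocks of 10, then standardized.
#' @param n_snp number of SNP genotypes: Hardy-Weinberg proportions with
#'   minor-allele frequency drawn uniformly from `maf_range`.
#' @param n_other number of additional covariates (age, menopausal indicator,
#'   family history, ... up to 10 named ones, generic beyond that).
#' @param informative data frame with columns `index` (feature position in
#'   env, snp, other order) and `beta` (log-odds effect per unit of the
#'   design-scale feature). `NULL` plants the calibrated default weak signal.
#' @param intercept log-odds intercept of the disease model.
#' @param env_block_correlation within-block equicorrelation of the
#'   environmental features, in \[0, 1).
#' @param maf_range length-2 minor-allele-frequency bounds.
#' @param menopause_margins named or positional vector
#'   `(pre_cases, pre_controls, post_cases, post_controls)`; must sum to the
#'   case/control margins. `NULL` drops the menopausal indicator constraint
#'   (the indicator is then a plain binary covariate).
#' @param pool_factor the generator simulates `pool_factor * (n_cases +
#'   n_controls)` individuals from the population model and then subsamples
#'   the exact case/control margins; raise it if margins turn out infeasible.
#' @param seed RNG seed; identical configs with identical seeds yield
#'   identical tables.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_cases = 919, n_controls = 946,
                             n_env = 50, n_snp = 64, n_other = 10,
                             informative = NULL, intercept = 0,
                             env_block_correlation = 0.3,
                             maf_range = c(0.05, 0.5),
                             menopause_margins = c(
                               pre_cases = 569, pre_controls = 664,
                               post_cases = 350, post_controls = 282
                             ),
                             pool_factor = 20, seed = 1) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_env = as.integer(n_env), n_snp = as.integer(n_snp),
    n_other = as.integer(n_other),
    informative = informative, intercept = intercept,
    env_block_correlation = env_block_correlation,
    maf_range = maf_range, menopause_margins = menopause_margins,
    pool_factor = pool_factor, seed = as.integer(seed)
  )
  p <- cfg$n_env + cfg$n_snp + cfg$n_other
  if (any(c(cfg$n_cases, cfg$n_controls, cfg$n_env, cfg$n_snp, cfg$n_other) < 0)) {
    abort("all counts must be non-negative")
  }
  if (p < 1) abort("at least one feature is required")
  if (is.null(cfg$informative)) {
    cfg$informative <- default_informative(cfg)
  } else {
    cfg$informative <- as_tibble(cfg$informative)
    stopifnot(all(c("index", "beta") %in% names(cfg$informative)))
    if (any(cfg$informative$index < 1 | cfg$informative$index > p)) {
      abort("informative feature index out of range")
    }
  }
  if (env_block_correlation < 0 || env_block_correlation >= 1) {
    abort("env_block_correlation must be in [0, 1)")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("maf_range must be (low, high) with 0 < low <= high <= 0.5")
  }
  if (!is.null(cfg$menopause_margins)) {
    mm <- as.integer(cfg$menopause_margins)
    if (length(mm) != 4 || any(mm < 0)) {
      abort("menopause_margins must be 4 non-negative counts")
    }
    names(mm) <- c("pre_cases", "pre_controls", "post_cases", "post_controls")
    if (mm["pre_cases"] + mm["post_cases"] != cfg$n_cases ||
        mm["pre_controls"] + mm["post_controls"] != cfg$n_controls) {
      abort("menopause_margins must sum to the case/control margins")
    }
    if (cfg$n_other < 2) {
      abort("menopause margins require n_other >= 2 (age + menopausal)")
    }
    cfg$menopause_margins <- mm
  }
  structure(cfg, class = "generator_config")
}

# calibrated default: 8 weak effects spread over the three blocks, sized so
# the full-set logistic CV AUC sits near 0.58-0.62
default_informative <- function(cfg) {
  idx <- c(1, 5, 12, 20)
  idx <- idx[idx <= cfg$n_env]
  beta <- c(0.25, -0.21, 0.17, 0.17)[seq_along(idx)]
  if (cfg$n_snp >= 1) {
    sidx <- cfg$n_env + c(1, 10, 25)
    keep <- sidx <= cfg$n_env + cfg$n_snp
    idx <- c(idx, sidx[keep])
    beta <- c(beta, c(0.35, -0.28, 0.28)[keep])
  }
  if (cfg$n_other >= 1) { # age
    idx <- c(idx, cfg$n_env + cfg$n_snp + 1)
    beta <- c(beta, 0.21)
  }
  tibble(index = idx, beta = beta)
}

#' Generator config with strongly planted signal features
#'
#' The parameter-recovery scenario: the default cohort structure with
#' `n_planted` features carrying a log-odds effect of `beta` per standard
#' deviation, all planted on unit-variance carriers (environmental features
#' in distinct correlation blocks, plus age). Unit-variance carriers give
#' every planted feature the same marginal effect size, which is what a
#' recovery benchmark should control; genotype carriers would make the
#' marginal strength depend on the randomly drawn minor-allele frequency.
#'
#' @param beta planted log-odds effect per standard deviation (default 1).
#' @param n_planted number of planted features (default 5, max 5).
#' @param seed generator seed.
#' @param ... further arguments to [generator_config()].
#' @return a `generator_config` whose `informative` field holds the planted
#'   effects.
#' @export
planted_config <- function(beta = 1, n_planted = 5, seed = 1, ...) {
  stopifnot(n_planted >= 1, n_planted <= 5)
  idx <- c(3, 13, 23, 33, 115)[seq_len(n_planted)] # env blocks 1-4, then age
  generator_config(
    informative = tibble(index = idx, beta = beta), seed = seed, ...
  )
}

other_feature_names <- c(
  "age", "menopausal", "family_history_bc", "education_level", "offspring",
  "nulliparous", "abdominal_obesity", "age_menarche", "lactation_months",
  "socioeconomic_level"
)

#' Generate a synthetic case-control feature table
#'
#' Simulates a population pool of `pool_factor * (n_cases + n_controls)`
#' individuals: block-correlated standardized environmental exposures, SNP
#' genotypes in Hardy-Weinberg proportions, and mixed-type covariates.
#' Disease labels are drawn from the logistic model of the config, after
#' which exactly `n_cases` cases and `n_controls` controls are retained
#' (case-control sampling). When menopause margins are set, the menopausal
#' indicator is assigned within each class stratum to the oldest individuals,
#' hitting the margins exactly and inducing a realistic age-menopause
#' dependence.
#'
#' @param config a [generator_config()].
#' @return a [feature_table()] with `n_cases + n_controls` rows.
#' @export
#' @examples
#' tab <- generate_dataset(generator_config(
#'   n_cases = 30, n_controls = 30, n_env = 5, n_snp = 5, n_other = 2,
#'   menopause_margins = c(20, 18, 10, 12), seed = 7
#' ))
#' dim(tab)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  N <- as.integer(cfg$pool_factor * (cfg$n_cases + cfg$n_controls))
  p <- cfg$n_env + cfg$n_snp + cfg$n_other

  cols <- list()
  meta <- list()

  # environmental block: equicorrelated gaussian blocks of 10, standardized
  if (cfg$n_env > 0) {
    rho <- cfg$env_block_correlation
    env <- matrix(rnorm(N * cfg$n_env), N, cfg$n_env)
    n_blocks <- ceiling(cfg$n_env / 10)
    zb <- matrix(rnorm(N * n_blocks), N, n_blocks)
    for (b in seq_len(n_blocks)) {
      j <- ((b - 1) * 10 + 1):min(b * 10, cfg$n_env)
      env[, j] <- sqrt(rho) * zb[, b] + sqrt(1 - rho) * env[, j]
    }
    env <- scale(env)
    colnames(env) <- sprintf("env_%02d", seq_len(cfg$n_env))
    cols$env <- env
    meta$env <- tibble(feature = colnames(env), kind = "environmental",
                       domain = "continuous")
  }

  # SNPs: genotype ~ Binomial(2, maf), i.e. Hardy-Weinberg proportions
  if (cfg$n_snp > 0) {
    maf <- runif(cfg$n_snp, cfg$maf_range[1], cfg$maf_range[2])
    snp <- vapply(maf, function(q) rbinom(N, 2L, q), numeric(N))
    colnames(snp) <- sprintf("snp_%03d", seq_len(cfg$n_snp))
    cols$snp <- snp
    meta$snp <- tibble(feature = colnames(snp), kind = "snp",
                       domain = "genotype")
  }

  # other covariates: age first, menopausal second (assigned later), then
  # binary/ordinal/continuous named covariates, generic beyond ten
  if (cfg$n_other > 0) {
    oth <- matrix(0, N, cfg$n_other)
    nm <- character(cfg$n_other)
    dom <- character(cfg$n_other)
    gens <- list(
      age = function() rnorm(N, 55, 10),
      menopausal = function() rbinom(N, 1L, 0.34),
      family_history_bc = function() rbinom(N, 1L, 0.12),
      education_level = function() sample(1:4, N, TRUE, c(.25, .35, .25, .15)),
      offspring = function() rbinom(N, 1L, 0.75),
      nulliparous = function() rbinom(N, 1L, 0.22),
      abdominal_obesity = function() rbinom(N, 1L, 0.35),
      age_menarche = function() round(rnorm(N, 12.8, 1.4), 1),
      lactation_months = function() pmax(0, round(rnorm(N, 8, 9))),
      socioeconomic_level = function() sample(1:5, N, TRUE)
    )
    doms <- c(age = "continuous", menopausal = "binary",
              family_history_bc = "binary", education_level = "ordinal",
              offspring = "binary", nulliparous = "binary",
              abdominal_obesity = "binary", age_menarche = "continuous",
              lactation_months = "continuous", socioeconomic_level = "ordinal")
    for (j in seq_len(cfg$n_other)) {
      if (j <= length(gens)) {
        nm[j] <- other_feature_names[j]
        oth[, j] <- gens[[j]]()
        dom[j] <- doms[[nm[j]]]
      } else {
        nm[j] <- sprintf("other_%02d", j)
        oth[, j] <- rnorm(N)
        dom[j] <- "continuous"
      }
    }
    colnames(oth) <- nm
    cols$other <- oth
    meta$other <- tibble(feature = nm, kind = "other", domain = dom)
  }

  X <- do.call(cbind, unname(cols))
  meta <- bind_rows(meta)

  # disease model on the design scale: continuous features z-scored,
  # binary/ordinal/genotype features raw
  D <- X
  cont <- which(meta$domain == "continuous")
  if (length(cont) > 0) D[, cont] <- scale(D[, cont])
  beta <- numeric(p)
  beta[cfg$informative$index] <- cfg$informative$beta
  eta <- cfg$intercept + as.vector(D %*% beta)
  lab <- rbinom(N, 1L, plogis(eta))

  ncase_pool <- sum(lab == 1L)
  nctrl_pool <- sum(lab == 0L)
  if (ncase_pool < cfg$n_cases || nctrl_pool < cfg$n_controls) {
    abort(sprintf(paste0(
      "case-control margins infeasible: pool of %d produced %d cases and ",
      "%d controls but %d/%d are required; raise pool_factor"),
      N, ncase_pool, nctrl_pool, cfg$n_cases, cfg$n_controls
    ))
  }
  take <- c(sample(which(lab == 1L), cfg$n_cases),
            sample(which(lab == 0L), cfg$n_controls))
  X <- X[take, , drop = FALSE]
  lab <- lab[take]

  # exact stratified menopause allocation: within each class, the oldest
  # individuals are post-menopausal
  if (!is.null(cfg$menopause_margins) && "menopausal" %in% colnames(X)) {
    mm <- cfg$menopause_margins
    men <- integer(nrow(X))
    age <- X[, "age"]
    for (cl in c(1L, 0L)) {
      idx <- which(lab == cl)
      n_post <- if (cl == 1L) mm[["post_cases"]] else mm[["post_controls"]]
      post <- idx[order(-age[idx], sample(length(idx)))][seq_len(n_post)]
      men[post] <- 1L
    }
    X[, "menopausal"] <- men
  }

  ord <- sample(nrow(X)) # shuffle so class is not row-ordered
  df <- as_tibble(as.data.frame(X[ord, , drop = FALSE]))
  df$class <- lab[ord]
  df$sample_id <- sprintf("S%05d", seq_len(nrow(df)))
  feature_table(df, meta = meta, label_col = "class")
}

#' Split a cohort by menopausal status
#'
#' Partitions the table on a binary indicator column (0 = pre, 1 = post) and
#' removes the indicator from both partitions, leaving `p - 1` features.
#'
#' @param x a `feature_table`.
#' @param indicator name of the indicator column (default `"menopausal"`).
#' @return named list with `feature_table`s `pre` and `post`.
#' @export
partition_by_menopause <- function(x, indicator = "menopausal") {
  if (!indicator %in% feature_names(x)) {
    abort(sprintf("menopausal indicator column '%s' not found", indicator))
  }
  v <- x[[indicator]]
  if (!all(v %in% c(0, 1))) abort("indicator column must be 0/1")
  if (all(v == 0) || all(v == 1)) {
    abort("degenerate partition: one menopausal stratum is empty")
  }
  feats <- setdiff(feature_names(x), indicator)
  list(
    pre = rebuild_table(x[v == 0, ], x, feats),
    post = rebuild_table(x[v == 1, ], x, feats)
  )
}

#' Subsample rows of a feature table without replacement
#'
#' Draws `floor(fraction * M)` rows uniformly without replacement, keeping
#' all columns. Seeded and reproducible; this is the perturbation underlying
#' the K-run stability protocol.
#'
#' @param x a `feature_table`.
#' @param fraction row fraction in (0, 1].
#' @param seed RNG seed.
#' @return a `feature_table` with `floor(fraction * nrow(x))` rows.
#' @export
subsample_table <- function(x, fraction, seed = 1) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]")
  }
  m <- floor(fraction * nrow(x))
  set.seed(seed)
  rows <- sample(nrow(x), m)
  rebuild_table(x[rows, ], x)
}
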