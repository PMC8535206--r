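#' Configure an end-to-end ranking-stability study
#'
#' Bundles every knob of the pipeline: the data source (a generator config
#' or paths to a table on disk), the ranking protocol (which rankers, K
#' runs, subsample fraction, aggregation), the classifiers and fold count
#' for AUC evaluation, the cardinality grids, and the master seed from
#' which all stage seeds are derived.
#'
#' The defaults mirror the study protocol: K = 7 runs on 70% subsamples,
#' mean-rank aggregation on the full cohort (median for menopausal
#' partitions), 7-fold cross-validation. The wrapper rankers are excluded
#' from the default ranker list on cost grounds; add `"svm_wrapper"` /
#' `"lr_wrapper"` for the full profile.
#'
#' @param generator a [generator_config()], or `NULL` when reading from disk.
#' @param table_path,meta_path input table and metadata sidecar paths
#'   (used when `generator` is `NULL`).
#' @param rankers character vector of ranker names (see [run_protocol()]).
#' @param K,fraction ranking protocol: runs and subsample fraction.
#' @param aggregation `"mean"` or `"median"` for the cohort-level consensus.
#' @param classifiers named list of [classifier_spec()]s.
#' @param folds cross-validation folds.
#' @param performance_ks cardinality grid for AUC-vs-k curves (`NULL`:
#'   deciles of p plus p).
#' @param jaccard_ks cardinality grid for the stability curves (`NULL`:
#'   decades plus p).
#' @param caps,top_n best-subset report parameters.
#' @param partition_indicator menopausal indicator column; partition stages
#'   run only when it is present in the data.
#' @param top_table_n rows of the per-partition top-feature tables.
#' @param ranker_args named list of extra arguments per ranker, e.g.
#'   `list(svm_rfe = list(step = 0.5))`.
#' @param out_dir output directory for [run_study()].
#' @param seed master seed.
#' @return a `study_config`.
#' @export
study_config <- function(generator = generator_config(),
                         table_path = NULL, meta_path = NULL,
                         rankers = c("pearson", "relief", "svm_rfe", "rf"),
                         K = 7, fraction = 0.7,
                         aggregation = c("mean", "median"),
                         classifiers = default_classifier_specs(),
                         folds = 7,
                         performance_ks = NULL, jaccard_ks = NULL,
                         caps = c(30, 60, 90), top_n = 3,
                         partition_indicator = "menopausal",
                         top_table_n = 30,
                         ranker_args = list(),
                         out_dir = "rankstab_outputs", seed = 1) {
  aggregation <- match.arg(aggregation)
  if (K < 2) abort("K must be >= 2")
  if (is.null(generator) && is.null(table_path)) {
    abort("either a generator config or a table path is required")
  }
  if (!is.null(table_path) && !file.exists(table_path)) {
    abort(sprintf("table file not found: %s", table_path))
  }
  structure(
    list(generator = generator, table_path = table_path,
         meta_path = meta_path, rankers = rankers, K = as.integer(K),
         fraction = fraction, aggregation = aggregation,
         classifiers = classifiers, folds = as.integer(folds),
         performance_ks = performance_ks, jaccard_ks = jaccard_ks,
         caps = caps, top_n = as.integer(top_n),
         partition_indicator = partition_indicator,
         top_table_n = as.integer(top_table_n),
         ranker_args = ranker_args,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Run the full study pipeline
#'
#' Generate (or read) the cohort, run the K-run ranking protocol for every
#' configured ranker, quantify stability (Spearman, Jaccard curves, MDS),
#' evaluate AUC-vs-cardinality curves and full-set baselines for every
#' classifier, and — when a menopausal indicator is present — repeat the
#' ranking and baseline stages on the pre/post partitions with median-rank
#' aggregation. All tables are written as CSV under `config$out_dir`, plus
#' a JSON manifest with the config snapshot, derived stage seeds and
#' per-file checksums. Re-running with the same config and seed reproduces
#' every output byte for byte.
#'
#' @param config a [study_config()].
#' @return the manifest, invisibly (a list; also written to
#'   `manifest.json`).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    readr::write_csv(df, path)
    paths[length(paths) + 1] <<- path
    path
  }
  stage <- "data"
  result <- tryCatch({
    # -- data ---------------------------------------------------------------
    tab <- if (!is.null(cfg$generator)) {
      gen <- cfg$generator
      gen$seed <- derive_seed(cfg$seed, "generate")
      generate_dataset(gen)
    } else {
      read_feature_table(cfg$table_path, cfg$meta_path)
    }
    emit(dplyr::mutate(as_tibble(tab), class = as.character(.data$class)),
         "feature_table.csv")
    emit(feature_meta(tab), "feature_meta.csv")

    # -- ranking ------------------------------------------------------------
    stage <- "ranking"
    matrices <- list()
    aggregated <- list()
    for (rk in cfg$rankers) {
      extra <- cfg$ranker_args[[rk]] %||% list()
      A <- do.call(run_protocol,
                   c(list(tab, rk, K = cfg$K, fraction = cfg$fraction,
                          seed = cfg$seed), extra))
      matrices[[rk]] <- A
      agg <- aggregate_rankings(A, cfg$aggregation)
      aggregated[[rk]] <- agg
      out <- as_tibble(A)
      out$aggregate <- agg$aggregate[match(out$feature, agg$feature)]
      out$final_rank <- agg$rank[match(out$feature, agg$feature)]
      emit(out, sprintf("rank_matrix_%s.csv", rk))
    }

    # -- stability ----------------------------------------------------------
    stage <- "stability"
    summary <- stability_summary(matrices, ks = cfg$jaccard_ks)
    emit(summary, "stability_summary.csv")
    pw <- imap(matrices, function(A, nm) {
      rep <- average_pairwise_stability(A, "spearman")
      mutate(rep$pairwise, ranker = nm)
    })
    emit(bind_rows(pw), "stability_pairwise_spearman.csv")
    emb <- mds_embed(matrices, seed = derive_seed(cfg$seed, "mds"))
    emit(mutate(emb$points, stress = emb$stress), "mds_coordinates.csv")

    # -- performance --------------------------------------------------------
    stage <- "performance"
    baseline <- full_baseline(tab, cfg$classifiers, folds = cfg$folds,
                              seed = derive_seed(cfg$seed, "cv"))
    emit(baseline, "baseline_auc.csv")
    p <- length(feature_names(tab))
    ks <- cfg$performance_ks %||%
      unique(c(pmax(1, round(seq(0.1, 1, by = 0.1) * p))))
    curves <- list()
    for (rk in names(aggregated)) {
      for (cl in names(cfg$classifiers)) {
        curves[[paste(rk, cl, sep = "_")]] <- performance_vs_cardinality(
          tab, aggregated[[rk]], cfg$classifiers[[cl]], ks = ks,
          folds = cfg$folds, seed = derive_seed(cfg$seed, "cv")
        )
      }
    }
    emit(bind_rows(lapply(curves, as_tibble)), "performance_curves.csv")
    emit(best_subsets_report(curves, caps = cfg$caps, top_n = cfg$top_n),
         "best_subsets.csv")

    # -- menopausal partitions ----------------------------------------------
    if (cfg$partition_indicator %in% feature_names(tab)) {
      stage <- "partitions"
      parts <- partition_by_menopause(tab, cfg$partition_indicator)
      for (pn in names(parts)) {
        pt <- parts[[pn]]
        emit(full_baseline(pt, cfg$classifiers, folds = cfg$folds,
                           seed = derive_seed(cfg$seed, paste0("cv_", pn))),
             sprintf("baseline_auc_%s.csv", pn))
        ranker <- if ("svm_rfe" %in% cfg$rankers) "svm_rfe" else cfg$rankers[1]
        extra <- cfg$ranker_args[[ranker]] %||% list()
        A <- do.call(run_protocol,
                     c(list(pt, ranker, K = cfg$K, fraction = cfg$fraction,
                            seed = derive_seed(cfg$seed, paste0("rank_", pn))),
                       extra))
        agg <- aggregate_rankings(A, "median")
        top <- agg |>
          arrange(.data$rank) |>
          head(cfg$top_table_n) |>
          select("feature", median_rank_position = "aggregate")
        emit(top, sprintf("top_features_%s.csv", pn))
      }
    }

    list(tab = tab)
  }, error = function(e) {
    abort(sprintf("study failed at stage '%s': %s (outputs so far kept in %s)",
                  stage, conditionMessage(e), cfg$out_dir))
  })

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("rankstab")),
    seed = cfg$seed,
    stage_seeds = list(
      generate = derive_seed(cfg$seed, "generate"),
      mds = derive_seed(cfg$seed, "mds"),
      cv = derive_seed(cfg$seed, "cv")
    ),
    config = config_snapshot(cfg),
    outputs = lapply(setNames(paths, basename(paths)), function(pth) {
      list(path = pth, md5 = unname(tools::md5sum(pth)))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_snapshot <- function(cfg) {
  snap <- cfg
  snap$classifiers <- lapply(cfg$classifiers, unclass)
  snap$generator <- if (!is.null(cfg$generator)) unclass(cfg$generator)
  snap$informative <- NULL
  class(snap) <- NULL
  snap
}
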