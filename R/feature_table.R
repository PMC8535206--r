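#' Construct a case-control feature table
#'
#' A feature table is a tibble with one row per individual: a `sample_id`
#' column, a binary `class` factor with levels `control`/`case` (the positive
#' class is `case`), and one numeric column per feature. Per-feature metadata
#' (block kind and value domain) travels along as the `feature_meta`
#' attribute, a tibble with columns `feature`, `kind` (one of
#' `environmental`, `snp`, `other`) and `domain` (one of `continuous`,
#' `binary`, `ordinal`, `genotype`).
#'
#' @param data data frame with `sample_id`, a label column and feature columns.
#' @param meta optional feature-metadata tibble; inferred when missing
#'   (integer 0/1/2 columns become `genotype`, 0/1 columns `binary`, the rest
#'   `continuous`; kind defaults to `other`).
#' @param label_col name of the label column, recoded to a `control`/`case`
#'   factor. Accepts factors, characters or 0/1 (1 = case).
#' @return a `feature_table` tibble.
#' @export
feature_table <- function(data, meta = NULL, label_col = "class") {
  data <- as_tibble(data)
  if (!label_col %in% names(data)) {
    abort(sprintf("label column '%s' not found", label_col))
  }
  lab <- data[[label_col]]
  lab <- recode_labels(lab)
  data[[label_col]] <- NULL
  if (!"sample_id" %in% names(data)) {
    data$sample_id <- sprintf("S%05d", seq_len(nrow(data)))
  }
  ids <- as.character(data$sample_id)
  data$sample_id <- NULL

  feats <- names(data)
  if (length(feats) == 0) abort("feature table has no feature columns")
  if (anyDuplicated(feats)) {
    abort(sprintf("duplicate feature name: '%s'", first_duplicate(feats)))
  }
  miss <- which(is.na(as.matrix(data)), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    abort(sprintf(
      "missing value at row %d, feature '%s'; complete cases are required",
      miss[1, 1], feats[miss[1, 2]]
    ))
  }
  if (!all(vapply(data, is.numeric, logical(1)))) {
    bad <- feats[!vapply(data, is.numeric, logical(1))][1]
    abort(sprintf("feature '%s' is not numeric", bad))
  }

  if (is.null(meta)) {
    meta <- infer_feature_meta(data)
  } else {
    meta <- as_tibble(meta)
    stopifnot(all(c("feature", "kind", "domain") %in% names(meta)))
    if (!setequal(meta$feature, feats)) {
      abort("feature metadata does not match table columns")
    }
    meta <- meta[match(feats, meta$feature), ]
  }

  out <- tibble(sample_id = ids, class = lab)
  out <- dplyr::bind_cols(out, data)
  attr(out, "feature_meta") <- meta
  class(out) <- c("feature_table", class(out))
  out
}

recode_labels <- function(lab) {
  if (is.numeric(lab)) {
    u <- sort(unique(lab))
    if (!all(u %in% c(0, 1))) {
      abort("numeric labels must be 0/1 (1 = case)")
    }
    lab <- ifelse(lab == 1, "case", "control")
  }
  lab <- as.character(lab)
  u <- unique(lab)
  if (length(u) > 2) {
    abort(sprintf("label must be binary; found %d classes", length(u)))
  }
  if (!all(u %in% c("case", "control"))) {
    abort("labels must be 'case'/'control' (or 0/1)")
  }
  factor(lab, levels = c("control", "case"))
}

infer_feature_meta <- function(data) {
  dom <- vapply(data, function(v) {
    u <- unique(v)
    if (all(u %in% c(0, 1))) return("binary")
    if (all(u %in% c(0, 1, 2)) && length(u) == 3) return("genotype")
    if (is.integer(v) || all(v == round(v))) return("ordinal")
    "continuous"
  }, character(1))
  tibble(feature = names(data), kind = "other", domain = unname(dom))
}

#' Feature names of a feature table
#' @param x a `feature_table`.
#' @return character vector of feature column names.
#' @export
feature_names <- function(x) {
  setdiff(names(x), c("sample_id", "class"))
}

#' Feature metadata of a feature table
#' @param x a `feature_table`.
#' @return tibble with columns `feature`, `kind`, `domain`.
#' @export
feature_meta <- function(x) {
  m <- attr(x, "feature_meta")
  if (is.null(m)) m <- infer_feature_meta(x[feature_names(x)])
  m
}

# numeric matrix of features, rows = individuals
feature_matrix <- function(x, features = NULL) {
  features <- features %||% feature_names(x)
  as.matrix(x[features])
}

# reattach feature_table class/metadata after row subsetting
rebuild_table <- function(df, template, features = NULL) {
  meta <- feature_meta(template)
  if (!is.null(features)) meta <- meta[meta$feature %in% features, ]
  keep <- c("sample_id", "class", features %||% feature_names(template))
  df <- as_tibble(df)[keep]
  attr(df, "feature_meta") <- meta
  if (!inherits(df, "feature_table")) class(df) <- c("feature_table", class(df))
  df
}

#' @export
print.feature_table <- function(x, ...) {
  m <- feature_meta(x)
  cat(sprintf(
    "<feature_table> %d individuals (%d cases, %d controls), %d features (%s)\n",
    nrow(x), sum(x$class == "case"), sum(x$class == "control"),
    nrow(m), paste(sprintf("%d %s", table(m$kind)[unique(m$kind)], unique(m$kind)),
                   collapse = ", ")
  ))
  NextMethod()
}

#' Write a feature table and its metadata sidecar
#'
#' The table is written as delimited text with a header row (`sample_id`,
#' `class`, then feature columns); metadata goes to a tab-separated sidecar
#' with columns `feature`, `kind`, `domain`.
#'
#' @param x a `feature_table`.
#' @param path output path for the table (`.csv` or `.tsv` by extension).
#' @param meta_path output path for the sidecar; defaults to
#'   `<path>.meta.tsv`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, meta_path = NULL) {
  meta_path <- meta_path %||% paste0(path, ".meta.tsv")
  df <- as_tibble(x)
  df$class <- as.character(df$class)
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(df, path)
  } else {
    readr::write_csv(df, path)
  }
  readr::write_tsv(feature_meta(x), meta_path)
  invisible(path)
}

#' Read a feature table from delimited text
#'
#' Parses a delimited table (comma or tab separated, header row required),
#' validates it (no missing cells, unique feature names, binary label) and
#' binds the metadata sidecar when present. Missing values are an error, not
#' imputed: complete-case filtering is the caller's responsibility.
#'
#' @param path table file.
#' @param meta_path optional metadata sidecar (tab-separated `feature`,
#'   `kind`, `domain`); tried at `<path>.meta.tsv` when `NULL`.
#' @param label_col name of the label column (default `"class"`).
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, meta_path = NULL, label_col = "class") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, name_repair = "minimal")
  meta <- NULL
  meta_path <- meta_path %||% paste0(path, ".meta.tsv")
  if (file.exists(meta_path)) {
    meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  }
  feature_table(df, meta = meta, label_col = label_col)
}
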