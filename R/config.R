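#' Read a run configuration
#'
#' Loads a YAML (or JSON) run configuration and merges it over the package
#' defaults, which mirror the reference protocol: missing-value threshold
#' 0.20, SMOTE gate 0.70, `alpha = gamma = 0.5` with the `min` combiner,
#' betas 0.1/1/10 and 10 x 5 stratified CV.  Unknown keys are rejected.
#'
#' @param path YAML/JSON file, or `NULL` for pure defaults.
#' @param overrides named list of values taking precedence over the file.
#' @return A [cv_config()].
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  known <- c("repetitions", "folds", "master_seed", "windows", "betas",
             "classifiers", "fs_methods", "missing_threshold", "smote_gate",
             "smote_k", "alpha", "gamma", "combiner", "compare_base_methods")
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    bad <- setdiff(names(vals), known)
    if (length(bad)) {
      stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    }
  }
  bad <- setdiff(names(overrides), known)
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  vals[names(overrides)] <- overrides
  get_or <- function(key, default) if (is.null(vals[[key]])) default else vals[[key]]
  classifiers <- lapply(get_or("classifiers", "NB"), function(kind) {
    classifier_spec(kind, seed = as.integer(get_or("master_seed", 1L)))
  })
  cv_config(
    repetitions = get_or("repetitions", 10),
    folds = get_or("folds", 5),
    master_seed = get_or("master_seed", 1L),
    windows = get_or("windows", c(2, 3, 4)),
    betas = get_or("betas", c(0.1, 1, 10)),
    classifiers = classifiers,
    fs_methods = get_or("fs_methods",
                        c("RELIEFF", "MIM", "CMIM", "MRMR", "CHI2", "LL21")),
    missing_threshold = get_or("missing_threshold", 0.20),
    smote_gate = get_or("smote_gate", 0.70),
    smote_k = get_or("smote_k", 5),
    perf = perf_config(alpha = get_or("alpha", 0.5),
                       gamma = get_or("gamma", 0.5),
                       combiner = toupper(get_or("combiner", "MIN"))),
    compare_base_methods = get_or("compare_base_methods", TRUE)
  )
}

#' Ranking CSV round-trip
#'
#' Rankings are exchanged between subcommands as CSVs with columns
#' `feature, position, weight`.
#'
#' @param ranking a `feature_ranking`.
#' @param path CSV path.
#' @export
write_ranking_csv <- function(ranking, path) {
  utils::write.csv(data.frame(feature = ranking$features,
                              position = seq_along(ranking$features),
                              weight = unname(ranking$weights),
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking_csv
#' @param method method label for the reconstructed ranking.
#' @export
read_ranking_csv <- function(path, method = "FILE") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[order(df$position), ]
  new_feature_ranking(method, df$feature,
                      stats::setNames(df$weight, df$feature))
}

# Labelled windowed-dataset CSV: example_id, features..., label.
write_windowed_csv <- function(wd, path) {
  df <- cbind(example_id = rownames(wd$table), as.data.frame(wd$table),
              label = as.character(wd$labels))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

read_windowed_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                        stringsAsFactors = FALSE)
  stopifnot(all(c("example_id", "label") %in% names(df)))
  labels <- factor(df$label, levels = c("sMCI", "cMCI"))
  ids <- df$example_id
  df$label <- NULL
  df$example_id <- NULL
  rownames(df) <- ids
  list(table = feature_table(df), labels = labels)
}
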