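# Canonical diagnosis vocabulary.  Raw labels are trimmed and matched
# case-insensitively: "MCI" -> MCI, {"AD", "dementia"} -> DEMENTIA,
# anything else -> OTHER.
normalize_diagnosis <- function(x) {
  key <- toupper(trimws(as.character(x)))
  out <- rep("OTHER", length(key))
  out[key == "MCI"] <- "MCI"
  out[key %in% c("AD", "DEMENTIA")] <- "DEMENTIA"
  out
}

#' Construct a feature table
#'
#' A feature table is the package's tabular container for baseline features:
#' a data frame with one row per example (row names are example ids), one
#' column per feature, and a `kinds` attribute mapping each feature to
#' `"numeric"` or `"nominal"`.  Missing values are `NA`; nominal columns are
#' character vectors.
#'
#' @param values data frame of feature values; row names identify examples.
#' @param kinds optional named character vector (`"numeric"`/`"nominal"`),
#'   one entry per column of `values`.  Inferred from column types when
#'   omitted.
#' @return An object of class `feature_table` (a data frame).
#' @export
feature_table <- function(values, kinds = NULL) {
  stopifnot(is.data.frame(values))
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  for (j in seq_along(values)) {
    if (is.factor(values[[j]])) values[[j]] <- as.character(values[[j]])
  }
  if (is.null(kinds)) {
    kinds <- vapply(values, function(col) {
      if (is.numeric(col)) "numeric" else "nominal"
    }, character(1))
    names(kinds) <- names(values)
  }
  if (!setequal(names(kinds), names(values)) && ncol(values) > 0) {
    stop("`kinds` must name exactly the columns of `values`")
  }
  kinds <- kinds[names(values)]
  for (j in seq_along(values)) {
    col <- values[[j]]
    ok <- if (kinds[[j]] == "numeric") is.numeric(col) else is.character(col)
    if (!ok && !all(is.na(col))) {
      stop(sprintf("column '%s' does not match declared kind '%s'",
                   names(values)[j], kinds[[j]]))
    }
    if (kinds[[j]] == "numeric" && !is.numeric(col)) {
      values[[j]] <- as.numeric(col)
    }
  }
  structure(values, kinds = kinds, class = c("feature_table", "data.frame"))
}

#' @export
ft_kinds <- function(table) attr(table, "kinds")

#' Read and write feature tables
#'
#' CSV round-trip for [feature_table()] objects.  The first column holds the
#' example id; empty fields encode missing values.  `read_feature_table()`
#' needs the feature kinds, either from a companion `<path>.kinds` file
#' written by `write_feature_table()` or inferred from the parsed columns.
#'
#' @param table a `feature_table`.
#' @param path CSV file path.
#' @return `read_feature_table()` returns a `feature_table`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  out <- cbind(example_id = rownames(df), df)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  kinds <- ft_kinds(table)
  writeLines(paste(names(kinds), unname(kinds), sep = ","),
             paste0(path, ".kinds"))
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"example_id" %in% names(df)) {
    stop(sprintf("%s: missing 'example_id' column", path))
  }
  ids <- df$example_id
  df$example_id <- NULL
  kinds_path <- paste0(path, ".kinds")
  kinds <- NULL
  if (file.exists(kinds_path)) {
    spec <- utils::read.csv(kinds_path, header = FALSE,
                            stringsAsFactors = FALSE)
    kinds <- stats::setNames(spec[[2]], spec[[1]])
    kinds <- kinds[names(df)]
  }
  for (j in seq_along(df)) {
    to_num <- if (is.null(kinds)) {
      all(is.na(df[[j]]) | !is.na(suppressWarnings(as.numeric(df[[j]]))))
    } else {
      kinds[[j]] == "numeric"
    }
    if (to_num) df[[j]] <- as.numeric(df[[j]])
  }
  rownames(df) <- ids
  feature_table(df, kinds = kinds)
}

#' Read a longitudinal cohort
#'
#' Loads a cohort from two CSV files: an assessments file
#' (`patient_id,time_years,diagnosis`; one row per clinical visit) and a
#' baseline features file (`patient_id` plus one column per feature).  A
#' patient record is created for every patient appearing in both files whose
#' baseline (time 0, or earliest) diagnosis is MCI and who has at least one
#' follow-up visit at time > 0.  Other patients are dropped and reported in
#' the `dropped` attribute.  Diagnosis labels are normalised via a trimmed,
#' case-insensitive alias table ("AD" and "dementia" both map to DEMENTIA).
#'
#' @param assessments_path CSV of visits.
#' @param features_path CSV of baseline features.
#' @return A list of patient records (class `cohort`).  Each record has
#'   `patient_id`, `features` (one-row slice of the feature table) and
#'   `assessments` (data frame `time_years`, `diagnosis`, sorted by time).
#'   Attributes: `feature_table` (full table for retained patients),
#'   `dropped` (data frame of dropped patients with reasons).
#' @export
read_cohort <- function(assessments_path, features_path) {
  for (p in c(assessments_path, features_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  av <- utils::read.csv(assessments_path, check.names = FALSE,
                        na.strings = "", stringsAsFactors = FALSE)
  need <- c("patient_id", "time_years", "diagnosis")
  if (!all(need %in% names(av))) {
    stop(sprintf("%s: expected columns %s", assessments_path,
                 paste(need, collapse = ", ")))
  }
  av$time_years <- suppressWarnings(as.numeric(av$time_years))
  bad <- which(is.na(av$patient_id) | is.na(av$time_years) | av$time_years < 0)
  if (length(bad)) {
    stop(sprintf("%s: malformed row %d (non-numeric or negative time)",
                 assessments_path, bad[1] + 1L))
  }
  dup <- duplicated(av[c("patient_id", "time_years")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("%s: duplicate assessment for patient '%s' at time %g",
                 assessments_path, av$patient_id[i], av$time_years[i]))
  }
  av$diagnosis <- normalize_diagnosis(av$diagnosis)

  ft <- read_feature_table_with_id(features_path)
  feat_ids <- rownames(ft)
  asmt_ids <- unique(av$patient_id)

  dropped <- data.frame(patient_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(id, why) {
    dropped[nrow(dropped) + 1L, ] <<- list(id, why)
  }
  for (id in setdiff(feat_ids, asmt_ids)) drop(id, "no assessments")
  for (id in setdiff(asmt_ids, feat_ids)) drop(id, "no baseline features")

  records <- list()
  keep_ids <- character(0)
  for (id in intersect(feat_ids, asmt_ids)) {
    rows <- av[av$patient_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_years), , drop = FALSE]
    if (rows$diagnosis[1] != "MCI") {
      drop(id, "baseline diagnosis not MCI")
      next
    }
    fup <- rows[rows$time_years > 0, , drop = FALSE]
    if (nrow(fup) == 0) {
      drop(id, "no follow-up assessment")
      next
    }
    records[[id]] <- list(
      patient_id = id,
      features = ft[id, , drop = FALSE],
      assessments = data.frame(time_years = fup$time_years,
                               diagnosis = fup$diagnosis,
                               stringsAsFactors = FALSE)
    )
    keep_ids <- c(keep_ids, id)
  }
  cohort <- records[keep_ids]
  attr(cohort, "feature_table") <- ft[keep_ids, , drop = FALSE]
  attr(cohort, "dropped") <- dropped
  class(cohort) <- c("cohort", "list")
  cohort
}

# Feature CSV with patient_id as first column -> feature_table keyed by id.
read_feature_table_with_id <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                        stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) {
    stop(sprintf("%s: missing 'patient_id' column", path))
  }
  if (anyDuplicated(df$patient_id)) {
    stop(sprintf("%s: duplicate patient_id", path))
  }
  ids <- as.character(df$patient_id)
  df$patient_id <- NULL
  rownames(df) <- ids
  feature_table(df)
}

#' @export
`[.feature_table` <- function(x, i, j, ..., drop = FALSE) {
  kinds <- attr(x, "kinds")
  out <- NextMethod(drop = drop)
  if (is.data.frame(out)) {
    attr(out, "kinds") <- kinds[names(out)]
    class(out) <- c("feature_table", "data.frame")
  }
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, %d baseline features\n",
              length(x), ncol(attr(x, "feature_table"))))
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && nrow(dropped)) {
    cat(sprintf("  dropped at load: %d\n", nrow(dropped)))
  }
  invisible(x)
}
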