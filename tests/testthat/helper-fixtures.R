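# Fixtures are built in code at test time.

# Write a cohort CSV pair from a per-patient assessment list and a feature
# data frame; returns the two paths.
write_cohort_files <- function(assessments, features, dir = NULL) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  rows <- do.call(rbind, lapply(names(assessments), function(id) {
    a <- assessments[[id]]
    data.frame(patient_id = id, time_years = a$time_years,
               diagnosis = a$diagnosis, stringsAsFactors = FALSE)
  }))
  ap <- file.path(dir, "assessments.csv")
  fp <- file.path(dir, "features.csv")
  utils::write.csv(rows, ap, row.names = FALSE, na = "")
  utils::write.csv(features, fp, row.names = FALSE, na = "")
  c(assessments = ap, features = fp)
}

# In-memory cohort (skips the CSV layer) for labelling tests.
make_cohort <- function(assessments, features = NULL) {
  ids <- names(assessments)
  if (is.null(features)) {
    features <- data.frame(x = seq_along(ids), row.names = ids)
  }
  ft <- feature_table(features)
  records <- lapply(ids, function(id) {
    a <- assessments[[id]]
    list(patient_id = id, features = ft[id, , drop = FALSE],
         assessments = data.frame(time_years = a$time_years,
                                  diagnosis = a$diagnosis,
                                  stringsAsFactors = FALSE))
  })
  names(records) <- ids
  attr(records, "feature_table") <- ft
  attr(records, "dropped") <- data.frame(patient_id = character(0),
                                         reason = character(0))
  class(records) <- c("cohort", "list")
  records
}

# A patient record with given (time, diagnosis) pairs.
patient <- function(times, diagnoses) {
  list(time_years = times, diagnosis = diagnoses)
}

# The six-patient toy cohort used in the window-labelling tests:
# 2 converters by 2y, 2 stable beyond 4y, 1 converter first seen demented
# at 2.5y, 1 with a single 1y follow-up.
toy_cohort <- function() {
  make_cohort(list(
    c1 = patient(c(1.0, 2.0), c("MCI", "DEMENTIA")),
    c2 = patient(1.5, "DEMENTIA"),
    s1 = patient(c(2.0, 4.5), c("MCI", "MCI")),
    s2 = patient(c(1.0, 4.0), c("MCI", "MCI")),
    late = patient(2.5, "DEMENTIA"),
    short = patient(1.0, "MCI")
  ))
}

# Quick ranking object from an ordered feature vector.
ranking_of <- function(features, method = "TEST") {
  m <- length(features)
  fsestab:::new_feature_ranking(
    method, features,
    stats::setNames((m - seq_len(m) + 1) / m, features))
}

# Small fully numeric feature table with one perfectly separating feature.
separable_table <- function(n = 20, seed = 1) {
  set.seed(seed)
  labels <- rep(c("sMCI", "cMCI"), length.out = n)
  feature_table(data.frame(
    sep = ifelse(labels == "cMCI", 1, 0) + stats::rnorm(n, sd = 0.01),
    n1 = stats::rnorm(n),
    n2 = stats::rnorm(n),
    row.names = sprintf("e%02d", seq_len(n))
  )) -> tb
  list(table = tb, labels = labels)
}

# Independent brute-force evaluation of the chance-corrected subset
# similarity: count the intersection by explicit membership testing.
oracle_similarity <- function(a, b, m) {
  r <- sum(vapply(a, function(f) f %in% b, logical(1)))
  k <- length(a)
  (r * m - k^2) / (k * (m - k))
}
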