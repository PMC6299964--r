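#' Label a patient for a prediction time window
#'
#' Applies the time-window rule that turns a longitudinal MCI record into a
#' learning example for a fixed prognostic horizon:
#' \itemize{
#'   \item \strong{cMCI} (converter) if any follow-up with a dementia
#'     diagnosis occurs at or before `window_years`;
#'   \item \strong{sMCI} (stable) if the patient still carries an MCI
#'     diagnosis at or after the window limit;
#'   \item \strong{EXCLUDED} otherwise.  Two reasons are distinguished:
#'     `"conversion after window"` when the first dementia record falls
#'     beyond the horizon (the true conversion time within the window is
#'     unobservable), and `"insufficient follow-up"` when follow-up simply
#'     does not reach the window limit.
#' }
#' A patient first seen with dementia at 2.5 years is therefore cMCI for a
#' 3-year window but excluded from a 2-year window.  Boundary comparisons
#' use `<=`/`>=` on times rounded to 3 decimals.
#'
#' @param record a patient record from [read_cohort()] or
#'   [generate_cohort()].
#' @param window_years positive horizon in years.
#' @return A list with `label` (`"cMCI"`, `"sMCI"` or `"EXCLUDED"`) and
#'   `reason` (`NA` unless excluded).
#' @export
label_patient <- function(record, window_years) {
  stopifnot(is.numeric(window_years), window_years > 0)
  a <- record$assessments
  t <- round(a$time_years, 3)
  w <- round(window_years, 3)
  dem <- t[a$diagnosis == "DEMENTIA"]
  mci <- t[a$diagnosis == "MCI"]
  if (length(dem) && min(dem) <= w) {
    return(list(label = "cMCI", reason = NA_character_))
  }
  if (length(mci) && max(mci) >= w) {
    return(list(label = "sMCI", reason = NA_character_))
  }
  reason <- if (length(dem)) "conversion after window" else
    "insufficient follow-up"
  list(label = "EXCLUDED", reason = reason)
}

#' Build a windowed dataset
#'
#' Labels every patient in the cohort for one time window and assembles the
#' baseline features of the retained patients into a labelled dataset.
#'
#' @param cohort a `cohort` from [read_cohort()] or [generate_cohort()].
#' @param window_years positive horizon in years.
#' @return A list of class `windowed_dataset`: `table` (a
#'   [feature_table()] of labelled patients), `labels` (factor with levels
#'   `sMCI`, `cMCI`), `window_years`, and `excluded` (data frame
#'   `patient_id`, `reason`).
#' @export
build_windowed_dataset <- function(cohort, window_years) {
  stopifnot(length(cohort) > 0)
  labs <- vapply(cohort, function(r) label_patient(r, window_years)$label,
                 character(1))
  reasons <- vapply(cohort, function(r) {
    lp <- label_patient(r, window_years)
    if (is.na(lp$reason)) "" else lp$reason
  }, character(1))
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  keep <- labs %in% c("sMCI", "cMCI")
  if (!any(keep)) stop("empty windowed dataset: all patients excluded")
  ft <- attr(cohort, "feature_table")
  structure(list(
    table = ft[ids[keep], , drop = FALSE],
    labels = factor(labs[keep], levels = c("sMCI", "cMCI")),
    window_years = window_years,
    excluded = data.frame(patient_id = ids[!keep], reason = reasons[!keep],
                          stringsAsFactors = FALSE, row.names = NULL)
  ), class = "windowed_dataset")
}

#' Class balance of a windowed dataset
#'
#' @param labels factor or character vector of `sMCI`/`cMCI` labels.
#' @return A list with raw proportions (`prop_sMCI`, `prop_cMCI`, summing
#'   to 1) and the rounded integer percentages (`pct_sMCI`, `pct_cMCI`) in
#'   which class imbalance is conventionally reported.
#' @export
class_balance <- function(labels) {
  labels <- as.character(labels)
  stopifnot(length(labels) > 0)
  n <- length(labels)
  p_c <- sum(labels == "cMCI") / n
  p_s <- 1 - p_c
  list(prop_sMCI = p_s, prop_cMCI = p_c,
       pct_sMCI = round(100 * p_s), pct_cMCI = round(100 * p_c))
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cb <- class_balance(x$labels)
  cat(sprintf(
    "<windowed_dataset> %g-year window: %d examples (%d sMCI / %d cMCI, %d%%/%d%%), %d excluded\n",
    x$window_years, length(x$labels),
    sum(x$labels == "sMCI"), sum(x$labels == "cMCI"),
    cb$pct_sMCI, cb$pct_cMCI, nrow(x$excluded)))
  invisible(x)
}
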