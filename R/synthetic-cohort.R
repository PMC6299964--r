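#' Synthetic-cohort specification
#'
#' Parameters of the simulated longitudinal MCI cohort used to exercise
#' every pipeline stage with known ground truth.  The defaults describe
#' the reference study condition of the package: 400 patients, 50
#' mixed-type baseline features of which 10 are informative (standardized
#' effect 0.8), 10 redundant and 30 pure noise, 15% missing values
#' completely at random, annual follow-up out to 5 years.
#'
#' @param n_patients number of patients.
#' @param n_informative,n_redundant,n_noise feature counts; the total
#'   feature pool is their sum.
#' @param effect_size standardized association strength between the
#'   informative features and eventual conversion (per-feature logistic
#'   hazard slope scale; 0 means no signal).
#' @param redundancy_rho correlation in `[0, 1)` between each redundant
#'   feature and the informative feature it copies.
#' @param missing_rate MCAR missingness fraction in `[0, 1)`.
#' @param nominal_fraction fraction of features discretized into 3-level
#'   nominal categories.
#' @param followup_times scheduled follow-up visits in years.
#' @param conversion_base_rate per-visit conversion hazard of a patient at
#'   average risk.
#' @param dropout_rate per-visit probability of leaving the study after
#'   the first follow-up (irregular follow-up lengths).
#' @param seed integer seed; the cohort is a pure function of the spec.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients = 400, n_informative = 10,
                           n_redundant = 10, n_noise = 30,
                           effect_size = 0.8, redundancy_rho = 0.8,
                           missing_rate = 0.15, nominal_fraction = 0.2,
                           followup_times = 1:5,
                           conversion_base_rate = 0.10,
                           dropout_rate = 0.1, seed = 1L) {
  stopifnot(n_patients >= 1, n_informative >= 0, n_redundant >= 0,
            n_noise >= 0, n_informative + n_redundant + n_noise >= 1,
            redundancy_rho >= 0, redundancy_rho < 1,
            missing_rate >= 0, missing_rate < 1,
            nominal_fraction >= 0, nominal_fraction <= 1,
            length(followup_times) >= 1, all(followup_times > 0),
            conversion_base_rate > 0, conversion_base_rate < 1,
            dropout_rate >= 0, dropout_rate < 1)
  if (n_redundant > 0 && n_informative == 0) {
    stop("redundant features require at least one informative feature")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic longitudinal cohort
#'
#' Informative baseline features are standard normal; a latent risk score
#' is their standardized mean, and conversion is drawn from a discrete-time
#' logistic hazard at each scheduled visit,
#' `h = plogis(qlogis(base_rate) + effect_size * sqrt(n_informative) * risk)`,
#' so the hazard increases with risk and the induced per-feature
#' standardized group shift between converters and non-converters is of
#' order `effect_size`.  Redundant features are `rho`-correlated copies of
#' informative ones; noise features are independent.  Visit times are
#' jittered (up to ±0.1 y) for schedule irregularity, a geometric dropout
#' truncates follow-up (every patient keeps at least one follow-up visit),
#' a fixed fraction of features is discretized into low/mid/high nominal
#' categories, and missing cells are inserted completely at random.  The
#' diagnosis is DEMENTIA from the first visit at or after the conversion
#' visit, MCI otherwise.
#'
#' @param spec a [synthetic_spec()].
#' @return A `cohort` (see [read_cohort()]) with attribute `ground_truth`:
#'   list with `informative_features` and `conversion_time` (named vector,
#'   `Inf` for never-converters; the time of the first dementia visit).
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  p_inf <- spec$n_informative; p_red <- spec$n_redundant
  p_noi <- spec$n_noise
  ids <- sprintf("P%04d", seq_len(n))

  inf_names <- if (p_inf) sprintf("npt_inf_%02d", seq_len(p_inf)) else character(0)
  red_names <- if (p_red) sprintf("npt_red_%02d", seq_len(p_red)) else character(0)
  noi_names <- if (p_noi) sprintf("npt_noise_%02d", seq_len(p_noi)) else character(0)
  feats <- c(inf_names, red_names, noi_names)

  Xinf <- matrix(stats::rnorm(n * p_inf), n, p_inf, dimnames = list(ids, inf_names))
  Xred <- if (p_red) {
    src <- Xinf[, rep_len(seq_len(p_inf), p_red), drop = FALSE]
    rho <- spec$redundancy_rho
    m <- rho * src + sqrt(1 - rho^2) * matrix(stats::rnorm(n * p_red), n, p_red)
    dimnames(m) <- list(ids, red_names)
    m
  } else NULL
  Xnoi <- if (p_noi) {
    matrix(stats::rnorm(n * p_noi), n, p_noi, dimnames = list(ids, noi_names))
  } else NULL
  X <- cbind(Xinf, Xred, Xnoi)

  # latent risk and discrete-time conversion hazard at scheduled visits
  risk <- if (p_inf) {
    r <- rowMeans(Xinf)
    (r - mean(r)) / stats::sd(r)
  } else rep(0, n)
  slope <- spec$effect_size * sqrt(max(p_inf, 1))
  hazard <- stats::plogis(stats::qlogis(spec$conversion_base_rate) +
                            slope * risk)
  sched <- sort(spec$followup_times)
  nv <- length(sched)
  conv_visit <- rep(Inf, n)
  for (v in seq_len(nv)) {
    newly <- is.infinite(conv_visit) & (stats::runif(n) < hazard)
    conv_visit[newly] <- v
  }

  # irregular schedules: jitter + geometric dropout (>= 1 follow-up kept)
  jit <- matrix(stats::runif(n * nv, -0.1, 0.1), n, nv)
  n_visits <- 1 + stats::rgeom(n, spec$dropout_rate)
  n_visits <- pmin(pmax(n_visits, 1), nv)
  # converters remain observed through their conversion visit
  n_visits <- pmax(n_visits, ifelse(is.finite(conv_visit), conv_visit, 1))

  # nominal discretization of a seeded random subset of features
  n_nom <- floor(spec$nominal_fraction * length(feats))
  nominal <- sort(sample(feats, n_nom))
  df <- as.data.frame(X[, feats, drop = FALSE])
  for (f in nominal) {
    q <- stats::quantile(df[[f]], c(1 / 3, 2 / 3))
    df[[f]] <- c("low", "mid", "high")[findInterval(df[[f]], q) + 1]
  }

  # MCAR missingness
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * length(feats)) < spec$missing_rate,
                   n, length(feats))
    for (j in seq_along(feats)) df[[j]][mask[, j]] <- NA
  }
  ft <- feature_table(df)

  records <- vector("list", n)
  names(records) <- ids
  conv_time <- stats::setNames(rep(Inf, n), ids)
  for (i in seq_len(n)) {
    vis <- seq_len(n_visits[i])
    times <- round(pmax(sched[vis] + jit[i, vis], 0.1), 3)
    times <- sort(times)
    diag <- ifelse(vis >= conv_visit[i], "DEMENTIA", "MCI")
    if (is.finite(conv_visit[i])) {
      conv_time[i] <- times[conv_visit[i]]
    }
    records[[i]] <- list(
      patient_id = ids[i],
      features = ft[ids[i], , drop = FALSE],
      assessments = data.frame(time_years = times, diagnosis = diag,
                               stringsAsFactors = FALSE)
    )
  }
  cohort <- records
  attr(cohort, "feature_table") <- ft
  attr(cohort, "dropped") <- data.frame(patient_id = character(0),
                                        reason = character(0))
  attr(cohort, "ground_truth") <- list(
    informative_features = inf_names,
    conversion_time = conv_time
  )
  class(cohort) <- c("cohort", "list")
  cohort
}

#' Write a synthetic cohort fixture to disk
#'
#' Emits the two cohort CSVs (assessments and baseline features) readable
#' by [read_cohort()], plus a ground-truth JSON with the informative
#' feature names and each patient's conversion time.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(spec)
  gt <- attr(cohort, "ground_truth")
  asmt <- do.call(rbind, lapply(cohort, function(r) {
    data.frame(patient_id = r$patient_id,
               time_years = r$assessments$time_years,
               diagnosis = r$assessments$diagnosis,
               stringsAsFactors = FALSE)
  }))
  # baseline rows make the MCI-at-baseline contract explicit in the file
  base <- data.frame(patient_id = names(cohort), time_years = 0,
                     diagnosis = "MCI", stringsAsFactors = FALSE)
  asmt <- rbind(base, asmt)
  asmt <- asmt[order(asmt$patient_id, asmt$time_years), ]
  paths <- c(assessments = file.path(out_dir, "assessments.csv"),
             features = file.path(out_dir, "features.csv"),
             ground_truth = file.path(out_dir, "ground_truth.json"))
  utils::write.csv(asmt, paths[["assessments"]], row.names = FALSE, na = "")
  ft <- attr(cohort, "feature_table")
  fdf <- cbind(patient_id = rownames(ft), as.data.frame(ft))
  utils::write.csv(fdf, paths[["features"]], row.names = FALSE, na = "")
  jsonlite::write_json(
    list(informative_features = gt$informative_features,
         conversion_time = as.list(ifelse(is.finite(gt$conversion_time),
                                          gt$conversion_time, -1))),
    paths[["ground_truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
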