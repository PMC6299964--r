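#' Cross-validation configuration
#'
#' Settings of the full repeated-CV experiment.  The defaults mirror the
#' package's reference protocol: 10 repetitions of stratified 5-fold CV,
#' ensemble of the six stable base selectors (SVM-RFE is screened out of
#' the default ensemble for its unstable rankings), RPT betas 0.1/1/10,
#' missing-value threshold 0.20 and SMOTE gate 0.70.
#'
#' @param repetitions fold-randomisation repetitions (default 10).
#' @param folds stratified CV folds (default 5).
#' @param master_seed integer; the whole experiment is a pure function of
#'   the cohort and this seed.
#' @param windows time windows in years.
#' @param betas RPT weights.
#' @param classifiers list of [classifier_spec()]s.
#' @param fs_methods base ranking methods joining the ensemble.
#' @param missing_threshold,smote_gate,smote_k preprocessing settings.
#' @param perf a [perf_config()].
#' @param compare_base_methods also run every base method alone (and the
#'   all-features baseline) through the same wrapper for comparison.
#' @return List of class `cv_config`.
#' @export
cv_config <- function(repetitions = 10, folds = 5, master_seed = 1L,
                      windows = c(2, 3, 4), betas = c(0.1, 1, 10),
                      classifiers = list(classifier_spec("NB")),
                      fs_methods = c("RELIEFF", "MIM", "CMIM", "MRMR",
                                     "CHI2", "LL21"),
                      missing_threshold = 0.20, smote_gate = 0.70,
                      smote_k = 5, perf = perf_config(),
                      compare_base_methods = TRUE) {
  stopifnot(repetitions >= 1, folds >= 2)
  if (inherits(classifiers, "classifier_spec")) classifiers <- list(classifiers)
  names(classifiers) <- vapply(classifiers, `[[`, character(1), "kind")
  structure(list(repetitions = repetitions, folds = folds,
                 master_seed = as.integer(master_seed), windows = windows,
                 betas = betas, classifiers = classifiers,
                 fs_methods = toupper(fs_methods),
                 missing_threshold = missing_threshold,
                 smote_gate = smote_gate, smote_k = smote_k, perf = perf,
                 compare_base_methods = compare_base_methods),
            class = "cv_config")
}

# Stratified fold assignment: within each class, a shuffled round-robin.
# Each fold's class proportions are within one example of the global ones.
stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(as.character(labels))) {
    idx <- which(as.character(labels) == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Per-(repetition, fold) child seeds derived from the master seed via a
# fixed counter scheme, kept within 32-bit integer range.
child_seed <- function(master_seed, rep, fold = 0L) {
  (as.integer(master_seed) * 1009L + rep * 101L + fold) %% .Machine$integer.max
}

#' Run the full feature-selection-ensemble experiment
#'
#' For each time window: builds the labelled dataset, then for every
#' repetition and stratified fold fits the leakage-safe preprocessing on
#' the training split only (missing-value filter, mean/mode imputation,
#' gated SMOTE), runs the base rankers on the processed training split,
#' aggregates them into the fold's consensus ranking, and finally
#' evaluates the stability/predictability wrapper curve for every
#' configured classifier.  Optionally each base method alone and the
#' all-features baseline go through the same folds for comparison.
#'
#' @param cohort a `cohort`.
#' @param config a [cv_config()].
#' @return List of class `experiment_result`, one entry per window, each
#'   with `dataset`, per-classifier per-selector curves, best-k choices
#'   per beta, the consensus ranking over all folds, the best
#'   (classifier, k) pair per beta, and the all-features baseline.
#' @export
run_experiment <- function(cohort, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  out <- list()
  for (w in config$windows) {
    wd <- tryCatch(build_windowed_dataset(cohort, w), error = function(e) NULL)
    if (is.null(wd) || min(table(wd$labels)) < 2) {
      warning(sprintf("window %g skipped: fewer than 2 examples per class", w))
      next
    }
    out[[paste0("window_", w)]] <- run_window(wd, config)
  }
  if (length(out) == 0) stop("no window produced a usable dataset")
  structure(out, class = "experiment_result", config = config)
}

run_window <- function(wd, config) {
  m_pool <- ncol(wd$table)
  folds <- list()
  selector_rankings <- list(ENSEMBLE = list())
  base_methods <- if (config$compare_base_methods) config$fs_methods else character(0)
  for (mth in base_methods) selector_rankings[[mth]] <- list()

  fi <- 0L
  for (rep in seq_len(config$repetitions)) {
    assign_seed <- child_seed(config$master_seed, rep)
    fold_id <- stratified_folds(wd$labels, config$folds, assign_seed)
    for (f in seq_len(config$folds)) {
      fi <- fi + 1L
      te <- fold_id == f
      tr_tab <- wd$table[!te, , drop = FALSE]
      tr_lab <- as.character(wd$labels[!te])
      te_tab <- wd$table[te, , drop = FALSE]
      te_lab <- as.character(wd$labels[te])

      kept <- fit_missing_filter(tr_tab, config$missing_threshold)
      state <- fit_imputer(tr_tab[, kept, drop = FALSE])
      tr_imp <- apply_imputer(state, tr_tab)
      te_imp <- apply_imputer(state, te_tab)
      fseed <- child_seed(config$master_seed, rep, f)
      if (length(unique(tr_lab)) > 1 &&
          smote_needed(tr_lab, config$smote_gate)) {
        sm <- apply_smote(tr_imp, tr_lab, seed = fseed, k = config$smote_k)
        tr_imp <- sm$table
        tr_lab <- sm$labels
      }
      folds[[fi]] <- list(train = tr_imp, train_labels = tr_lab,
                          test = te_imp, test_labels = te_lab)

      base <- lapply(config$fs_methods, function(mth) {
        rank_features(mth, tr_imp, tr_lab, seed = fseed)
      })
      names(base) <- config$fs_methods
      selector_rankings$ENSEMBLE[[fi]] <- mean_rank_aggregate(base)
      for (mth in base_methods) selector_rankings[[mth]][[fi]] <- base[[mth]]
    }
  }

  # folds may keep different feature sets (per-fold missing-value filter);
  # complete each fold ranking to the full pool before the cross-fold
  # consensus, placing a fold's filtered-out features at the tail
  pool <- names(wd$table)
  consensus <- mean_rank_aggregate(
    lapply(selector_rankings$ENSEMBLE, complete_ranking, pool = pool))
  selectors <- list()
  for (sel in names(selector_rankings)) {
    curves <- list()
    for (cl in names(config$classifiers)) {
      curves[[cl]] <- wrapper_curve(selector_rankings[[sel]], folds,
                                    config$classifiers[[cl]],
                                    config = config$perf,
                                    betas = config$betas, m_pool = m_pool)
    }
    best_k <- lapply(curves, function(cv) {
      stats::setNames(vapply(config$betas, function(b) select_best_k(cv, b),
                             numeric(1)),
                      paste0("beta_", config$betas))
    })
    selectors[[sel]] <- list(curves = curves, best_k = best_k)
  }

  # all-features baseline: full table through the same folds
  baseline <- list()
  for (cl in names(config$classifiers)) {
    nf <- length(folds)
    met <- matrix(NA_real_, nf, 4,
                  dimnames = list(NULL, c("auc", "sens", "spec", "perf")))
    for (j in seq_len(nf)) {
      fold <- folds[[j]]
      res <- tryCatch(fit_and_score(config$classifiers[[cl]], fold$train,
                                    fold$train_labels, fold$test),
                      error = function(e) NULL)
      if (is.null(res)) next
      met[j, "auc"] <- auc_score(res$score, fold$test_labels)
      ss <- sens_spec(res$pred, fold$test_labels)
      met[j, "sens"] <- ss[["sensitivity"]]
      met[j, "spec"] <- ss[["specificity"]]
      met[j, "perf"] <- performance_score(met[j, "auc"], met[j, "sens"],
                                          met[j, "spec"], config$perf)
    }
    baseline[[cl]] <- list(
      auc = mean(met[, "auc"], na.rm = TRUE),
      sensitivity = mean(met[, "sens"], na.rm = TRUE),
      specificity = mean(met[, "spec"], na.rm = TRUE),
      performance = performance_score(mean(met[, "auc"], na.rm = TRUE),
                                      mean(met[, "sens"], na.rm = TRUE),
                                      mean(met[, "spec"], na.rm = TRUE),
                                      config$perf),
      n_features = m_pool,
      perf_folds = met[, "perf"]
    )
  }

  best_pair <- lapply(config$betas, function(b) {
    select_best_pair(selectors$ENSEMBLE$curves, b, consensus)
  })
  names(best_pair) <- paste0("beta_", config$betas)

  list(dataset = wd, folds_n = length(folds), consensus = consensus,
       selectors = selectors, baseline = baseline, best_pair = best_pair,
       m_pool = m_pool)
}

#' Compare selectors with Friedman and Wilcoxon tests
#'
#' Builds aligned per-fold composite-performance vectors for each selector
#' (at its own RPT-chosen subset size) plus the all-features baseline, runs
#' a Friedman test across them, and -- when it is significant at 0.05 --
#' pairwise Wilcoxon signed-rank tests of the ensemble against every other
#' selector with Bonferroni correction.  With exactly two selectors the
#' Friedman test is skipped and a single Wilcoxon test is run.
#'
#' @param window_result one window's entry of an `experiment_result`.
#' @param classifier classifier kind to compare on.
#' @param beta RPT weight fixing each selector's subset size.
#' @param alpha significance level (default 0.05).
#' @return List with `friedman` (htest or NULL), `pairwise` (data frame of
#'   ensemble-vs-other tests with raw and Bonferroni-corrected p-values and
#'   direction), and the `performance` matrix (folds x selectors).
#' @export
compare_selectors <- function(window_result, classifier = NULL, beta = 10,
                              alpha = 0.05) {
  sels <- names(window_result$selectors)
  if (is.null(classifier)) {
    classifier <- names(window_result$selectors$ENSEMBLE$curves)[1]
  }
  cols <- lapply(sels, function(sel) {
    entry <- window_result$selectors[[sel]]
    k <- entry$best_k[[classifier]][[paste0("beta_", beta)]]
    pf <- attr(entry$curves[[classifier]], "perf_folds")
    pf[, k]
  })
  names(cols) <- sels
  if (!is.null(window_result$baseline[[classifier]])) {
    cols$ALL_FEATURES <- window_result$baseline[[classifier]]$perf_folds
  }
  lens <- lengths(cols)
  if (length(unique(lens)) != 1) stop("misaligned per-fold metric vectors")
  perf <- do.call(cbind, cols)
  perf <- perf[stats::complete.cases(perf), , drop = FALSE]

  friedman <- NULL
  run_pairwise <- FALSE
  if (ncol(perf) >= 3) {
    if (all(apply(perf, 1, function(r) length(unique(r)) == 1))) {
      # identical vectors: trivially non-significant, test undefined
      friedman <- list(p.value = 1, statistic = NA_real_)
    } else {
      friedman <- stats::friedman.test(perf)
    }
    run_pairwise <- friedman$p.value < alpha
  } else if (ncol(perf) == 2) {
    run_pairwise <- TRUE
  }

  pairwise <- NULL
  if (run_pairwise) {
    others <- setdiff(colnames(perf), "ENSEMBLE")
    n_comp <- length(others)
    rows <- lapply(others, function(other) {
      d <- perf[, "ENSEMBLE"] - perf[, other]
      wt <- if (all(d == 0)) list(statistic = NA_real_, p.value = 1) else {
        suppressWarnings(stats::wilcox.test(perf[, "ENSEMBLE"], perf[, other],
                                            paired = TRUE))
      }
      data.frame(comparison = paste0("ENSEMBLE vs ", other),
                 statistic = unname(wt$statistic),
                 p_raw = wt$p.value,
                 p_bonferroni = min(1, wt$p.value * n_comp),
                 direction = ifelse(mean(d) > 0, "ensemble higher",
                                    ifelse(mean(d) < 0, "ensemble lower",
                                           "tied")),
                 stringsAsFactors = FALSE)
    })
    pairwise <- do.call(rbind, rows)
  }
  list(friedman = friedman, pairwise = pairwise, performance = perf,
       classifier = classifier, beta = beta)
}

#' Consensus feature report across windows
#'
#' For each window, the consensus ranking truncated at the RPT-chosen
#' subset size of the winning classifier; features appearing in the chosen
#' subset of every window are flagged as common, with their per-window
#' ranking positions listed.
#'
#' @param result an `experiment_result`.
#' @param beta RPT weight (default 10).
#' @return List with `per_window` (named list of data frames
#'   `feature, position`) and `common` (data frame of features shared by
#'   all windows, with one position column per window).
#' @export
feature_report <- function(result, beta = 10) {
  per_window <- list()
  for (wn in names(result)) {
    wr <- result[[wn]]
    bp <- wr$best_pair[[paste0("beta_", beta)]]
    feats <- bp$features
    per_window[[wn]] <- data.frame(
      feature = feats,
      position = wr$consensus$positions[feats],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  common_feats <- Reduce(intersect, lapply(per_window, `[[`, "feature"))
  common <- data.frame(feature = common_feats, stringsAsFactors = FALSE)
  for (wn in names(per_window)) {
    common[[wn]] <- result[[wn]]$consensus$positions[common_feats]
  }
  list(per_window = per_window, common = common)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d window(s)\n", length(x)))
  for (wn in names(x)) {
    wr <- x[[wn]]
    bp <- wr$best_pair[[length(wr$best_pair)]]
    cat(sprintf("  %s: %d examples, best pair %s with k = %d (RPT %.3f)\n",
                wn, length(wr$dataset$labels), bp$classifier, bp$k, bp$rpt))
  }
  invisible(x)
}
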