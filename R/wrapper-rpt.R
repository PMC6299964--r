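#' Composite classification performance
#'
#' The predictability score
#' \deqn{performance = \alpha\, AUC + \gamma\, F(sens, spec)}
#' with `F` either the minimum (default: targets the weaker of the two
#' class-conditional accuracies, appropriate under class imbalance) or the
#' mean.  `alpha` and `gamma` are non-negative with `alpha + gamma <= 1`;
#' the defaults `alpha = gamma = 0.5` weight discrimination and the
#' sensitivity/specificity balance equally.
#'
#' @param auc,sensitivity,specificity metrics in `[0, 1]`.
#' @param config a [perf_config()].
#' @return Composite score in `[0, alpha + gamma]`.
#' @export
performance_score <- function(auc, sensitivity, specificity,
                              config = perf_config()) {
  stopifnot(inherits(config, "perf_config"))
  for (v in c(auc, sensitivity, specificity)) {
    if (!is.na(v) && (v < 0 || v > 1)) stop("metrics must lie in [0, 1]")
  }
  f <- switch(config$combiner, MIN = pmin, MEAN = function(a, b) (a + b) / 2)
  config$alpha * auc + config$gamma * f(sensitivity, specificity)
}

#' @rdname performance_score
#' @param alpha,gamma non-negative weights with `alpha + gamma <= 1`.
#' @param combiner `"MIN"` or `"MEAN"`.
#' @export
perf_config <- function(alpha = 0.5, gamma = 0.5,
                        combiner = c("MIN", "MEAN")) {
  combiner <- match.arg(combiner)
  if (alpha < 0 || gamma < 0 || alpha + gamma > 1) {
    stop("need alpha >= 0, gamma >= 0 and alpha + gamma <= 1")
  }
  structure(list(alpha = alpha, gamma = gamma, combiner = combiner),
            class = "perf_config")
}

#' Robustness-performance trade-off (RPT)
#'
#' F-measure-style combination of selection stability and predictability,
#' \deqn{RPT = \frac{(\beta^2 + 1)\, s\, p}{\beta^2 s + p},}
#' lying between `min(s, p)` and `max(s, p)`.  `beta = 1` is the harmonic
#' mean; small `beta` weights stability, large `beta` weights
#' classification performance.  Non-positive stability (possible for the
#' chance-corrected Kuncheva index) or zero predictability makes the ratio
#' ill-behaved; the score is then reported as 0 with a warning rather than
#' clipped.
#'
#' @param stability stability score (Kuncheva-index based).
#' @param predictability composite performance score.
#' @param beta positive trade-off weight.
#' @return RPT score.
#' @export
rpt_score <- function(stability, predictability, beta) {
  stopifnot(beta > 0)
  if (is.na(stability) || is.na(predictability)) return(NA_real_)
  if (stability <= 0 || predictability <= 0) {
    warning("non-positive stability or predictability; RPT reported as 0")
    return(0)
  }
  ((beta^2 + 1) * stability * predictability) /
    (beta^2 * stability + predictability)
}

#' Stability/predictability curve over nested subset sizes
#'
#' For each subset size `k = 1, ..., m`, trains the classifier on each
#' fold's training split restricted to that fold's top-`k` ranked features,
#' evaluates AUC, sensitivity and specificity on the fold's test split, and
#' averages across folds.  Stability at `k` is the collection stability of
#' the folds' top-`k` subsets.  The composite performance and the RPT score
#' at each requested `beta` complete the per-`k` evaluation.
#'
#' @param fold_rankings list of per-fold `feature_ranking`s (ranking `j`
#'   fitted on fold `j`'s training split).
#' @param folds list of folds, each `list(train, train_labels, test,
#'   test_labels)` with fully imputed tables.
#' @param classifier a [classifier_spec()].
#' @param config a [perf_config()].
#' @param betas numeric vector of RPT weights (default `c(0.1, 1, 10)`).
#' @param m_pool feature-pool size for the stability index (defaults to
#'   the ranking length).
#' @return A data frame (class `subset_curve`) with one row per `k`:
#'   `k, auc, sensitivity, specificity, performance, stability` and one
#'   `rpt_<beta>` column per beta.  Attribute `perf_folds` holds the
#'   per-fold composite performance matrix (folds x k) used for paired
#'   statistical tests.
#' @export
wrapper_curve <- function(fold_rankings, folds, classifier,
                          config = perf_config(), betas = c(0.1, 1, 10),
                          m_pool = NULL) {
  stopifnot(length(fold_rankings) == length(folds))
  m <- min(vapply(fold_rankings, function(r) length(r$features), integer(1)))
  if (m < 2) stop("wrapper_curve() needs at least 2 ranked features")
  if (is.null(m_pool)) m_pool <- length(fold_rankings[[1]]$features)
  nf <- length(folds)
  met <- array(NA_real_, c(nf, m, 3),
               dimnames = list(NULL, NULL, c("auc", "sens", "spec")))
  for (j in seq_len(nf)) {
    fold <- folds[[j]]
    rk <- fold_rankings[[j]]
    for (k in seq_len(m)) {
      sel <- top_k(rk, k)
      res <- tryCatch(
        fit_and_score(classifier, fold$train[, sel, drop = FALSE],
                      fold$train_labels,
                      fold$test[, sel, drop = FALSE]),
        error = function(e) {
          warning(sprintf("fold %d, k = %d: classifier failed (%s); fold skipped",
                          j, k, conditionMessage(e)))
          NULL
        })
      if (is.null(res)) next
      met[j, k, "auc"] <- auc_score(res$score, fold$test_labels)
      ss <- sens_spec(res$pred, fold$test_labels)
      met[j, k, "sens"] <- ss[["sensitivity"]]
      met[j, k, "spec"] <- ss[["specificity"]]
    }
  }
  if (all(is.na(met))) stop("classifier failed on every fold")
  stab <- vapply(seq_len(m), function(k) {
    collection_stability(lapply(fold_rankings, top_k, k = k), m_pool,
                         warn = FALSE)
  }, numeric(1))
  auc <- colMeans(matrix(met[, , "auc"], nrow = nf), na.rm = TRUE)
  sens <- colMeans(matrix(met[, , "sens"], nrow = nf), na.rm = TRUE)
  spec <- colMeans(matrix(met[, , "spec"], nrow = nf), na.rm = TRUE)
  perf <- performance_score(auc, sens, spec, config)
  curve <- data.frame(k = seq_len(m), auc = auc, sensitivity = sens,
                      specificity = spec, performance = perf,
                      stability = stab)
  for (b in betas) {
    curve[[rpt_col(b)]] <- vapply(seq_len(m), function(k) {
      suppressWarnings(rpt_score(stab[k], perf[k], b))
    }, numeric(1))
  }
  perf_folds <- matrix(NA_real_, nf, m)
  for (j in seq_len(nf)) {
    perf_folds[j, ] <- performance_score(met[j, , "auc"], met[j, , "sens"],
                                         met[j, , "spec"], config)
  }
  attr(curve, "perf_folds") <- perf_folds
  attr(curve, "betas") <- betas
  class(curve) <- c("subset_curve", "data.frame")
  curve
}

rpt_col <- function(beta) paste0("rpt_", format(beta, trim = TRUE))

#' Best subset size under the RPT criterion
#'
#' @param curve a [wrapper_curve()] result.
#' @param beta which RPT column to maximise.
#' @return The `k` with maximal RPT; ties resolve to the smallest `k`.
#' @export
select_best_k <- function(curve, beta) {
  col <- rpt_col(beta)
  if (!col %in% names(curve)) {
    stop(sprintf("curve has no RPT column for beta = %g", beta))
  }
  v <- curve[[col]]
  curve$k[which.max(v)]
}

#' Best (classifier, subset size) pair
#'
#' Compares the RPT-optimal point of each classifier's curve and returns
#' the winning pair together with the consensus feature subset of that
#' size.  Ties resolve by the fixed classifier order NB, LOGREG, SVM_RBF,
#' SVM_POLY, DT, then by smaller `k`.
#'
#' @param curves named list (classifier kind -> `subset_curve`).
#' @param beta RPT weight used for the comparison.
#' @param consensus_ranking the `feature_ranking` aggregated over all
#'   folds' rankings, from which the returned subset is drawn.
#' @return List with `classifier`, `k`, `rpt` and `features`.
#' @export
select_best_pair <- function(curves, beta, consensus_ranking) {
  stopifnot(length(curves) >= 1)
  rows <- lapply(names(curves), function(cl) {
    k <- select_best_k(curves[[cl]], beta)
    data.frame(classifier = cl, k = k,
               rpt = curves[[cl]][[rpt_col(beta)]][curves[[cl]]$k == k],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$ord <- match(tab$classifier, classifier_tie_order)
  tab <- tab[order(-tab$rpt, tab$ord, tab$k), ]
  best <- tab[1, ]
  list(classifier = best$classifier, k = best$k, rpt = best$rpt,
       features = top_k(consensus_ranking, best$k))
}
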