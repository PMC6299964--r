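#' Aggregate feature rankings by mean position
#'
#' Combines several rankings over the same feature pool into a consensus
#' ranking.  Each feature's consensus score is the arithmetic mean of its
#' 1-based positions across the input rankings; features are ordered by
#' ascending mean position (ties broken by ascending feature name).  The
#' emitted weights are `(m - mean_position + 1) / m`, so higher weight
#' means more relevant.
#'
#' Median and maximum position aggregators are available via `stat` for
#' completeness; the mean is the default and the only one tuned here.
#'
#' @param rankings list of `feature_ranking` objects sharing one feature
#'   set.
#' @param stat `"mean"` (default), `"median"` or `"max"` position
#'   aggregation.
#' @return A consensus `feature_ranking` (method `"ENSEMBLE"`).
#' @export
mean_rank_aggregate <- function(rankings, stat = c("mean", "median", "max")) {
  stat <- match.arg(stat)
  stopifnot(length(rankings) >= 1)
  pool <- sort(rankings[[1]]$features)
  for (r in rankings) {
    if (!setequal(r$features, pool)) {
      stop("rankings do not share the same feature pool")
    }
  }
  pos <- sapply(rankings, function(r) r$positions[pool])
  pos <- matrix(pos, nrow = length(pool), dimnames = list(pool, NULL))
  agg <- apply(pos, 1, switch(stat, mean = mean, median = stats::median,
                              max = max))
  ord <- order(agg, pool)
  m <- length(pool)
  w <- (m - agg + 1) / m
  new_feature_ranking("ENSEMBLE", pool[ord],
                      stats::setNames(w, pool)[ord])
}

# Extend a ranking to a larger pool: absent features are appended after
# the ranked ones, in name order.
complete_ranking <- function(ranking, pool) {
  missing <- sort(setdiff(pool, ranking$features))
  if (length(missing) == 0) return(ranking)
  feats <- c(ranking$features, missing)
  m <- length(feats)
  w <- c(ranking$weights * (length(ranking$features) / m),
         stats::setNames(rep(0, length(missing)), missing))
  new_feature_ranking(ranking$method, feats, w)
}

#' Top-k feature subset of a ranking
#'
#' @param ranking a `feature_ranking`.
#' @param k subset size, `1 <= k <= m`.
#' @return Character vector of the `k` best-ranked features.
#' @export
top_k <- function(ranking, k) {
  m <- length(ranking$features)
  if (!(is.numeric(k) && k >= 1 && k <= m)) {
    stop(sprintf("k must be in [1, %d]", m))
  }
  ranking$features[seq_len(k)]
}
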