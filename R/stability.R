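#' Kuncheva similarity between two equal-size feature subsets
#'
#' The chance-corrected similarity between two subsets of size `k` drawn
#' from a pool of `m` features,
#' \deqn{Sim(A, B) = \frac{r m - k^2}{k (m - k)},}
#' where `r` is the size of the intersection.  The index is bounded by
#' \eqn{[-1, 1]}; identical subsets score 1, and independently drawn random
#' subsets score 0 in expectation.  The index requires `|A| = |B|`; for the
#' degenerate sizes `k = 0` and `k = m` (where the subsets are forced
#' equal) it is defined as 1 by convention, with a warning.
#'
#' @param a,b character vectors (feature subsets) of equal size.
#' @param m feature-pool size.
#' @return Similarity in `[-1, 1]`.
#' @export
kuncheva_similarity <- function(a, b, m) {
  a <- unique(a); b <- unique(b)
  k <- length(a)
  if (length(b) != k) {
    stop("kuncheva_similarity() requires subsets of equal cardinality")
  }
  stopifnot(k <= m)
  if (k == 0 || k == m) {
    warning(sprintf("similarity undefined at k = %d with m = %d; ",
                    k, m), "returning 1 by convention")
    return(1)
  }
  r <- length(intersect(a, b))
  (r * m - k^2) / (k * (m - k))
}

#' Stability of a collection of feature subsets
#'
#' The mean Kuncheva similarity over all \eqn{n(n-1)/2} unordered pairs of
#' `n` equal-size subsets -- the selection-stability score of a feature
#' selector across cross-validation folds.
#'
#' @param subsets list of `n >= 2` character vectors of identical size.
#' @param m feature-pool size.
#' @param warn emit the degenerate-size warning of
#'   [kuncheva_similarity()] (once).
#' @return Stability in `[-1, 1]`.
#' @export
collection_stability <- function(subsets, m, warn = TRUE) {
  n <- length(subsets)
  stopifnot(n >= 2)
  sizes <- lengths(lapply(subsets, unique))
  if (length(unique(sizes)) != 1) {
    stop("collection_stability() requires subsets of identical size")
  }
  k <- sizes[1]
  if (k == 0 || k == m) {
    if (warn) {
      warning(sprintf("similarity undefined at k = %d with m = %d; ", k, m),
              "returning 1 by convention")
    }
    return(1)
  }
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      tot <- tot + kuncheva_similarity(subsets[[i]], subsets[[j]], m)
    }
  }
  tot / (n * (n - 1) / 2)
}

#' Self-stability profile of a ranking method
#'
#' Averages the collection stability of the method's top-`k` subsets across
#' folds over every informative subset size `k = 1, ..., m - 1` (the
#' degenerate sizes 0 and `m` are excluded, where the index is undefined).
#'
#' @param fold_rankings list of `feature_ranking`s, one per fold.
#' @param m feature-pool size (defaults to the ranking length).
#' @return Mean stability over subset sizes.
#' @export
method_stability_profile <- function(fold_rankings, m = NULL) {
  stopifnot(length(fold_rankings) >= 2)
  if (is.null(m)) m <- length(fold_rankings[[1]]$features)
  ks <- seq_len(m - 1)
  mean(vapply(ks, function(k) {
    collection_stability(lapply(fold_rankings, top_k, k = k), m)
  }, numeric(1)))
}

#' Pairwise stability between two ranking methods
#'
#' Mean Kuncheva similarity between the top-`k` subsets of two methods,
#' paired fold by fold and averaged over folds and over
#' `k = 1, ..., m - 1`.
#'
#' @param rankings_a,rankings_b per-fold rankings of the two methods.
#' @param m feature-pool size.
#' @return Mean cross-method similarity.
#' @export
pairwise_method_stability <- function(rankings_a, rankings_b, m = NULL) {
  stopifnot(length(rankings_a) == length(rankings_b))
  if (is.null(m)) m <- length(rankings_a[[1]]$features)
  ks <- seq_len(m - 1)
  mean(vapply(ks, function(k) {
    mean(mapply(function(ra, rb) {
      kuncheva_similarity(top_k(ra, k), top_k(rb, k), m)
    }, rankings_a, rankings_b))
  }, numeric(1)))
}

#' Stability report over a set of ranking methods
#'
#' Builds the method-by-method stability grid used to vet ensemble
#' members: self-stability on the diagonal, pairwise stability off it.
#'
#' @param method_rankings named list (method -> list of per-fold
#'   `feature_ranking`s).
#' @param m feature-pool size.
#' @return A list of class `stability_report` with the symmetric `grid`,
#'   `self` (named diagonal), `n_subsets` and `m`.
#' @export
stability_report <- function(method_rankings, m = NULL) {
  methods <- names(method_rankings)
  stopifnot(length(methods) >= 1)
  if (is.null(m)) m <- length(method_rankings[[1]][[1]]$features)
  p <- length(methods)
  grid <- matrix(NA_real_, p, p, dimnames = list(methods, methods))
  for (i in seq_len(p)) {
    grid[i, i] <- method_stability_profile(method_rankings[[i]], m)
    if (i < p) for (j in seq(i + 1, p)) {
      v <- pairwise_method_stability(method_rankings[[i]],
                                     method_rankings[[j]], m)
      grid[i, j] <- v
      grid[j, i] <- v
    }
  }
  structure(list(grid = grid, self = diag(grid),
                 n_subsets = length(method_rankings[[1]]), m = m),
            class = "stability_report")
}

#' Screen out unstable ranking methods
#'
#' Retains the methods whose self-stability reaches the cutoff.  A
#' selector whose top-`k` subsets disagree wildly across folds (as
#' recursive-elimination SVM rankings typically do) degrades the
#' robustness of a consensus ranking and is excluded before aggregation.
#'
#' @param profiles named numeric vector of self-stability scores.
#' @param cutoff minimum self-stability (default 0.5).
#' @return List with `included` and `excluded` (named scores).
#' @export
screen_unstable_methods <- function(profiles, cutoff = 0.5) {
  if (length(profiles) == 0) stop("no stability profiles supplied")
  keep <- profiles >= cutoff
  if (!any(keep)) stop("all methods fall below the stability cutoff")
  list(included = names(profiles)[keep],
       excluded = profiles[!keep])
}

#' @export
print.stability_report <- function(x, digits = 3, ...) {
  cat(sprintf("<stability_report> %d methods, %d subsets, m = %d\n",
              nrow(x$grid), x$n_subsets, x$m))
  print(round(x$grid, digits))
  invisible(x)
}
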