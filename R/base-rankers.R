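#' Ranking-based feature selectors
#'
#' Produces a total relevance ranking of all features by one of seven base
#' selectors commonly used in feature-selection ensembles:
#'
#' \describe{
#'   \item{MIM}{mutual information \eqn{I(X; y)} (information gain), in
#'     bits, on equal-frequency discretized features.}
#'   \item{CMIM}{conditional mutual information maximisation: iteratively
#'     adds the feature maximising \eqn{\min_{s \in S} I(X; y | X_s)}.}
#'   \item{MRMR}{minimum redundancy, maximum relevance: iteratively adds
#'     the feature maximising \eqn{I(X;y) - \mathrm{mean}_{s \in S} I(X; X_s)}.}
#'   \item{CHI2}{chi-squared statistic of the discretized feature against
#'     the class.}
#'   \item{RELIEFF}{neighbour-based relevance weights (10 nearest
#'     hits/misses, every example used as a reference point).}
#'   \item{SVM_RFE}{recursive feature elimination by squared linear-SVM
#'     weights (C = 1, one feature eliminated per iteration).}
#'   \item{LL21}{block norms of an l2,1-regularised logistic-loss solution
#'     fitted by proximal gradient descent.}
#' }
#'
#' Numeric features are discretized into `min(10, ceiling(sqrt(n)))`
#' equal-frequency bins for the information-theoretic and chi-squared
#' scores; nominal features are used as-is.  For the margin-based methods
#' (SVM_RFE, LL21) nominal features are one-hot expanded and scored by
#' their per-feature weight-block norm.  All score ties are broken by
#' ascending feature name, so every method is deterministic given `seed`.
#'
#' @param method one of `"RELIEFF"`, `"MIM"`, `"CMIM"`, `"MRMR"`,
#'   `"CHI2"`, `"SVM_RFE"`, `"LL21"`.
#' @param train a fully imputed [feature_table()].
#' @param labels two-class label vector aligned with `train`.
#' @param seed integer seed (consumed only by methods with a stochastic
#'   option, but accepted by all for a uniform interface).
#' @return A `feature_ranking`: list with `method`, `features` (ordered,
#'   best first), `positions` (named 1-based integer vector) and `weights`
#'   (named, in `[0, 1]`, non-increasing along the order).
#' @export
rank_features <- function(method, train, labels, seed = 1L) {
  method <- toupper(method)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("rank_features() requires a non-constant label vector")
  }
  stopifnot(nrow(train) == length(labels))
  if (anyNA(as.data.frame(train))) {
    stop("rank_features() requires fully imputed data")
  }
  feats <- names(train)
  scores <- switch(method,
    MIM     = score_mim(train, labels),
    CHI2    = score_chi2(train, labels),
    CMIM    = NULL,
    MRMR    = NULL,
    RELIEFF = score_relieff(train, labels, seed = seed),
    SVM_RFE = NULL,
    LL21    = score_ll21(train, labels),
    stop(sprintf("unknown ranking method '%s'", method))
  )
  if (method %in% c("CMIM", "MRMR")) {
    order_feats <- greedy_mi_order(train, labels, criterion = method)
    ranking_from_order(method, order_feats, length(feats))
  } else if (method == "SVM_RFE") {
    order_feats <- svm_rfe_order(train, labels)
    ranking_from_order(method, order_feats, length(feats))
  } else {
    ranking_from_scores(method, scores)
  }
}

#' List the available base selectors
#'
#' @param relieff_subsample logical; when reference-point subsampling is
#'   enabled for ReliefF its output depends on the seed.
#' @return Data frame with columns `method`, `weighted` (emits per-feature
#'   weights) and `stochastic` (seed-dependent under the current settings).
#' @export
available_methods <- function(relieff_subsample = FALSE) {
  data.frame(
    method = c("RELIEFF", "MIM", "CMIM", "MRMR", "CHI2", "SVM_RFE", "LL21"),
    weighted = TRUE,
    stochastic = c(isTRUE(relieff_subsample), FALSE, FALSE, FALSE,
                   FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

ranking_from_scores <- function(method, scores) {
  feats <- names(scores)
  ord <- order(-scores, feats)
  rng <- range(scores)
  w <- if (diff(rng) == 0) rep(1, length(scores)) else {
    (scores - rng[1]) / diff(rng)
  }
  new_feature_ranking(method, feats[ord], stats::setNames(w, feats)[ord])
}

ranking_from_order <- function(method, ordered_feats, m) {
  w <- (m - seq_len(m) + 1) / m
  new_feature_ranking(method, ordered_feats,
                      stats::setNames(w, ordered_feats))
}

new_feature_ranking <- function(method, ordered_feats, weights) {
  structure(list(
    method = method,
    features = ordered_feats,
    positions = stats::setNames(seq_along(ordered_feats), ordered_feats),
    weights = weights
  ), class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %s over %d features; top: %s\n",
              x$method, length(x$features),
              paste(utils::head(x$features, 5), collapse = ", ")))
  invisible(x)
}

# ---- discretization and information measures (bits) ------------------------

# Equal-frequency discretization into min(10, ceiling(sqrt(n))) bins.
discretize_ef <- function(x, n_bins = NULL) {
  n <- length(x)
  if (is.null(n_bins)) n_bins <- min(10, ceiling(sqrt(n)))
  if (!is.numeric(x)) return(as.character(x))
  ux <- unique(x)
  # already-discrete features (few distinct values) keep their own levels
  if (length(ux) <= n_bins) return(as.character(match(x, sort(ux))))
  breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE, type = 7))
  if (length(breaks) < 2) return(rep("b1", n))
  as.character(cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE))
}

discretize_table <- function(table) {
  kinds <- ft_kinds(table)
  out <- lapply(names(table), function(f) {
    if (kinds[[f]] == "numeric") discretize_ef(table[[f]])
    else as.character(table[[f]])
  })
  names(out) <- names(table)
  out
}

entropy_bits <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

mutual_info <- function(x, y) {
  entropy_bits(x) + entropy_bits(y) - entropy_bits(paste(x, y, sep = "\r"))
}

# I(X; Y | Z) = H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z)
cond_mutual_info <- function(x, y, z) {
  j <- function(...) paste(..., sep = "\r")
  entropy_bits(j(x, z)) + entropy_bits(j(y, z)) -
    entropy_bits(z) - entropy_bits(j(x, y, z))
}

score_mim <- function(train, labels) {
  disc <- discretize_table(train)
  vapply(disc, mutual_info, numeric(1), y = labels)
}

score_chi2 <- function(train, labels) {
  disc <- discretize_table(train)
  vapply(disc, function(x) {
    if (length(unique(x)) < 2) return(0)
    suppressWarnings(
      unname(stats::chisq.test(table(x, labels), correct = FALSE)$statistic))
  }, numeric(1))
}

# Greedy forward selection under the CMIM or MRMR criterion; returns the
# full selection order.
greedy_mi_order <- function(train, labels, criterion) {
  disc <- discretize_table(train)
  feats <- names(disc)
  m <- length(feats)
  relevance <- vapply(disc, mutual_info, numeric(1), y = labels)
  remaining <- feats
  selected <- character(0)
  # caches keyed "candidate\rselected"
  cmi_cache <- new.env(hash = TRUE)
  mi_cache <- new.env(hash = TRUE)
  # running criterion state
  cmim_min <- stats::setNames(relevance, feats)   # min over selected so far
  mrmr_red <- stats::setNames(rep(0, m), feats)   # sum of redundancies
  while (length(remaining) > 0) {
    crit <- if (criterion == "CMIM") {
      cmim_min[remaining]
    } else {
      k <- length(selected)
      relevance[remaining] -
        if (k == 0) 0 else mrmr_red[remaining] / k
    }
    pick <- remaining[order(-crit, remaining)][1]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0) {
      for (f in remaining) {
        if (criterion == "CMIM") {
          v <- cond_mutual_info(disc[[f]], labels, disc[[pick]])
          cmim_min[f] <- min(cmim_min[f], v)
        } else {
          mrmr_red[f] <- mrmr_red[f] + mutual_info(disc[[f]], disc[[pick]])
        }
      }
    }
  }
  selected
}

# ---- ReliefF ---------------------------------------------------------------

score_relieff <- function(train, labels, n_neighbors = 10, seed = 1L,
                          subsample = NULL) {
  kinds <- ft_kinds(train)
  n <- nrow(train)
  feats <- names(train)
  is_nom <- kinds[feats] == "nominal"
  # numeric features range-normalized to [0,1]; nominal features integer
  # coded, with difference defined as mismatch (0/1)
  Xn <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
  for (j in seq_along(feats)) {
    f <- feats[j]
    if (is_nom[j]) {
      Xn[, j] <- as.integer(factor(train[[f]]))
    } else {
      rng <- range(train[[f]])
      Xn[, j] <- if (diff(rng) == 0) 0 else (train[[f]] - rng[1]) / diff(rng)
    }
  }
  feat_diff <- function(i, idx) {
    d <- abs(Xn[idx, , drop = FALSE] -
               matrix(Xn[i, ], length(idx), length(feats), byrow = TRUE))
    if (any(is_nom)) d[, is_nom] <- (d[, is_nom] != 0) * 1
    d
  }
  # pairwise manhattan distance on the same representation (nominal
  # contributions are 0/1 mismatches)
  d <- matrix(0, n, n)
  for (j in seq_along(feats)) {
    col <- Xn[, j]
    dj <- abs(outer(col, col, "-"))
    if (is_nom[j]) dj <- (dj != 0) * 1
    d <- d + dj
  }
  refs <- seq_len(n)
  if (!is.null(subsample) && subsample < n) {
    set.seed(seed)
    refs <- sort(sample.int(n, subsample))
  }
  classes <- unique(labels)
  priors <- table(labels)[classes] / n
  w <- stats::setNames(rep(0, length(feats)), feats)
  for (i in refs) {
    same <- setdiff(which(labels == labels[i]), i)
    k_hit <- min(n_neighbors, length(same))
    if (k_hit > 0) {
      hits <- same[order(d[i, same])][seq_len(k_hit)]
      w <- w - colMeans(feat_diff(i, hits)) / length(refs)
    }
    for (cl in setdiff(classes, labels[i])) {
      other <- which(labels == cl)
      k_miss <- min(n_neighbors, length(other))
      misses <- other[order(d[i, other])][seq_len(k_miss)]
      wt <- priors[[cl]] / (1 - priors[[labels[i]]])
      w <- w + wt * colMeans(feat_diff(i, misses)) / length(refs)
    }
  }
  w
}

# ---- SVM-RFE ---------------------------------------------------------------

# Grouped one-hot design matrix, columns standardized for margin methods.
encode_groups <- function(table, standardize = TRUE) {
  enc <- one_hot_encode(table)
  X <- enc$matrix
  if (standardize) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0 | is.na(attr(X, "scaled:scale"))] <- 0
    X[is.na(X)] <- 0
  }
  groups <- lapply(enc$map, function(cols) match(cols, colnames(enc$matrix)))
  list(X = X, groups = groups)
}

svm_rfe_order <- function(train, labels, cost = 1) {
  enc <- encode_groups(train)
  y <- factor(labels)
  feats <- names(train)
  remaining <- feats
  eliminated <- character(0)
  while (length(remaining) > 1) {
    cols <- sort(unlist(enc$groups[remaining]))
    fit <- e1071::svm(x = enc$X[, cols, drop = FALSE], y = y,
                      kernel = "linear", cost = cost, scale = FALSE)
    wvec <- drop(t(fit$coefs) %*% fit$SV)
    names(wvec) <- colnames(enc$X)[cols]
    sc <- vapply(remaining, function(f) {
      sum(wvec[colnames(enc$X)[enc$groups[[f]]]]^2)
    }, numeric(1))
    # eliminate the weakest feature; ties by descending name so that the
    # final ranking breaks ties by ascending name
    worst <- remaining[order(sc, remaining, decreasing = c(FALSE, TRUE),
                             method = "radix")][1]
    eliminated <- c(worst, eliminated)
    remaining <- setdiff(remaining, worst)
  }
  c(remaining, eliminated)
}

# ---- l2,1-regularised logistic ranking -------------------------------------

# Two-class softmax loss with row-block (per original feature) l2,1 penalty,
# solved by proximal gradient descent.  Regularisation strength chosen from
# a small fixed grid by training loss; feature score = block norm.
score_ll21 <- function(train, labels, lambda_grid = c(0.001, 0.01, 0.1),
                       max_iter = 500, tol = 1e-6) {
  enc <- encode_groups(train)
  X <- enc$X
  n <- nrow(X)
  classes <- sort(unique(labels))
  Y <- cbind(labels == classes[1], labels == classes[2]) * 1
  L <- (svd(X, nu = 0, nv = 0)$d[1]^2) / (2 * n) + 1e-8
  step <- 1 / L
  best <- NULL
  for (lam in lambda_grid) {
    W <- matrix(0, ncol(X), 2)
    b <- c(0, 0)
    prev_obj <- Inf
    for (it in seq_len(max_iter)) {
      Z <- sweep(X %*% W, 2, b, "+")
      Z <- Z - apply(Z, 1, max)
      P <- exp(Z) / rowSums(exp(Z))
      G <- t(X) %*% (P - Y) / n
      gb <- colSums(P - Y) / n
      W <- W - step * G
      b <- b - step * gb
      # block soft-threshold per original feature
      for (g in enc$groups) {
        blk <- W[g, , drop = FALSE]
        nrm <- sqrt(sum(blk^2))
        W[g, ] <- if (nrm <= lam * step) 0 else blk * (1 - lam * step / nrm)
      }
      obj <- -sum(Y * log(pmax(P, 1e-12))) / n +
        lam * sum(vapply(enc$groups,
                         function(g) sqrt(sum(W[g, ]^2)), numeric(1)))
      if (abs(prev_obj - obj) < tol) break
      prev_obj <- obj
    }
    train_loss <- -sum(Y * log(pmax(P, 1e-12))) / n
    if (is.null(best) || train_loss < best$loss) {
      best <- list(loss = train_loss, W = W)
    }
  }
  vapply(names(train), function(f) {
    sqrt(sum(best$W[enc$groups[[f]], ]^2))
  }, numeric(1))
}
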