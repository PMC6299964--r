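#' Missing-value feature filter
#'
#' Keeps the features whose training-set missingness does not exceed the
#' threshold.  A feature is dropped iff its fraction of missing values is
#' strictly above `threshold` (default 0.20, i.e. "above 20%"), so a
#' feature missing in exactly 20 of 100 rows is kept.
#'
#' @param train a [feature_table()] (training split only).
#' @param threshold real in `[0, 1)`.
#' @return Character vector of kept feature names.
#' @export
fit_missing_filter <- function(train, threshold = 0.20) {
  stopifnot(threshold >= 0, threshold < 1)
  frac <- vapply(as.data.frame(train), function(col) mean(is.na(col)),
                 numeric(1))
  kept <- names(frac)[frac <= threshold]
  if (length(kept) == 0) stop("missing-value filter dropped every feature")
  kept
}

#' Mean/mode imputation fitted on training data
#'
#' `fit_imputer()` learns per-feature imputation statistics from the
#' training split: the mean for numeric features and the mode (most
#' frequent category, ties broken alphabetically) for nominal features.
#' `apply_imputer()` fills missing cells of any table with those
#' \emph{training} statistics, so applying it to a test split never uses
#' test information.
#'
#' @param train a [feature_table()] restricted to the kept features.
#' @param state a preprocess state from `fit_imputer()`.
#' @param table a `feature_table` with the same features.
#' @return `fit_imputer()` returns a list of class `preprocess_state` with
#'   `kept_features`, `numeric_means`, `nominal_modes`; `apply_imputer()`
#'   returns the imputed `feature_table`.
#' @export
fit_imputer <- function(train) {
  kinds <- ft_kinds(train)
  means <- list(); modes <- list()
  for (f in names(train)) {
    col <- train[[f]]
    obs <- col[!is.na(col)]
    if (length(obs) == 0) {
      stop(sprintf("feature '%s' entirely missing in training data", f))
    }
    if (kinds[[f]] == "numeric") {
      means[[f]] <- mean(obs)
    } else {
      tab <- table(obs)
      top <- names(tab)[tab == max(tab)]
      modes[[f]] <- sort(top)[1]
    }
  }
  structure(list(kept_features = names(train),
                 numeric_means = unlist(means),
                 nominal_modes = unlist(modes)),
            class = "preprocess_state")
}

#' @rdname fit_imputer
#' @export
apply_imputer <- function(state, table) {
  stopifnot(inherits(state, "preprocess_state"))
  table <- table[, state$kept_features, drop = FALSE]
  for (f in names(state$numeric_means)) {
    miss <- is.na(table[[f]])
    if (any(miss)) table[[f]][miss] <- state$numeric_means[[f]]
  }
  for (f in names(state$nominal_modes)) {
    miss <- is.na(table[[f]])
    if (any(miss)) table[[f]][miss] <- state$nominal_modes[[f]]
  }
  table
}

#' SMOTE gate
#'
#' Synthetic oversampling is only applied when the class imbalance is
#' severe: the gate opens iff the majority-class proportion is strictly
#' above `gate` (default 0.70).  An exact 70/30 split does not trigger it.
#'
#' @param labels two-class label vector.
#' @param gate real in `(0.5, 1)`.
#' @return Logical scalar.
#' @export
smote_needed <- function(labels, gate = 0.70) {
  tab <- table(as.character(labels))
  if (length(tab) < 2) stop("smote_needed() requires two classes")
  max(tab) / sum(tab) > gate
}

#' SMOTE oversampling of the minority class
#'
#' Brings the minority class to parity with the majority by adding
#' synthetic examples.  Each synthetic example is a convex combination of a
#' minority example and one of its `k` nearest minority neighbours
#' (Euclidean distance in a one-hot numeric encoding; synthetic nominal
#' values are rounded back to the nearest category).  Original rows are
#' preserved untouched and the result is deterministic given `seed`.
#'
#' If the minority class has fewer than `k + 1` members the neighbour count
#' is lowered to class size − 1; a singleton minority is duplicated with a
#' warning.
#'
#' @param train a fully imputed [feature_table()].
#' @param labels two-class label vector aligned with `train` rows.
#' @param seed integer seed.
#' @param k number of nearest minority neighbours (default 5).
#' @return A list with `table` (augmented `feature_table`) and `labels`.
#' @export
apply_smote <- function(train, labels, seed, k = 5) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("apply_smote() requires two classes")
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  n_new <- n_maj - n_min
  if (n_new == 0) return(list(table = train, labels = labels))

  kinds <- ft_kinds(train)
  min_idx <- which(labels == minority)
  enc <- one_hot_encode(train)
  Xm <- enc$matrix[min_idx, , drop = FALSE]

  set.seed(seed)
  if (n_min == 1) {
    warning("singleton minority class: duplicating the single example")
    new_rows <- train[rep(min_idx, n_new), , drop = FALSE]
  } else {
    k_eff <- min(k, n_min - 1)
    d <- as.matrix(stats::dist(Xm))
    diag(d) <- Inf
    nn <- matrix(apply(d, 1, function(row) order(row)[seq_len(k_eff)]),
                 nrow = n_min, byrow = TRUE)
    base_i <- sample.int(n_min, n_new, replace = TRUE)
    new_enc <- matrix(0, n_new, ncol(Xm), dimnames = list(NULL, colnames(Xm)))
    for (s in seq_len(n_new)) {
      i <- base_i[s]
      j <- nn[i, if (k_eff == 1) 1L else sample.int(k_eff, 1)]
      lam <- stats::runif(1)
      new_enc[s, ] <- Xm[i, ] + lam * (Xm[j, ] - Xm[i, ])
    }
    new_rows <- one_hot_decode(new_enc, train)
  }
  rownames(new_rows) <- sprintf("smote_%0*d", nchar(n_new), seq_len(n_new))
  out <- rbind(as.data.frame(train), as.data.frame(new_rows))
  list(table = feature_table(out, kinds = kinds),
       labels = c(labels, rep(minority, n_new)))
}

# One-hot expansion of nominal columns; numeric columns pass through.
one_hot_encode <- function(table) {
  kinds <- ft_kinds(table)
  cols <- list()
  map <- list()
  for (f in names(table)) {
    if (kinds[[f]] == "numeric") {
      cols[[f]] <- as.numeric(table[[f]])
      map[[f]] <- f
    } else {
      lev <- sort(unique(table[[f]]))
      for (lv in lev) {
        nm <- paste0(f, "=", lv)
        cols[[nm]] <- as.numeric(table[[f]] == lv)
      }
      map[[f]] <- paste0(f, "=", lev)
    }
  }
  list(matrix = do.call(cbind, cols), map = map)
}

# Inverse of one_hot_encode for synthetic rows: nominal value = category
# with the largest (interpolated) indicator.
one_hot_decode <- function(mat, template) {
  kinds <- ft_kinds(template)
  out <- list()
  for (f in names(template)) {
    if (kinds[[f]] == "numeric") {
      out[[f]] <- mat[, f]
    } else {
      lev <- sort(unique(template[[f]]))
      block <- mat[, paste0(f, "=", lev), drop = FALSE]
      out[[f]] <- lev[max.col(block, ties.method = "first")]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
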