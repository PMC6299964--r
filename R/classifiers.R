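#' Classifier specification
#'
#' Declares one of the supported classifiers with its hyperparameters.
#' Defaults: Gaussian naive Bayes; depth-unlimited decision tree; SVMs
#' with `C = 1` (RBF `gamma = 1/m`, polynomial degree 3); L2-regularised
#' logistic regression with `C = 1`.
#'
#' @param kind one of `"NB"`, `"DT"`, `"SVM_RBF"`, `"SVM_POLY"`,
#'   `"LOGREG"`.
#' @param hyperparameters named list overriding the defaults (`cost`,
#'   `gamma`, `degree`, `C`).
#' @param seed integer seed for any stochastic fitting step.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("NB", "DT", "SVM_RBF", "SVM_POLY",
                                     "LOGREG"),
                            hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# Deterministic tie order used when two classifiers reach the same RPT.
classifier_tie_order <- c("NB", "LOGREG", "SVM_RBF", "SVM_POLY", "DT")

# Numeric encoder for margin/linear models: one-hot with training levels,
# columns standardized with training statistics.  Unseen test categories
# map to all-zero indicator blocks.
fit_encoder <- function(train) {
  kinds <- ft_kinds(train)
  levels <- lapply(names(train), function(f) {
    if (kinds[[f]] == "nominal") sort(unique(train[[f]])) else NULL
  })
  names(levels) <- names(train)
  X <- encode_with_levels(train, kinds, levels)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(kinds = kinds, levels = levels, mu = mu, sd = sd)
}

apply_encoder <- function(enc, table) {
  X <- encode_with_levels(table, enc$kinds, enc$levels)
  sweep(sweep(X, 2, enc$mu), 2, enc$sd, "/")
}

encode_with_levels <- function(table, kinds, levels) {
  cols <- list()
  for (f in names(kinds)) {
    if (kinds[[f]] == "numeric") {
      cols[[f]] <- as.numeric(table[[f]])
    } else {
      for (lv in levels[[f]]) {
        cols[[paste0(f, "=", lv)]] <- as.numeric(table[[f]] == lv)
      }
    }
  }
  do.call(cbind, cols)
}

#' Fit a classifier and score a test split
#'
#' Internal engine used by [wrapper_curve()]: fits `spec` on the training
#' split and returns continuous scores (probability or decision value for
#' the positive class `cMCI`) plus hard predictions at the default 0.5 /
#' sign threshold.
#'
#' @param spec a [classifier_spec()].
#' @param train,test fully imputed [feature_table()]s.
#' @param train_labels factor/character labels aligned with `train`.
#' @return A function of the test table returning `list(score, pred)`.
#' @keywords internal
fit_and_score <- function(spec, train, train_labels, test) {
  y <- factor(as.character(train_labels), levels = c("sMCI", "cMCI"))
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("training fold has a single class")
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  if (spec$kind == "NB") {
    df_tr <- nominal_as_factor(train)
    fit <- e1071::naiveBayes(x = df_tr, y = y)
    pr <- stats::predict(fit, nominal_as_factor(test, like = df_tr),
                         type = "raw")
    score <- pr[, "cMCI"]
    list(score = score, pred = ifelse(score >= 0.5, "cMCI", "sMCI"))
  } else if (spec$kind == "DT") {
    df_tr <- nominal_as_factor(train)
    df_tr$.y <- y
    fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class")
    pr <- stats::predict(fit, nominal_as_factor(test, like = df_tr),
                         type = "prob")
    score <- pr[, "cMCI"]
    list(score = score, pred = ifelse(score >= 0.5, "cMCI", "sMCI"))
  } else if (spec$kind %in% c("SVM_RBF", "SVM_POLY")) {
    enc <- fit_encoder(train)
    Xtr <- apply_encoder(enc, train)
    Xte <- apply_encoder(enc, test)
    cost <- hp$cost %||% 1
    gamma <- hp$gamma %||% (1 / ncol(Xtr))
    degree <- hp$degree %||% 3
    kern <- if (spec$kind == "SVM_RBF") "radial" else "polynomial"
    fit <- e1071::svm(x = Xtr, y = y, kernel = kern, cost = cost,
                      gamma = gamma, degree = degree, scale = FALSE)
    dv <- attr(stats::predict(fit, Xte, decision.values = TRUE),
               "decision.values")
    # orient the decision value toward cMCI
    sgn <- if (grepl("^cMCI", colnames(dv)[1])) 1 else -1
    score <- sgn * dv[, 1]
    list(score = score, pred = ifelse(score >= 0, "cMCI", "sMCI"))
  } else { # LOGREG: ridge logistic, C = 1
    enc <- fit_encoder(train)
    Xtr <- apply_encoder(enc, train)
    Xte <- apply_encoder(enc, test)
    C <- hp$C %||% 1
    if (ncol(Xtr) == 1) Xtr <- cbind(Xtr, `(dup)` = Xtr[, 1])
    if (ncol(Xte) == 1) Xte <- cbind(Xte, `(dup)` = Xte[, 1])
    fit <- glmnet::glmnet(Xtr, y, family = "binomial", alpha = 0,
                          lambda = 1 / (C * nrow(Xtr)),
                          standardize = FALSE)
    score <- drop(stats::predict(fit, Xte, type = "response"))
    list(score = score, pred = ifelse(score >= 0.5, "cMCI", "sMCI"))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nominal_as_factor <- function(table, like = NULL) {
  df <- as.data.frame(table)
  kinds <- ft_kinds(table)
  for (f in names(df)) {
    if (!is.null(kinds) && kinds[[f]] == "nominal") {
      lev <- if (!is.null(like) && is.factor(like[[f]])) levels(like[[f]])
             else sort(unique(df[[f]]))
      df[[f]] <- factor(df[[f]], levels = lev)
    }
  }
  df
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of continuous scores for the positive
#' class `cMCI`; equivalent to the trapezoidal ROC area, with tied scores
#' contributing 1/2.
#'
#' @param scores numeric scores, larger = more cMCI-like.
#' @param labels `sMCI`/`cMCI` labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- scores[labels == "cMCI"]
  neg <- scores[labels == "sMCI"]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Sensitivity/specificity of hard predictions (positive class cMCI).
sens_spec <- function(pred, labels) {
  labels <- as.character(labels)
  pos <- labels == "cMCI"
  c(sensitivity = if (any(pos)) mean(pred[pos] == "cMCI") else NA_real_,
    specificity = if (any(!pos)) mean(pred[!pos] == "sMCI") else NA_real_)
}
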