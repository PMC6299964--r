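test_that("the composite performance score follows its definition", {
  cfg <- perf_config(alpha = 0.5, gamma = 0.5, combiner = "MIN")
  expect_equal(performance_score(0.8, 0.6, 0.9, cfg), 0.70)
  expect_equal(performance_score(0.77, 0.2, 0.4, perf_config(1, 0)), 0.77)
  # fixed point: all three metrics equal x
  expect_equal(performance_score(0.63, 0.63, 0.63, cfg), 0.63)
  mean_cfg <- perf_config(0.5, 0.5, "MEAN")
  expect_equal(performance_score(0.8, 0.6, 0.9, mean_cfg), 0.4 + 0.375)
  expect_error(perf_config(0.7, 0.5), "alpha")
  expect_error(performance_score(1.2, 0.5, 0.5, cfg), "0, 1")
})

test_that("performance is monotone non-decreasing in each metric", {
  cfg <- perf_config()
  base <- performance_score(0.7, 0.6, 0.8, cfg)
  expect_gte(performance_score(0.8, 0.6, 0.8, cfg), base)
  expect_gte(performance_score(0.7, 0.7, 0.8, cfg), base)
  expect_gte(performance_score(0.7, 0.6, 0.9, cfg), base)
})

test_that("RPT matches hand arithmetic and its harmonic-mean fixed point", {
  expect_equal(rpt_score(0.8, 0.8, 1), 0.8)
  expect_equal(rpt_score(0.6, 0.9, 1), 2 * 0.54 / 1.5)  # 0.72
  expect_equal(rpt_score(0.5, 0.9, 10), 101 * 0.45 / 50.9, tolerance = 1e-12)
  expect_warning(z <- rpt_score(-0.2, 0.9, 1), "non-positive")
  expect_equal(z, 0)
  expect_warning(expect_equal(rpt_score(0.5, 0, 1), 0))
})

test_that("RPT interpolates between stability and predictability with beta", {
  s <- 0.55; p <- 0.91
  expect_equal(rpt_score(s, p, 1e-3), s, tolerance = 1e-3)   # beta -> 0
  expect_equal(rpt_score(s, p, 1e3), p, tolerance = 1e-3)    # beta -> infinity
  for (b in c(0.1, 1, 10)) {
    v <- rpt_score(s, p, b)
    expect_gte(v, min(s, p))
    expect_lte(v, max(s, p))
  }
  # monotone in each argument
  expect_gt(rpt_score(0.6, 0.8, 1), rpt_score(0.5, 0.8, 1))
  expect_gt(rpt_score(0.6, 0.9, 1), rpt_score(0.6, 0.8, 1))
})

test_that("select_best_k maximises RPT with ties to the smallest k", {
  curve <- data.frame(k = 1:4, rpt_10 = c(0.5, 0.9, 0.9, 0.7))
  expect_equal(select_best_k(curve, 10), 2)
  inc <- data.frame(k = 1:5, rpt_1 = seq(0.1, 0.5, by = 0.1))
  expect_equal(select_best_k(inc, 1), 5)
  one <- data.frame(k = 1, rpt_1 = 0.4)
  expect_equal(select_best_k(one, 1), 1)
  expect_error(select_best_k(one, 99), "no RPT column")
})

test_that("rank-based AUC equals the trapezoidal ROC area (pROC cross-check)", {
  skip_if_not_installed("pROC")
  set.seed(9)
  labels <- rep(c("sMCI", "cMCI"), each = 30)
  scores <- rnorm(60, mean = ifelse(labels == "cMCI", 1, 0))
  ours <- auc_score(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("sMCI", "cMCI"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(auc_score(c(1, 1, 0, 0), c("cMCI", "cMCI", "sMCI", "sMCI")), 1)
})

make_separable_folds <- function() {
  f1 <- separable_table(seed = 1)
  f2 <- separable_table(seed = 2)
  folds <- list(
    list(train = f1$table, train_labels = f1$labels,
         test = f2$table, test_labels = f2$labels),
    list(train = f2$table, train_labels = f2$labels,
         test = f1$table, test_labels = f1$labels))
  rk <- ranking_of(c("sep", "n1", "n2"))
  list(folds = folds, rankings = list(rk, rk))
}

test_that("a perfectly separating top feature yields AUC = sens = spec = stability = 1 at k = 1", {
  fx <- make_separable_folds()
  for (kind in c("NB", "LOGREG", "DT", "SVM_RBF", "SVM_POLY")) {
    curve <- wrapper_curve(fx$rankings, fx$folds, classifier_spec(kind))
    expect_equal(curve$auc[1], 1, info = kind)
    expect_equal(curve$sensitivity[1], 1, info = kind)
    expect_equal(curve$specificity[1], 1, info = kind)
    expect_equal(curve$stability[1], 1, info = kind)
    expect_equal(curve$rpt_1[1], 1, info = kind)
  }
})

test_that("the curve at k = m reproduces the all-features baseline", {
  fx <- make_separable_folds()
  spec <- classifier_spec("NB")
  curve <- wrapper_curve(fx$rankings, fx$folds, spec)
  m <- 3
  metrics <- sapply(fx$folds, function(fold) {
    res <- fsestab:::fit_and_score(spec, fold$train, fold$train_labels,
                                   fold$test)
    c(auc_score(res$score, fold$test_labels),
      fsestab:::sens_spec(res$pred, fold$test_labels))
  })
  expect_equal(curve$auc[m], mean(metrics[1, ]), tolerance = 1e-9)
  expect_equal(curve$sensitivity[m], mean(metrics[2, ]), tolerance = 1e-9)
  expect_equal(curve$specificity[m], mean(metrics[3, ]), tolerance = 1e-9)
})

test_that("the curve's stability sequence matches hand-computed pair similarities", {
  fx <- make_separable_folds()
  rk2 <- list(ranking_of(c("sep", "n1", "n2")), ranking_of(c("n1", "sep", "n2")))
  curve <- wrapper_curve(rk2, fx$folds, classifier_spec("NB"))
  # k=1: disjoint singletons, m=3 -> (0*3 - 1)/(1*2) = -0.5; k=2: r=2 -> 1
  expect_equal(curve$stability[1], -0.5)
  expect_equal(curve$stability[2], 1)
  expect_equal(curve$stability[3], 1)  # k = m convention
})

test_that("select_best_pair picks the highest RPT with the fixed tie order", {
  cv1 <- data.frame(k = 1:2, rpt_10 = c(0.80, 0.60))
  cv2 <- data.frame(k = 1:2, rpt_10 = c(0.85, 0.10))
  cons <- ranking_of(c("A", "B"))
  out <- select_best_pair(list(NB = cv1, DT = cv2), 10, cons)
  expect_equal(out$classifier, "DT")
  expect_equal(out$k, 1)
  expect_equal(out$features, "A")
  # exact tie resolves NB before DT
  tie <- select_best_pair(list(DT = cv1, NB = cv1), 10, cons)
  expect_equal(tie$classifier, "NB")
  single <- select_best_pair(list(LOGREG = cv2), 10, cons)
  expect_equal(single$classifier, "LOGREG")
})
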