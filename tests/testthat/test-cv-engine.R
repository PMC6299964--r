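small_cohort <- function(seed = 5) {
  generate_cohort(synthetic_spec(
    n_patients = 60, n_informative = 3, n_redundant = 1, n_noise = 4,
    effect_size = 1.2, missing_rate = 0.05, nominal_fraction = 0.25,
    seed = seed))
}

small_config <- function(seed = 11, ...) {
  cv_config(repetitions = 1, folds = 2, master_seed = seed, windows = 3,
            fs_methods = c("MIM", "CHI2"),
            classifiers = list(classifier_spec("NB")), ...)
}

test_that("the experiment produces the expected structure", {
  co <- small_cohort()
  res <- suppressWarnings(run_experiment(co, small_config()))
  expect_s3_class(res, "experiment_result")
  wr <- res$window_3
  expect_equal(wr$folds_n, 2)
  m <- wr$m_pool
  expect_equal(m, 8)
  curve <- wr$selectors$ENSEMBLE$curves$NB
  expect_equal(nrow(curve), m)
  expect_equal(dim(attr(curve, "perf_folds")), c(2, m))
  # base-method comparison selectors present alongside the ensemble
  expect_setequal(names(wr$selectors), c("ENSEMBLE", "MIM", "CHI2"))
  expect_equal(wr$baseline$NB$n_features, m)
  # the consensus ranking covers the full pool
  expect_setequal(wr$consensus$features, names(wr$dataset$table))
})

test_that("the experiment is a pure function of the cohort and master seed", {
  co <- small_cohort()
  r1 <- suppressWarnings(run_experiment(co, small_config(seed = 42)))
  r2 <- suppressWarnings(run_experiment(co, small_config(seed = 42)))
  c1 <- r1$window_3$selectors$ENSEMBLE$curves$NB
  c2 <- r2$window_3$selectors$ENSEMBLE$curves$NB
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(r1$window_3$best_pair, r2$window_3$best_pair)
})

test_that("stratified folds keep class proportions within one example", {
  set.seed(7)
  labels <- c(rep("sMCI", 33), rep("cMCI", 14))
  fold <- fsestab:::stratified_folds(labels, 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  for (f in 1:5) {
    n_c <- sum(labels[fold == f] == "cMCI")
    expect_lte(abs(n_c - 14 / 5), 1)
    n_s <- sum(labels[fold == f] == "sMCI")
    expect_lte(abs(n_s - 33 / 5), 1)
  }
})

test_that("corrupting test folds changes no fitted statistic and no ranking", {
  co <- small_cohort()
  wd <- build_windowed_dataset(co, 3)
  fold <- fsestab:::stratified_folds(wd$labels, 2, seed = 1)
  te <- fold == 1
  tr_tab <- wd$table[!te, , drop = FALSE]
  tr_lab <- as.character(wd$labels[!te])

  run_side <- function(test_tab) {
    kept <- fit_missing_filter(tr_tab)
    st <- fit_imputer(tr_tab[, kept, drop = FALSE])
    rk <- lapply(c("MIM", "CHI2", "RELIEFF"), function(m) {
      rank_features(m, apply_imputer(st, tr_tab), tr_lab, seed = 2)$features
    })
    list(kept = kept, means = st$numeric_means, modes = st$nominal_modes,
         rankings = rk, test_imputed = apply_imputer(st, test_tab))
  }
  clean <- wd$table[te, , drop = FALSE]
  corrupt <- clean
  for (f in names(corrupt)) {
    corrupt[[f]] <- if (is.numeric(corrupt[[f]])) {
      rep(9e9, nrow(corrupt))
    } else rep("corrupted", nrow(corrupt))
  }
  a <- run_side(clean)
  b <- run_side(feature_table(as.data.frame(corrupt),
                              kinds = ft_kinds(wd$table)))
  expect_identical(a$kept, b$kept)
  expect_identical(a$means, b$means)
  expect_identical(a$modes, b$modes)
  expect_identical(a$rankings, b$rankings)
})

fake_window_result <- function(perf_cols) {
  nf <- length(perf_cols[[1]])
  selectors <- lapply(perf_cols, function(v) {
    curve <- data.frame(k = 1, rpt_10 = 0.5)
    attr(curve, "perf_folds") <- matrix(v, ncol = 1)
    list(curves = list(NB = curve),
         best_k = list(NB = c(beta_10 = 1)))
  })
  list(selectors = selectors, baseline = list())
}

test_that("identical selector results give a non-significant omnibus test and no pairwise tests", {
  v <- seq(0.5, 0.9, length.out = 20)
  wr <- fake_window_result(list(ENSEMBLE = v, MIM = v, CHI2 = v))
  cmp <- compare_selectors(wr, "NB", 10)
  expect_gte(cmp$friedman$p.value, 0.05)
  expect_null(cmp$pairwise)
})

test_that("a selector dominating by a constant margin is flagged by the signed-rank test", {
  set.seed(13)
  base <- runif(50, 0.6, 0.9)
  wr <- fake_window_result(list(ENSEMBLE = base, MIM = base - 0.05,
                                CHI2 = base - 0.001))
  cmp <- compare_selectors(wr, "NB", 10)
  expect_lt(cmp$friedman$p.value, 0.05)
  row <- cmp$pairwise[cmp$pairwise$comparison == "ENSEMBLE vs MIM", ]
  expect_lt(row$p_raw, 0.001)
  expect_equal(row$direction, "ensemble higher")
  expect_gte(row$p_bonferroni, row$p_raw)
})

test_that("with exactly two selectors the omnibus test is skipped for a single Wilcoxon", {
  set.seed(14)
  base <- runif(30, 0.5, 0.9)
  wr <- fake_window_result(list(ENSEMBLE = base, MIM = base - 0.04))
  cmp <- compare_selectors(wr, "NB", 10)
  expect_null(cmp$friedman)
  expect_equal(nrow(cmp$pairwise), 1)
  expect_lt(cmp$pairwise$p_raw, 0.01)
})

test_that("the feature report truncates the consensus at the chosen size and flags common features", {
  co <- small_cohort()
  cfg <- cv_config(repetitions = 1, folds = 2, master_seed = 8,
                   windows = c(2, 3), fs_methods = c("MIM", "CHI2"),
                   classifiers = list(classifier_spec("NB")),
                   compare_base_methods = FALSE)
  res <- suppressWarnings(run_experiment(co, cfg))
  fr <- feature_report(res, beta = 10)
  expect_setequal(names(fr$per_window), names(res))
  for (wn in names(res)) {
    bp <- res[[wn]]$best_pair$beta_10
    expect_equal(fr$per_window[[wn]]$feature, bp$features)
    expect_equal(fr$per_window[[wn]]$position, seq_len(bp$k))
  }
  expect_true(all(fr$common$feature %in% fr$per_window[[1]]$feature))
})

test_that("a window with fewer than two examples per class is skipped", {
  co <- make_cohort(list(
    a = patient(c(1, 4), c("MCI", "MCI")),
    b = patient(c(1, 4.5), c("MCI", "MCI")),
    c = patient(1, "DEMENTIA"),
    d = patient(c(1, 5), c("MCI", "MCI"))),
    features = data.frame(x = rnorm(4), y = rnorm(4),
                          row.names = c("a", "b", "c", "d")))
  cfg <- small_config()
  cfg$windows <- 3
  expect_error(suppressWarnings(run_experiment(co, cfg)), "no window")
})
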