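test_that("missing-value filter drops features strictly above the threshold", {
  vals <- data.frame(
    over = c(rep(NA, 21), rnorm(79)),
    at = c(rep(NA, 20), rnorm(80)),
    full = rnorm(100)
  )
  kept <- fit_missing_filter(feature_table(vals), threshold = 0.20)
  expect_setequal(kept, c("at", "full"))
  all_na <- feature_table(data.frame(x = rep(NA_real_, 5)))
  expect_error(fit_missing_filter(all_na), "every feature")
})

test_that("imputation uses training means and modes and is idempotent", {
  tr <- feature_table(data.frame(
    num = c(1, NA, 3),
    cat = c("a", "a", "b"),
    stringsAsFactors = FALSE))
  st <- fit_imputer(tr)
  expect_equal(unname(st$numeric_means["num"]), 2)
  expect_equal(unname(st$nominal_modes["cat"]), "a")
  imp <- apply_imputer(st, tr)
  expect_equal(imp$num, c(1, 2, 3))
  expect_equal(apply_imputer(st, imp), imp)        # idempotent
  # a table with no missing cells passes through unchanged
  clean <- feature_table(data.frame(num = c(4, 5), cat = c("b", "b"),
                                    stringsAsFactors = FALSE))
  expect_equal(as.data.frame(apply_imputer(fit_imputer(clean), clean)),
               as.data.frame(clean))
  # nominal mode by count
  tr2 <- feature_table(data.frame(cat = c("a", "a", "b", NA),
                                  stringsAsFactors = FALSE))
  expect_equal(apply_imputer(fit_imputer(tr2), tr2)$cat[4], "a")
})

test_that("test-split statistics never leak into the fitted state", {
  set.seed(3)
  tr <- feature_table(data.frame(num = c(1, NA, 3, 6), cat = c("a", "a", "b", NA),
                                 stringsAsFactors = FALSE))
  te <- feature_table(data.frame(num = c(NA, 100), cat = c(NA, "zzz"),
                                 stringsAsFactors = FALSE))
  st <- fit_imputer(tr)
  out1 <- apply_imputer(st, te)
  # perturbing the test data changes nothing about the fitted statistics
  te2 <- feature_table(data.frame(num = c(NA, -999), cat = c(NA, "qqq"),
                                  stringsAsFactors = FALSE))
  out2 <- apply_imputer(st, te2)
  expect_equal(out1$num[1], mean(c(1, 3, 6)))
  expect_equal(out2$num[1], out1$num[1])
  expect_equal(out1$cat[1], "a")
})

test_that("the SMOTE gate opens only strictly above 70% majority share", {
  expect_true(smote_needed(c(rep("s", 78), rep("c", 22))))
  expect_false(smote_needed(c(rep("s", 70), rep("c", 30))))
  expect_false(smote_needed(c(rep("s", 56), rep("c", 44))))
  expect_error(smote_needed(rep("s", 10)), "two classes")
})

test_that("SMOTE reaches parity, preserves originals, and interpolates convexly", {
  set.seed(1)
  n_min <- 10; n_maj <- 90
  tb <- feature_table(data.frame(
    x = c(rnorm(n_min, 5), rnorm(n_maj, 0)),
    y = c(rnorm(n_min, 5), rnorm(n_maj, 0)),
    row.names = sprintf("r%03d", 1:100)))
  labels <- c(rep("cMCI", n_min), rep("sMCI", n_maj))
  out <- apply_smote(tb, labels, seed = 7)
  expect_equal(unname(table(out$labels)["cMCI"]), 90)
  expect_equal(unname(table(out$labels)["sMCI"]), 90)
  # originals untouched, in place
  expect_equal(as.data.frame(out$table)[1:100, ], as.data.frame(tb))
  # determinism
  out2 <- apply_smote(tb, labels, seed = 7)
  expect_identical(out$table, out2$table)
  # convexity: every synthetic point lies within the minority bounding box
  syn <- as.data.frame(out$table)[101:180, ]
  minor <- as.data.frame(tb)[1:10, ]
  expect_true(all(syn$x >= min(minor$x) & syn$x <= max(minor$x)))
  expect_true(all(syn$y >= min(minor$y) & syn$y <= max(minor$y)))
})

test_that("synthetic points lie exactly on the segment between their two parents", {
  # with a two-point minority class every synthetic row must be a convex
  # combination of those two rows
  tb <- feature_table(data.frame(
    x = c(0, 1, 5, 6, 7, 8, 9, 10),
    y = c(0, 2, 5, 6, 7, 8, 9, 10)))
  labels <- c("c", "c", rep("s", 6))
  out <- apply_smote(tb, labels, seed = 11)
  syn <- as.data.frame(out$table)[9:12, ]
  lam <- syn$x - 0   # x runs 0 -> 1, so lambda = x
  expect_equal(syn$y, 0 + lam * 2, tolerance = 1e-12)
  expect_true(all(lam >= 0 & lam <= 1))
})

test_that("degenerate minorities fall back gracefully", {
  tb <- feature_table(data.frame(x = c(0, 5, 6, 7), y = c(0, 5, 6, 7)))
  labels <- c("c", "s", "s", "s")
  expect_warning(out <- apply_smote(tb, labels, seed = 2), "singleton")
  expect_equal(sum(out$labels == "c"), 3)
  syn <- as.data.frame(out$table)[5:6, ]
  expect_true(all(syn$x == 0))
})

test_that("SMOTE one-hot rounds nominal features back to observed categories", {
  tb <- feature_table(data.frame(
    x = c(0, 1, 0.5, 5, 6, 7, 8, 9),
    g = c("a", "b", "a", "c", "c", "c", "c", "c"),
    stringsAsFactors = FALSE))
  labels <- c("c", "c", "c", rep("s", 5))
  out <- apply_smote(tb, labels, seed = 5)
  syn_g <- as.data.frame(out$table)$g[9:10]
  expect_true(all(syn_g %in% c("a", "b")))
})
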