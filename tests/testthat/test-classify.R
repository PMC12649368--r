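test_that("classifier metrics follow the confusion-matrix formulas", {
  perfect <- c(TP = 10, FP = 0, FN = 0, TN = 10)
  expect_equal(unname(classifier_metrics(perfect)), c(1, 1, 1, 1))

  cm <- c(TP = 14, FP = 2, FN = 5, TN = 18)
  met <- classifier_metrics(cm)
  expect_equal(unname(met["f1"]), 28 / 35)      # 2TP / (2TP + FP + FN)
  expect_equal(unname(met["precision"]), 14 / 16)
  expect_equal(unname(met["recall"]), 14 / 19)
  # F1 computed from precision and recall agrees with the count form
  p <- met[["precision"]]; r <- met[["recall"]]
  expect_equal(2 * p * r / (p + r), met[["f1"]], tolerance = 1e-15)

  # zero-denominator conventions
  none <- classifier_metrics(c(TP = 0, FP = 0, FN = 5, TN = 15))
  expect_equal(unname(none["precision"]), 0)
  expect_equal(unname(none["f1"]), 0)
  expect_error(classifier_metrics(c(TP = 0, FP = 0, FN = 0, TN = 0)), "empty")
})

test_that("rank AUC hits its anchors and is monotone-invariant", {
  lab <- c(rep(TRUE, 8), rep(FALSE, 12))
  expect_equal(auc_rank(as.numeric(lab), lab), 1)
  expect_equal(auc_rank(-as.numeric(lab), lab), 0)
  set.seed(7)
  s <- rnorm(20)
  a0 <- auc_rank(s, lab)
  expect_equal(auc_rank(exp(s), lab), a0)
  expect_equal(auc_rank(5 * s - 3, lab), a0)
  expect_error(auc_rank(s, rep(TRUE, 20)), "both classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  lab <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  s <- rnorm(50) + lab
  expect_equal(auc_rank(s, lab),
               as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("cross-validation is seeded-deterministic and separates wide margins", {
  set.seed(31)
  n <- 40
  y <- rep(c("healthy", "stroke"), each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  x <- x + ifelse(y == "stroke", 8, 0)              # wide margin
  r1 <- cross_validate(x, y, seed = 5)
  r2 <- cross_validate(x, y, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$accuracy == 1))
  expect_true(all(r1$auc == 1))
  expect_equal(unique(r1$n_evaluated), n)
  expect_setequal(r1$model, c("QSVM", "GSVM", "LR", "SD", "LD"))
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(17)
  n <- 40
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- sample(rep(c("healthy", "stroke"), each = n / 2))
  r <- cross_validate(x, y, models = c("QSVM", "LD"), seed = 9)
  band <- 1.96 * sqrt(0.25 / n)
  expect_true(all(abs(r$accuracy - 0.5) <= band + 0.15))
})

test_that("stratification requires enough samples per class", {
  x <- matrix(rnorm(12), 6, 2)
  y <- c(rep("healthy", 4), rep("stroke", 2))
  expect_error(cross_validate(x, y, k = 5), "at least k samples")
})

test_that("feature selection splits phase-specific and whole-task sets", {
  cmp <- data.frame(metric = c("A", "B", "C", "D"),
                    window = c("PhaseII", "Whole", "PhaseIV", "Whole"),
                    p_adjusted = c(0.01, 0.001, 0.2, 0.04),
                    significant = c(TRUE, TRUE, FALSE, TRUE))
  sel <- select_features(cmp)
  expect_setequal(sel$phase_specific, c("A__PhaseII", "B__Whole", "D__Whole"))
  expect_setequal(sel$whole_task, c("B__Whole", "D__Whole"))
  # ordered by adjusted p
  expect_equal(sel$phase_specific[1], "B__Whole")
  cmp$significant <- FALSE
  expect_warning(expect_warning(sel0 <- select_features(cmp), "empty"),
                 "empty")
  expect_length(sel0$phase_specific, 0)
})
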