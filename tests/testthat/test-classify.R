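test_that("weighted SVM separates blobs and orients scores toward class 1", {
  set.seed(1)
  X <- rbind(matrix(rnorm(20, -2, 0.5), 10, 2),
             matrix(rnorm(20, 2, 0.5), 10, 2))
  y <- rep(0:1, each = 10)
  mdl <- train_weighted_svm(X, y, kernel = "linear", C = 1)
  out <- predict(mdl, X)
  expect_equal(out$predicted_label, y)
  expect_true(all(abs(out$decision_score) > 0))
  expect_true(all(out$decision_score[y == 1] > 0))
  expect_error(train_weighted_svm(X, rep(1L, 20)), "both classes")
})

test_that("balanced weighting lifts minority sensitivity on imbalanced
           overlap", {
  sens <- function(weighting) {
    mean(vapply(1:20, function(s) {
      set.seed(s)
      x <- c(rnorm(90, 0), rnorm(10, 1.2))
      y <- rep(0:1, c(90, 10))
      xt <- c(rnorm(90, 0), rnorm(10, 1.2))
      mdl <- train_weighted_svm(matrix(x, ncol = 1), y, kernel = "linear",
                                class_weighting = weighting)
      out <- predict(mdl, matrix(xt, ncol = 1))
      mean(out$predicted_label[91:100] == 1)
    }, 1.0))
  }
  expect_gte(sens("balanced"), sens("none"))
})

test_that("duplicating minority cases matches 2:1 class weighting (linear
           kernel)", {
  set.seed(9)
  X <- matrix(c(rnorm(20, 0), rnorm(10, 1.5)), ncol = 1)
  y <- rep(0:1, c(20, 10))
  dup <- c(seq_len(30), 21:30)  # duplicate every minority sample
  m_dup <- e1071::svm(x = scale(X)[dup, , drop = FALSE],
                      y = factor(y[dup], levels = 0:1), kernel = "linear",
                      cost = 1, scale = FALSE)
  m_wt <- e1071::svm(x = scale(X), y = factor(y, levels = 0:1),
                     kernel = "linear", cost = 1, scale = FALSE,
                     class.weights = c("0" = 1, "1" = 2))
  grid <- matrix(seq(-2, 3, length.out = 101), ncol = 1)
  gz <- (grid - mean(X)) / sd(X)
  p_dup <- attr(predict(m_dup, gz, decision.values = TRUE),
                "decision.values")[, 1]
  p_wt <- attr(predict(m_wt, gz, decision.values = TRUE),
               "decision.values")[, 1]
  expect_equal(sign(p_dup), sign(p_wt))
})

test_that("confusion metrics follow the stated formulas", {
  preds <- data.frame(
    true_label = c(rep(1, 10), rep(0, 10)),
    predicted_label = c(rep(1, 9), 0, rep(0, 8), 1, 1))
  m <- confusion_metrics(preds)
  expect_equal(m$sens, 0.9)
  expect_equal(m$spec, 0.8)
  expect_equal(m$acc, 0.85)

  all_right <- data.frame(true_label = c(0, 0, 1, 1),
                          predicted_label = c(0, 0, 1, 1))
  m2 <- confusion_metrics(all_right)
  expect_equal(c(m2$acc, m2$sens, m2$spec), c(1, 1, 1))

  all_pos <- data.frame(true_label = c(0, 0, 1, 1),
                        predicted_label = rep(1, 4))
  m3 <- confusion_metrics(all_pos)
  expect_equal(c(m3$sens, m3$spec), c(1, 0))

  expect_error(confusion_metrics(data.frame(true_label = c(1, 1),
                                            predicted_label = c(1, 0))),
               "both classes")
})

test_that("AUC matches exhaustive pair counting and the trapezoid identity", {
  # worked example: enumerate all four positive-negative pairs
  ra <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(ra$auc, 0.75)
  expect_equal(ra$roc$fpr[1], 0)
  expect_equal(ra$roc$tpr[1], 0)
  expect_equal(ra$roc$fpr[nrow(ra$roc)], 1)
  expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)

  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)

  # identity between pair counting and trapezoid area on random draws
  set.seed(2)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    ra <- roc_auc(scores, labels)
    expect_true(all(diff(ra$roc$fpr) >= 0))
    expect_true(all(diff(ra$roc$tpr) >= 0))
    expect_equal(srtexture:::trapezoid_auc(ra$roc), ra$auc,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("pair-counting AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (i in 1:20) {
    scores <- rnorm(30)
    labels <- sample(0:1, 30, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap AUC interval is deterministic, degenerate when perfect,
           and calibrated", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  ci1 <- bootstrap_auc_ci(scores, labels, n_boot = 200, seed = 4)
  ci2 <- bootstrap_auc_ci(scores, labels, n_boot = 200, seed = 4)
  expect_identical(ci1, ci2)
  expect_equal(ci1, c(1, 1))

  # coverage under a binormal model with true AUC 0.8
  dprime <- sqrt(2) * qnorm(0.8)
  covered <- vapply(1:100, function(rep) {
    set.seed(rep + 500)
    s <- c(rnorm(20), rnorm(20, dprime))
    l <- rep(0:1, each = 20)
    ci <- bootstrap_auc_ci(s, l, n_boot = 300, level = 0.95, seed = rep)
    ci[1] <= 0.8 && 0.8 <= ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.9)
})

test_that("Mann-Whitney exact enumeration handles ties, symmetry and the
           textbook case", {
  expect_equal(mannwhitney_feature_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(mannwhitney_feature_test(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(mannwhitney_feature_test(c(1, 5, 3), c(2, 4, 9)),
               mannwhitney_feature_test(c(2, 4, 9), c(1, 5, 3)))
  # exact branch agrees with wilcox.test when there are no ties
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(5)
    b <- rnorm(6)
    expect_equal(mannwhitney_feature_test(a, b),
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large-sample branch
  a <- rnorm(30)
  b <- rnorm(25, 0.5)
  expect_equal(mannwhitney_feature_test(a, b),
               wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-12)
  expect_error(mannwhitney_feature_test(numeric(0), 1:3), "nonempty")
})

test_that("LOOCV on feature matrices honours the refit flag and records it", {
  set.seed(6)
  n <- 24
  X <- matrix(rnorm(n * 40), n, 40)
  y <- rep(0:1, each = n / 2)
  X[, 7] <- X[, 7] + 3 * y
  cfg <- small_gray_config()
  fm <- list(features = X, label = y,
             case_id = sprintf("c%02d", seq_len(n)), layout = NULL)
  rep_t <- loocv_evaluate(fm, cfg, refit_per_fold = TRUE)
  rep_f <- loocv_evaluate(fm, cfg, refit_per_fold = FALSE)
  expect_true(rep_t$refit_per_fold)
  expect_false(rep_f$refit_per_fold)
  expect_false(rep_t$fingerprint == rep_f$fingerprint)
  expect_gt(rep_t$auc, 0.9)  # strong planted effect survives honest refit
  expect_s3_class(rep_t, "srt_eval")
  expect_equal(nrow(rep_t$folds), n)
  # metric consistency with stored confusion counts
  with(rep_t$confusion, {
    expect_equal(rep_t$acc, (tp + tn) / n)
    expect_equal(rep_t$sens, tp / (tp + fn))
    expect_equal(rep_t$spec, tn / (tn + fp))
  })
})

test_that("LOOCV AUC trends downward as generator noise grows", {
  # per-level mean over three dataset seeds: single LOOCV AUCs at n = 16 are
  # too granular (steps of 1/64) to order reliably
  mean_auc <- function(ns) {
    mean(vapply(1:3, function(r) {
      cfg <- small_gray_config(
        generator = small_gray_generator(noise_sigma = ns,
                                         disjoint_support = TRUE))
      ds <- generate_dataset(8, cfg, seed = 30 + r)
      feds <- suppressWarnings(train_dictionaries(ds$cases, cfg))
      fm <- features_for_cases(ds$cases, feds, cfg)
      suppressWarnings(loocv_evaluate(fm, cfg, refit_per_fold = TRUE))$auc
    }, 1.0))
  }
  aucs <- vapply(c(0, 0.4, 1, 2.5, 6), mean_auc, 1.0)
  expect_lt(cor(seq_along(aucs), aucs, method = "spearman"), 0)
})
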