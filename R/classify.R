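# Classification and evaluation: class-weighted SVM, leakage-safe LOOCV over
# the whole pipeline, ROC/AUC, bootstrap confidence intervals and the
# Mann-Whitney feature screen.

#' Train a class-weighted soft-margin SVM
#'
#' Features are column-standardized with statistics computed from the training
#' rows only; with `class_weighting = "balanced"` each class c gets the
#' per-class penalty `C * n / (2 * n_c)`, which removes the bias a skewed
#' class ratio induces on the margin. The returned object scores new cases
#' with a signed decision value oriented so that positive scores mean class 1;
#' the predicted label is 1 iff the score is strictly positive (ties go to
#' class 0).
#'
#' @param features training matrix (cases x features).
#' @param labels 0/1 labels; both classes must be present.
#' @param kernel `"linear"` or `"rbf"` (Gaussian, bandwidth by the median
#'   heuristic unless `gamma` is given).
#' @param C soft-margin penalty.
#' @param class_weighting `"balanced"` or `"none"`.
#' @param gamma optional RBF kernel parameter.
#' @return an object of class `wsvm`.
#' @export
train_weighted_svm <- function(features, labels,
                               kernel = c("linear", "rbf"), C = 1,
                               class_weighting = c("balanced", "none"),
                               gamma = NULL) {
  kernel <- match.arg(kernel)
  class_weighting <- match.arg(class_weighting)
  check_that(is.matrix(features), "features must be a matrix")
  labels <- as.integer(labels)
  check_that(all(labels %in% c(0L, 1L)), "labels must be 0/1")
  n0 <- sum(labels == 0L)
  n1 <- sum(labels == 1L)
  check_that(n0 > 0L && n1 > 0L,
             "training set must contain both classes")

  st <- standardize_columns(features)
  wts <- if (class_weighting == "balanced") {
    n <- n0 + n1
    c("0" = n / (2 * n0), "1" = n / (2 * n1))
  } else NULL
  if (kernel == "rbf" && is.null(gamma)) {
    # median heuristic: gamma = 1 / (2 * median squared pairwise distance)
    Z <- st$Z
    m <- min(nrow(Z), 100L)
    d2 <- as.numeric(stats::dist(Z[seq_len(m), , drop = FALSE]))^2
    med <- stats::median(d2[d2 > 0])
    gamma <- if (is.finite(med) && med > 0) 1 / (2 * med) else
      1 / ncol(Z)
  }
  args <- list(x = st$Z, y = factor(labels, levels = c(0L, 1L)),
               kernel = if (kernel == "linear") "linear" else "radial",
               cost = C, scale = FALSE)
  if (!is.null(wts)) args$class.weights <- wts
  if (kernel == "rbf") args$gamma <- gamma
  fit <- do.call(e1071::svm, args)

  # orient decision values: e1071 reports them for the class named first in
  # the "a/b" attribute, which depends on which label appears first
  dv <- attr(predict(fit, st$Z, decision.values = TRUE),
             "decision.values")
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  flip <- if (first == "1") 1 else -1
  structure(list(fit = fit, center = st$center, scale = st$scale,
                 constant = st$constant, flip = flip, kernel = kernel,
                 C = C, class_weighting = class_weighting, gamma = gamma),
            class = "wsvm")
}

#' @export
#' @rdname train_weighted_svm
#' @param object a `wsvm` model.
#' @param newdata matrix of cases to score (original feature scale).
#' @param ... unused.
predict.wsvm <- function(object, newdata, ...) {
  Z <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  Z[, object$constant] <- 0
  dv <- attr(predict(object$fit, Z, decision.values = TRUE),
             "decision.values")
  score <- object$flip * as.numeric(dv[, 1L])
  data.frame(decision_score = score,
             predicted_label = as.integer(score > 0))
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity and specificity from fold predictions, with class 1
#' (the target/malignant class) as positive: `sens = TP / (TP + FN)`,
#' `spec = TN / (TN + FP)`, `acc = (TP + TN) / n`.
#'
#' @param predictions data frame with columns `true_label` and
#'   `predicted_label` (0/1), e.g. the `folds` element of an `srt_eval`.
#' @return named list with `acc`, `sens`, `spec` and the confusion counts
#'   `tp`, `fn`, `tn`, `fp`.
#' @export
#' @examples
#' confusion_metrics(data.frame(true_label = c(1, 1, 0, 0),
#'                              predicted_label = c(1, 0, 0, 1)))
confusion_metrics <- function(predictions) {
  tl <- as.integer(predictions$true_label)
  pl <- as.integer(predictions$predicted_label)
  check_that(any(tl == 1L) && any(tl == 0L),
             "predictions must include both classes")
  tp <- sum(tl == 1L & pl == 1L)
  fn <- sum(tl == 1L & pl == 0L)
  tn <- sum(tl == 0L & pl == 0L)
  fp <- sum(tl == 0L & pl == 1L)
  list(acc = (tp + tn) / length(tl), sens = tp / (tp + fn),
       spec = tn / (tn + fp), tp = tp, fn = fn, tn = tn, fp = fp)
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney pair-counting identity (a tied positive/negative
#' score pair counts 1/2), computed from average ranks; the ROC curve sweeps
#' all distinct score thresholds from high to low, so tied scores move
#' diagonally and the trapezoidal area under the returned curve equals the
#' pair-counting AUC to machine precision.
#'
#' @param scores numeric decision scores (higher = more class-1).
#' @param labels 0/1 labels; both classes must be present.
#' @return list with `auc` and `roc`, a data frame with columns `threshold`,
#'   `fpr`, `tpr` starting at (0, 0) and ending at (1, 1).
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  check_that(n1 > 0L && n0 > 0L, "labels must contain both classes")
  r <- rank(scores)  # average ranks implement the 1/2 tie convention
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  fp <- cumsum(1L - l)
  last <- !duplicated(grp, fromLast = TRUE)  # last index of each tie block
  roc <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp[last] / n0),
                    tpr = c(0, tp[last] / n1))
  list(auc = auc, roc = roc)
}

# trapezoidal area under an ROC curve (internal cross-check of the identity)
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples cases with replacement within each class (so every resample
#' keeps both classes), recomputes the pair-counting AUC, and returns the
#' percentile interval. Deterministic given the seed.
#'
#' @param scores numeric decision scores.
#' @param labels 0/1 labels.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @return numeric vector `c(low, high)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000L, level = 0.95,
                             seed = 1L) {
  check_that(n_boot >= 100L, "n_boot must be >= 100")
  labels <- as.integer(labels)
  i1 <- which(labels == 1L)
  i0 <- which(labels == 0L)
  check_that(length(i1) > 0L && length(i0) > 0L,
             "labels must contain both classes")
  aucs <- local_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      roc_auc(scores[idx], labels[idx])$auc
    }, 1.0)
  })
  alpha <- (1 - level) / 2
  unname(quantile(aucs, c(alpha, 1 - alpha)))
}

#' Mann-Whitney U test for a single feature
#'
#' Two-sided test of whether a feature separates the two groups. For
#' `n0 + n1 <= 12` the null distribution of U is enumerated exactly over all
#' label assignments (ties contribute 1/2 to U, so the enumeration stays
#' exact under ties); larger samples use the tie-corrected normal
#' approximation of [stats::wilcox.test()].
#'
#' @param values_group0,values_group1 numeric vectors of the feature values in
#'   the two groups (both nonempty).
#' @return two-sided p-value.
#' @export
#' @examples
#' mannwhitney_feature_test(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
mannwhitney_feature_test <- function(values_group0, values_group1) {
  n0 <- length(values_group0)
  n1 <- length(values_group1)
  check_that(n0 > 0L && n1 > 0L, "both groups must be nonempty")
  if (n0 + n1 <= 12L) {
    pooled <- c(values_group0, values_group1)
    n <- n0 + n1
    r <- rank(pooled)
    u_of <- function(idx0) sum(r[idx0]) - n0 * (n0 + 1) / 2
    mu <- n0 * n1 / 2
    dev_obs <- abs(u_of(seq_len(n0)) - mu)
    combs <- combn(n, n0)
    devs <- apply(combs, 2L, function(idx0) abs(u_of(idx0) - mu))
    return(mean(devs >= dev_obs - 1e-9))
  }
  suppressWarnings(
    wilcox.test(values_group0, values_group1, exact = FALSE,
                correct = FALSE)$p.value
  )
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' For every fold one case is held out. With `refit_per_fold = TRUE` (the
#' leakage-safe default) the KSVD dictionaries, FEDs, feature pooling, feature
#' selection, standardization and SVM are all fit on the remaining cases only,
#' and the held-out case is coded against the fold's FEDs and scored. With
#' `refit_per_fold = FALSE` dictionaries, features and selection are computed
#' once on all cases (the permissive protocol, kept for comparison) and only
#' the SVM is refit per fold; the flag is recorded in the report so the two
#' protocols are never conflated.
#'
#' @param dataset list of `mm_case` (e.g. `generate_dataset(...)$cases`), or a
#'   feature-matrix list as returned by [features_for_cases()] /
#'   [read_features()] (then dictionaries are fixed and the flag only controls
#'   per-fold feature selection).
#' @param config a [pipeline_config()].
#' @param refit_per_fold overrides `config$cv$refit_per_fold`.
#' @return an object of class `srt_eval`: `acc`, `sens`, `spec`, `auc`,
#'   `auc_ci`, `roc`, `n_pos`, `n_neg`, `folds` (one `FoldPrediction` row per
#'   case: `case_id`, `true_label`, `decision_score`, `predicted_label`),
#'   `refit_per_fold`, `fingerprint`, `config`.
#' @export
loocv_evaluate <- function(dataset, config,
                           refit_per_fold = config$cv$refit_per_fold) {
  check_that(inherits(config, "pipeline_config"),
             "config must be a pipeline_config")
  is_cases <- is.null(dataset$features)
  if (is_cases) {
    cases <- if (!is.null(dataset$cases)) dataset$cases else dataset
    check_that(length(cases) >= 4L, "need at least 2 cases per class")
    labels <- vapply(cases, function(cs) cs$label, 1L)
    ids <- vapply(cases, function(cs) cs$case_id, "")
  } else {
    labels <- as.integer(dataset$label)
    ids <- dataset$case_id
  }
  check_that(sum(labels == 0L) >= 2L && sum(labels == 1L) >= 2L,
             "need at least 2 cases per class")
  n <- length(labels)

  if (is_cases && !refit_per_fold) {
    feds <- train_dictionaries(cases, config)
    dataset <- features_for_cases(cases, feds, config)
    is_cases <- FALSE
  }

  k_sel <- config$selection$k_select
  scores <- numeric(n)
  preds <- integer(n)

  fit_and_score <- function(F_train, y_train, F_test, fold) {
    k <- if (is.na(k_sel)) min(nrow(F_train) - 1L, 30L) else
      min(k_sel, ncol(F_train))
    sel <- iterative_sr_selection(
      F_train, y_train,
      n_iterations = config$selection$n_iterations,
      subsample_fraction = config$selection$subsample_fraction,
      solver_sparsity = config$selection$solver_sparsity,
      k_select = k,
      seed = derive_seed(config$seed, paste0("select-fold", fold)),
      solver = config$selection$solver)
    cols <- sel$result$selected
    mdl <- train_weighted_svm(F_train[, cols, drop = FALSE], y_train,
                              kernel = config$svm$kernel, C = config$svm$C,
                              class_weighting = config$svm$weighting)
    predict(mdl, F_test[, cols, drop = FALSE])
  }

  if (is_cases && refit_per_fold) {
    for (i in seq_len(n)) {
      train_cases <- cases[-i]
      y_train <- labels[-i]
      check_that(length(unique(y_train)) == 2L,
                 "a fold has a single-class training set")
      feds <- train_dictionaries(train_cases, config)
      fm <- features_for_cases(train_cases, feds, config)
      F_test <- matrix(extract_case_features(cases[[i]], feds,
                                             config)$values, nrow = 1L)
      out <- fit_and_score(fm$features, y_train, F_test, i)
      scores[i] <- out$decision_score
      preds[i] <- out$predicted_label
    }
  } else {
    F_all <- dataset$features
    if (refit_per_fold) {
      for (i in seq_len(n)) {
        y_train <- labels[-i]
        check_that(length(unique(y_train)) == 2L,
                   "a fold has a single-class training set")
        out <- fit_and_score(F_all[-i, , drop = FALSE], y_train,
                             F_all[i, , drop = FALSE], i)
        scores[i] <- out$decision_score
        preds[i] <- out$predicted_label
      }
    } else {
      # selection once on all cases, SVM refit per fold
      k <- if (is.na(k_sel)) min(n - 1L, 30L) else min(k_sel, ncol(F_all))
      sel <- iterative_sr_selection(
        F_all, labels,
        n_iterations = config$selection$n_iterations,
        subsample_fraction = config$selection$subsample_fraction,
        solver_sparsity = config$selection$solver_sparsity,
        k_select = k,
        seed = derive_seed(config$seed, "select-full"),
        solver = config$selection$solver)
      cols <- sel$result$selected
      for (i in seq_len(n)) {
        y_train <- labels[-i]
        check_that(length(unique(y_train)) == 2L,
                   "a fold has a single-class training set")
        mdl <- train_weighted_svm(F_all[-i, cols, drop = FALSE], y_train,
                                  kernel = config$svm$kernel,
                                  C = config$svm$C,
                                  class_weighting = config$svm$weighting)
        out <- predict(mdl, F_all[i, cols, drop = FALSE])
        scores[i] <- out$decision_score
        preds[i] <- out$predicted_label
      }
    }
  }

  folds <- data.frame(case_id = ids, true_label = labels,
                      decision_score = scores, predicted_label = preds,
                      stringsAsFactors = FALSE)
  rownames(folds) <- NULL
  evaluation_report(folds, config, refit_per_fold)
}

# assemble an srt_eval report from fold predictions
evaluation_report <- function(folds, config, refit_per_fold) {
  cm <- confusion_metrics(folds)
  ra <- roc_auc(folds$decision_score, folds$true_label)
  ci <- bootstrap_auc_ci(folds$decision_score, folds$true_label,
                         n_boot = config$cv$n_boot,
                         level = config$cv$ci_level,
                         seed = derive_seed(config$seed, "bootstrap"))
  fp <- object_fingerprint(list(config = unclass(config),
                                refit_per_fold = refit_per_fold))
  structure(list(
    acc = cm$acc, sens = cm$sens, spec = cm$spec, auc = ra$auc,
    auc_ci = ci, roc = ra$roc, confusion = cm[c("tp", "fn", "tn", "fp")],
    n_pos = sum(folds$true_label == 1L),
    n_neg = sum(folds$true_label == 0L),
    folds = folds, refit_per_fold = refit_per_fold,
    fingerprint = fp, config = config
  ), class = "srt_eval")
}

#' @export
print.srt_eval <- function(x, ...) {
  cat("Leave-one-out evaluation (sparse-representation radiomics)\n")
  cat(sprintf("  n = %d (%d positive / %d negative), refit per fold: %s\n",
              x$n_pos + x$n_neg, x$n_pos, x$n_neg, x$refit_per_fold))
  cat(sprintf("  AUC %.3f (%d%% CI %.3f-%.3f)\n", x$auc,
              round(100 * x$config$cv$ci_level), x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  ACC %.3f  SENS %.3f  SPEC %.3f\n", x$acc, x$sens, x$spec))
  invisible(x)
}

#' @export
summary.srt_eval <- function(object, ...) {
  print(object)
  cat(sprintf("  confusion: TP %d, FN %d, TN %d, FP %d\n",
              object$confusion$tp, object$confusion$fn,
              object$confusion$tn, object$confusion$fp))
  cat(sprintf("  config fingerprint: %s\n", object$fingerprint))
  invisible(object)
}

#' @export
plot.srt_eval <- function(x, ...) {
  plot.default(x$roc$fpr, x$roc$tpr, type = "l",
               xlab = "False positive rate", ylab = "True positive rate",
               main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Write an evaluation report to JSON and the ROC curve to CSV
#'
#' @param report an `srt_eval`.
#' @param json_path output path for `report.json` (metrics, CI, confusion
#'   counts, config fingerprint, per-fold predictions).
#' @param roc_path optional output path for `roc.csv`
#'   (`threshold,fpr,tpr`).
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, roc_path = NULL) {
  out <- list(
    acc = report$acc, sens = report$sens, spec = report$spec,
    auc = report$auc,
    auc_ci = list(low = report$auc_ci[1], high = report$auc_ci[2],
                  level = report$config$cv$ci_level),
    confusion = report$confusion,
    n_pos = report$n_pos, n_neg = report$n_neg,
    refit_per_fold = report$refit_per_fold,
    fingerprint = report$fingerprint,
    folds = report$folds
  )
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(roc_path)) {
    write.csv(report$roc, roc_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
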