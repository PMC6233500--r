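# Central fitting surface: fit the full pipeline (dictionaries -> features ->
# selection -> SVM) on a dataset and return one classed model object.

#' Fit the sparse-representation radiomics model on a dataset
#'
#' Trains the per-class, per-channel KSVD dictionaries on all cases, extracts
#' the pooled sparse-coefficient feature vector of every case, runs iterative
#' sparse-representation feature selection, and fits the class-weighted SVM on
#' the selected features. The result predicts new cases end to end. For an
#' unbiased performance estimate use [loocv_evaluate()], which refits all of
#' these steps inside each fold.
#'
#' @param dataset list of `mm_case` (or the list returned by
#'   [generate_dataset()]).
#' @param config a [pipeline_config()].
#' @return an object of class `srt_model` with elements `feds`, `features`
#'   (the training feature matrix list), `selection`, `svm`, `config`,
#'   `fingerprint`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(modalities = c(gray = 1), n_atoms = 36,
#'                        ksvd_iters = 2,
#'                        generator = list(image_edge = 48, roi_edge = 32))
#' ds <- generate_dataset(3, cfg, seed = 1)
#' fit <- srt_fit(ds, cfg)
#' predict(fit, ds$cases[1:2])
#' }
srt_fit <- function(dataset, config) {
  check_that(inherits(config, "pipeline_config"),
             "config must be a pipeline_config")
  cases <- if (!is.null(dataset$cases)) dataset$cases else dataset
  labels <- vapply(cases, function(cs) cs$label, 1L)
  check_that(all(c(0L, 1L) %in% labels), "need cases from both classes")

  feds <- train_dictionaries(cases, config)
  fm <- features_for_cases(cases, feds, config)
  k_sel <- config$selection$k_select
  k <- if (is.na(k_sel)) min(nrow(fm$features) - 1L, 30L) else
    min(k_sel, ncol(fm$features))
  sel <- iterative_sr_selection(
    fm$features, fm$label,
    n_iterations = config$selection$n_iterations,
    subsample_fraction = config$selection$subsample_fraction,
    solver_sparsity = config$selection$solver_sparsity,
    k_select = k,
    seed = derive_seed(config$seed, "select-full"),
    solver = config$selection$solver)
  cols <- sel$result$selected
  mdl <- train_weighted_svm(fm$features[, cols, drop = FALSE], fm$label,
                            kernel = config$svm$kernel, C = config$svm$C,
                            class_weighting = config$svm$weighting)
  structure(list(
    feds = feds, features = fm, selection = sel, svm = mdl,
    selected = cols, config = config,
    fingerprint = object_fingerprint(unclass(config))
  ), class = "srt_model")
}

#' @export
#' @rdname srt_fit
#' @param object an `srt_model`.
#' @param newdata a single `mm_case`, a list of them, or a feature matrix
#'   whose columns match the training features.
#' @param ... unused.
predict.srt_model <- function(object, newdata, ...) {
  if (inherits(newdata, "mm_case")) newdata <- list(newdata)
  if (is.list(newdata) && length(newdata) &&
      inherits(newdata[[1L]], "mm_case")) {
    F <- do.call(rbind, lapply(newdata, function(cs)
      extract_case_features(cs, object$feds, object$config)$values))
    ids <- vapply(newdata, function(cs) cs$case_id, "")
  } else {
    F <- as.matrix(newdata)
    ids <- if (!is.null(rownames(F))) rownames(F) else
      sprintf("case_%d", seq_len(nrow(F)))
  }
  out <- predict(object$svm, F[, object$selected, drop = FALSE])
  cbind(data.frame(case_id = ids, stringsAsFactors = FALSE), out)
}

#' @export
print.srt_model <- function(x, ...) {
  nf <- ncol(x$features$features)
  cat("Sparse-representation radiomics model\n")
  cat(sprintf("  %d cases (%d / %d per class), %d features -> %d selected\n",
              length(x$features$label), sum(x$features$label == 0L),
              sum(x$features$label == 1L), nf, length(x$selected)))
  cat(sprintf("  dictionaries: %s\n", paste(names(x$feds), collapse = ", ")))
  cat(sprintf("  SVM: %s kernel, C = %g, %s weights\n",
              x$svm$kernel, x$svm$C, x$svm$class_weighting))
  invisible(x)
}

#' @export
summary.srt_model <- function(object, ...) {
  print(object)
  sc <- object$selection$importance$scores
  top <- head(object$selection$result$ranking, 10L)
  cat("  top features (importance):\n")
  for (j in top) {
    cat(sprintf("    f%04d  %.4g\n", j, sc[j]))
  }
  invisible(object)
}

#' @export
#' @rdname srt_fit
coef.srt_model <- function(object, ...) {
  sc <- object$selection$importance$scores
  stats::setNames(sc[object$selected],
                  sprintf("f%04d", object$selected))
}

#' @export
plot.srt_model <- function(x, ...) {
  sc <- x$selection$importance$scores
  plot.default(seq_along(sc), sc, type = "h",
               xlab = "feature index", ylab = "mean |SR coefficient|",
               main = "Sparse-representation feature importances", ...)
  invisible(x)
}
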