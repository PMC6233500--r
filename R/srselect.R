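# Iterative sparse-representation feature selection: sparsely regress the
# class labels on the feature columns, average absolute coefficients over
# stratified subsampled repetitions, rank and select.

# standardize columns to mean 0 / sd 1; constant columns become exact zeros
standardize_columns <- function(X) {
  cm <- colMeans(X)
  csd <- apply(X, 2L, sd)
  const <- !is.finite(csd) | csd < 1e-12
  csd[const] <- 1
  Z <- sweep(sweep(X, 2L, cm), 2L, csd, "/")
  Z[, const] <- 0
  list(Z = Z, center = cm, scale = csd, constant = const)
}

#' Sparse regression of labels on features
#'
#' Solves `labels ~ features %*% w` with a sparse solver over column-
#' standardized features; the absolute value of each coefficient is the
#' feature's importance. The default solver is OMP over the feature columns
#' (at most `solver_sparsity` nonzero weights); a lasso alternative (glmnet,
#' choosing the path point whose active set is closest to `solver_sparsity`)
#' is available with `solver = "lasso"`.
#'
#' @param features cases x features numeric matrix.
#' @param labels vector of class labels (0/1 or -1/+1; both classes must be
#'   present).
#' @param solver_sparsity maximum number of nonzero weights.
#' @param solver `"omp"` or `"lasso"`.
#' @return numeric weight vector, one entry per feature (exact zeros off the
#'   active set; constant columns always get weight 0).
#' @export
sr_importance <- function(features, labels, solver_sparsity = 10L,
                          solver = c("omp", "lasso")) {
  solver <- match.arg(solver)
  check_that(is.matrix(features), "features must be a matrix")
  check_that(nrow(features) == length(labels),
             "rows of features must match the labels")
  y <- as.integer(labels %in% c(1L, 1)) * 2L - 1L
  if (all(labels %in% c(-1, 1))) y <- as.integer(labels)
  check_that(length(unique(y)) == 2L,
             "labels must contain both classes")
  st <- standardize_columns(features)
  Z <- st$Z
  p <- ncol(Z)
  s <- min(as.integer(solver_sparsity), nrow(Z) - 1L, p)
  check_that(s >= 1L, "solver_sparsity must allow at least one feature")

  if (solver == "lasso") {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      stop("solver = \"lasso\" needs the glmnet package", call. = FALSE)
    }
    fit <- glmnet::glmnet(Z, y, standardize = FALSE, intercept = TRUE)
    df <- fit$df
    pick <- which.min(abs(df - s))  # ties: largest lambda (first index)
    w <- as.numeric(coef(fit, s = fit$lambda[pick]))[-1L]
    w[st$constant] <- 0
    return(w)
  }

  # OMP over unit-normalized standardized columns; weights mapped back to the
  # standardized scale (all non-constant columns share the same norm, so the
  # greedy selection order is unaffected)
  nrm <- sqrt(colSums(Z^2))
  keep <- nrm > 0
  w <- numeric(p)
  if (any(keep)) {
    Zn <- sweep(Z[, keep, drop = FALSE], 2L, nrm[keep], "/")
    wk <- omp_encode(Zn, matrix(as.numeric(y), ncol = 1L), s)[, 1L]
    w[keep] <- wk / nrm[keep]
  }
  w
}

#' Iterative sparse-representation feature selection
#'
#' Each iteration draws a class-stratified subsample of the cases without
#' replacement, runs [sr_importance()], and accumulates the absolute
#' coefficients; the final score of a feature is the mean absolute coefficient
#' over iterations. Features are ranked by descending score (ties broken by
#' ascending feature index) and the top `k_select` are selected.
#'
#' @param features cases x features matrix.
#' @param labels class labels (0/1).
#' @param n_iterations number of subsampled repetitions.
#' @param subsample_fraction fraction of each class drawn per iteration (the
#'   per-class draw is `ceiling(fraction * n_class)` and must be >= 2).
#' @param solver_sparsity sparsity of each regression.
#' @param k_select number of features to select.
#' @param seed master seed (per-iteration seeds are derived from it).
#' @param solver `"omp"` or `"lasso"`.
#' @return list with `importance` (class `sr_importance_scores`: `scores`,
#'   `n_iterations`, `subsample_fraction`, `seed`) and `result` (class
#'   `sr_selection`: `ranking`, `selected`, `k`).
#' @export
#' @examples
#' X <- matrix(rnorm(40 * 20), 40, 20)
#' y <- as.integer(X[, 3] > 0)
#' sel <- iterative_sr_selection(X, y, n_iterations = 5, k_select = 5,
#'                               seed = 1)
#' sel$result$selected
iterative_sr_selection <- function(features, labels, n_iterations = 50L,
                                   subsample_fraction = 0.8,
                                   solver_sparsity = 10L, k_select = 30L,
                                   seed = 1L, solver = "omp") {
  check_that(n_iterations >= 1L, "n_iterations must be >= 1")
  check_that(subsample_fraction > 0 && subsample_fraction <= 1,
             "subsample_fraction must lie in (0, 1]")
  check_that(k_select >= 1L && k_select <= ncol(features),
             "k_select must lie in [1, n_features]")
  labels <- as.integer(labels)
  idx0 <- which(labels == 0L)
  idx1 <- which(labels != 0L)
  n_draw0 <- ceiling(subsample_fraction * length(idx0))
  n_draw1 <- ceiling(subsample_fraction * length(idx1))
  check_that(n_draw0 >= 2L && n_draw1 >= 2L,
             "subsample must keep at least 2 cases per class")

  acc <- numeric(ncol(features))
  for (it in seq_len(n_iterations)) {
    sub <- local_seed(derive_seed(seed, paste0("srsel-it", it)), {
      c(sample(idx0, n_draw0), sample(idx1, n_draw1))
    })
    w <- sr_importance(features[sub, , drop = FALSE], labels[sub],
                       solver_sparsity = solver_sparsity, solver = solver)
    acc <- acc + abs(w)
  }
  scores <- acc / n_iterations
  ranking <- order(-scores, seq_along(scores))
  list(
    importance = structure(list(scores = scores,
                                n_iterations = as.integer(n_iterations),
                                subsample_fraction = subsample_fraction,
                                seed = as.integer(seed)),
                           class = "sr_importance_scores"),
    result = structure(list(ranking = ranking,
                            selected = ranking[seq_len(k_select)],
                            k = as.integer(k_select)),
                       class = "sr_selection")
  )
}

#' @export
print.sr_selection <- function(x, ...) {
  cat(sprintf("<sr_selection> top %d of %d features: %s%s\n", x$k,
              length(x$ranking),
              paste(head(x$selected, 10L), collapse = ", "),
              if (x$k > 10L) ", ..." else ""))
  invisible(x)
}

#' Write importances and selection to CSV + JSON run record
#'
#' @param sel result of [iterative_sr_selection()].
#' @param path CSV path (`feature`, `score`, `rank`, `selected`); a JSON run
#'   record is written next to it as `<path>.run.json`.
#' @param solver solver recorded in the run record.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path, solver = "omp") {
  sc <- sel$importance$scores
  rk <- integer(length(sc))
  rk[sel$result$ranking] <- seq_along(sc)
  df <- data.frame(feature = sprintf("f%04d", seq_along(sc)),
                   score = sc, rank = rk,
                   selected = seq_along(sc) %in% sel$result$selected)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(seed = sel$importance$seed,
                            n_iterations = sel$importance$n_iterations,
                            subsample_fraction =
                              sel$importance$subsample_fraction,
                            solver = solver, k_select = sel$result$k),
                       paste0(path, ".run.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
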