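# Dictionary learning: overcomplete DCT initialization, KSVD training, and
# assembly of per-class dictionaries into the feature extraction dictionary.

new_dictionary <- function(atoms, patch_edge, class_label = NA_integer_,
                           modality = NA_character_,
                           channel = NA_character_, rmse = numeric(0)) {
  stopifnot(nrow(atoms) == patch_edge^2)
  structure(list(
    atoms = atoms,
    patch_edge = as.integer(patch_edge),
    class_label = as.integer(class_label),
    modality = as.character(modality),
    channel = as.character(channel),
    rmse = as.double(rmse)
  ), class = "sr_dictionary")
}

#' @export
print.sr_dictionary <- function(x, ...) {
  cat(sprintf("<sr_dictionary> %d x %d (patch %dx%d)", nrow(x$atoms),
              ncol(x$atoms), x$patch_edge, x$patch_edge))
  if (!is.na(x$class_label)) cat(sprintf(", class %d", x$class_label))
  if (!is.na(x$modality)) cat(sprintf(", %s/%s", x$modality, x$channel))
  if (length(x$rmse)) {
    cat(sprintf("; training RMSE %.4g -> %.4g (%d iterations)",
                x$rmse[1], x$rmse[length(x$rmse)], length(x$rmse) - 1L))
  }
  cat("\n")
  invisible(x)
}

#' Overcomplete 2-D DCT dictionary
#'
#' The standard overcomplete DCT construction: `sqrt(n_atoms)` sampled cosine
#' atoms of length `patch_edge` (`cos(pi * k * i / m)`, `i = 0..patch_edge-1`,
#' `k = 0..m-1`), each non-DC 1-D atom mean-removed, all pairwise outer
#' products vectorized as columns and L2-normalized. The first column is the
#' DC atom (constant `1/patch_edge`). When `n_atoms = patch_edge^2` this
#' reduces to an orthonormal separable cosine basis.
#'
#' @param patch_edge patch edge length (atoms are `patch_edge^2`-vectors).
#' @param n_atoms number of atoms; must be a perfect square with
#'   `sqrt(n_atoms) >= patch_edge`.
#' @param class_label,modality,channel optional metadata tags carried on the
#'   dictionary.
#' @return an `sr_dictionary` of dimension `patch_edge^2 x n_atoms`.
#' @export
#' @examples
#' d <- init_dct_dictionary(8, 256)
#' dim(d$atoms)          # 64 256
#' range(colSums(d$atoms^2))  # all 1
init_dct_dictionary <- function(patch_edge, n_atoms,
                                class_label = NA_integer_,
                                modality = NA_character_,
                                channel = NA_character_) {
  m <- sqrt(n_atoms)
  check_that(m == round(m), "n_atoms must be a perfect square")
  m <- as.integer(round(m))
  check_that(m >= patch_edge, "sqrt(n_atoms) must be >= patch_edge")
  p <- as.integer(patch_edge)
  V <- outer(0:(p - 1L), 0:(m - 1L), function(i, k) cospi(k * i / m))
  V[, -1L] <- sweep(V[, -1L, drop = FALSE], 2,
                    colMeans(V[, -1L, drop = FALSE]))
  # column order: (k1, k2) with k2 fastest; column 1 is the DC x DC product
  D <- matrix(0, p * p, m * m)
  for (k1 in seq_len(m)) {
    for (k2 in seq_len(m)) {
      # vectorization is row-major over the patch: entry (r, c) at index
      # (r-1)*p + c, matching extract_patches()
      D[, (k1 - 1L) * m + k2] <- as.vector(outer(V[, k1], V[, k2]))
    }
  }
  new_dictionary(normalize_columns(D), p, class_label, modality, channel)
}

#' Sparse-code a batch of signals with OMP
#'
#' Thin wrapper over the compiled batch OMP used by both KSVD training and
#' feature extraction. Greedy atom selection by maximal absolute correlation
#' with the residual (ties to the lowest atom index), least-squares refit on
#' the selected set at every step, stopping at `sparsity` atoms or residual
#' norm below `res_tol`.
#'
#' @param dict_matrix patch_dim x n_atoms matrix with unit-norm columns.
#' @param signals patch_dim x n_signals matrix.
#' @param sparsity maximum atoms per signal.
#' @param res_tol residual-norm stopping tolerance.
#' @return dense n_atoms x n_signals coefficient matrix.
#' @export
omp_encode <- function(dict_matrix, signals, sparsity, res_tol = 1e-10) {
  check_that(is.matrix(dict_matrix) && is.matrix(signals),
             "dictionary and signals must be matrices")
  check_that(nrow(dict_matrix) == nrow(signals),
             "dictionary and signals must share the patch dimension")
  check_that(sparsity >= 1, "sparsity must be >= 1")
  omp_encode_cpp(dict_matrix, signals, as.integer(sparsity), res_tol)
}

ksvd_rmse <- function(X, D, W) sqrt(mean((X - D %*% W)^2))

#' Train a dictionary with KSVD
#'
#' Classical KSVD: alternate batch OMP sparse coding (at `code_sparsity` atoms
#' per patch) with sequential rank-1 SVD updates of each atom together with its
#' active coefficients. Two standard safeguards keep the dictionary healthy
#' and the objective monotone:
#'
#' * *Atom cleanup.* Atoms unused by the current code, atoms active on fewer
#'   than `use_min` patches, and near-duplicate atoms (mutual coherence above
#'   `mu_max`) are replaced by the worst-represented patch (normalized; ties
#'   broken by the lowest patch index). The cleanup step is accepted only if
#'   it does not increase the training RMSE, so the reported RMSE trace is
#'   non-increasing by construction.
#' * *Guarded recoding.* After each sweep the patches are recoded with OMP,
#'   but a patch keeps its previous (still valid) code whenever that code has
#'   the smaller residual — greedy recoding alone cannot otherwise guarantee
#'   improvement.
#'
#' After every update the atom's sign is fixed so its first nonzero entry is
#' nonnegative, making training fully deterministic. Stops after `n_iters`
#' iterations or when the RMSE improvement falls below `tol_improve`.
#'
#' @param patches a `patch_matrix` (see [extract_patches()]) or a plain
#'   patch_dim x n_patches matrix.
#' @param init initial `sr_dictionary` (typically [init_dct_dictionary()]).
#' @param code_sparsity OMP sparsity during training.
#' @param n_iters maximum KSVD iterations; `0` returns `init` unchanged.
#' @param seed accepted for interface stability; the algorithm as implemented
#'   is deterministic and never consumes randomness.
#' @param tol_improve early-stopping threshold on per-iteration RMSE
#'   improvement.
#' @param use_min replace atoms active on fewer than this many patches;
#'   default: a third of the expected per-atom usage
#'   `n_patches * code_sparsity / n_atoms`, at least 1 (1 replaces only
#'   completely unused atoms).
#' @param mu_max coherence threshold above which the lower-indexed duplicate
#'   atom survives and the other is replaced.
#' @return an `sr_dictionary` with the trained atoms and the per-iteration
#'   training RMSE trace in `$rmse` (first entry: RMSE of coding against
#'   `init`).
#' @export
ksvd_train <- function(patches, init, code_sparsity = 5L, n_iters = 30L,
                       seed = 1L, tol_improve = 1e-5, use_min = NULL,
                       mu_max = 0.99) {
  X <- if (inherits(patches, "patch_matrix")) patches$data else patches
  check_that(is.matrix(X) && ncol(X) >= 1L, "patch matrix is empty")
  check_that(inherits(init, "sr_dictionary"), "init must be an sr_dictionary")
  check_that(nrow(X) == nrow(init$atoms),
             "patch dimension does not match the dictionary")
  check_that(code_sparsity >= 1L, "code_sparsity must be >= 1")
  if (ncol(X) < ncol(init$atoms)) {
    warning("fewer patches than atoms; the dictionary may be underdetermined")
  }
  if (n_iters == 0L) return(init)

  D <- init$atoms
  K <- ncol(D)
  if (is.null(use_min)) {
    use_min <- max(1L, floor(ncol(X) * code_sparsity / K / 3))
  }
  W <- omp_encode(D, X, code_sparsity)
  trace <- ksvd_rmse(X, D, W)

  recode_guarded <- function(D, W_old) {
    W_new <- omp_encode(D, X, code_sparsity)
    e_new <- colSums((X - D %*% W_new)^2)
    e_old <- colSums((X - D %*% W_old)^2)
    keep <- e_old < e_new
    W_new[, keep] <- W_old[, keep]
    W_new
  }

  for (it in seq_len(n_iters)) {
    for (k in seq_len(K)) {
      I <- which(W[k, ] != 0)
      if (!length(I)) next
      # residual with atom k's contribution restored
      Ek <- X[, I, drop = FALSE] - D %*% W[, I, drop = FALSE] +
        tcrossprod(D[, k], W[k, I])
      sv <- svd(Ek, nu = 1L, nv = 1L)
      d_new <- sv$u[, 1L]
      g_new <- sv$d[1L] * sv$v[, 1L]
      if (sign_mismatch(d_new)) {
        d_new <- -d_new
        g_new <- -g_new
      }
      D[, k] <- d_new
      W[k, I] <- g_new
    }
    W <- recode_guarded(D, W)
    rmse_sweep <- ksvd_rmse(X, D, W)

    # cleanup: unused / under-used / duplicate atoms <- worst patches;
    # accepted only if the objective does not get worse
    res_norm <- colSums((X - D %*% W)^2)
    worst <- order(-res_norm, seq_along(res_norm))
    usage <- rowSums(W != 0)
    Gm <- abs(crossprod(D))
    diag(Gm) <- 0
    D2 <- D
    replaced <- logical(K)
    pick <- 1L
    for (k in seq_len(K)) {
      if (usage[k] >= use_min && max(Gm[k, ]) <= mu_max) next
      while (pick <= length(worst) &&
             sum(X[, worst[pick]]^2) < 1e-20) pick <- pick + 1L
      if (pick > length(worst)) break
      v <- X[, worst[pick]]
      D2[, k] <- sign_fix(v / sqrt(sum(v^2)))
      replaced[k] <- TRUE
      Gm[k, ] <- 0
      Gm[, k] <- 0
      pick <- pick + 1L
    }
    if (any(replaced)) {
      W_stub <- W
      W_stub[replaced, ] <- 0
      W2 <- recode_guarded(D2, W_stub)
      rmse_clean <- ksvd_rmse(X, D2, W2)
      if (rmse_clean <= rmse_sweep) {
        D <- D2
        W <- W2
        rmse_sweep <- rmse_clean
      }
    }
    trace <- c(trace, rmse_sweep)
    n <- length(trace)
    if (trace[n - 1L] - trace[n] < tol_improve) break
  }
  new_dictionary(D, init$patch_edge, init$class_label, init$modality,
                 init$channel, rmse = trace)
}

# TRUE if the first entry with |v| > tol is negative
sign_mismatch <- function(v, tol = 1e-12) {
  idx <- which(abs(v) > tol)
  length(idx) > 0L && v[idx[1L]] < 0
}

#' Assemble class dictionaries into a feature extraction dictionary (FED)
#'
#' Horizontally concatenates per-class dictionaries (class 0 block first, then
#' class 1) into one coding matrix, with a block map recording, for every atom
#' column, its class, modality, channel and within-block index. A signal's
#' coefficient distribution across the class blocks is the discriminative
#' feature downstream.
#'
#' @param dicts list of `sr_dictionary` objects sharing `patch_edge`, exactly
#'   one per (class, channel) pair.
#' @return an object of class `sr_fed` with fields `blocks`, `combined`
#'   (patch_dim x total_atoms) and `block_map` (data frame with columns
#'   `index`, `class_label`, `modality`, `channel`, `within`).
#' @export
#' @examples
#' d0 <- init_dct_dictionary(4, 16, class_label = 0, channel = "gray")
#' d1 <- init_dct_dictionary(4, 16, class_label = 1, channel = "gray")
#' fed <- build_fed(list(d0, d1))
#' ncol(fed$combined)  # 32
build_fed <- function(dicts) {
  check_that(length(dicts) >= 1L, "need at least one dictionary")
  check_that(all(vapply(dicts, inherits, TRUE, "sr_dictionary")),
             "all elements must be sr_dictionary objects")
  pd <- vapply(dicts, function(d) nrow(d$atoms), 1L)
  check_that(length(unique(pd)) == 1L,
             "dictionaries have mismatched patch dimensions")
  keys <- vapply(dicts, function(d)
    paste(d$class_label, d$channel, sep = "|"), "")
  check_that(!anyDuplicated(keys),
             "duplicate (class, channel) dictionary")
  ord <- order(vapply(dicts, function(d) d$class_label, 1L))
  dicts <- dicts[ord]

  combined <- do.call(cbind, lapply(dicts, function(d) d$atoms))
  block_map <- do.call(rbind, lapply(seq_along(dicts), function(b) {
    d <- dicts[[b]]
    data.frame(block = b, class_label = d$class_label,
               modality = d$modality, channel = d$channel,
               within = seq_len(ncol(d$atoms)), stringsAsFactors = FALSE)
  }))
  block_map$index <- seq_len(nrow(block_map))
  structure(list(blocks = dicts, combined = combined,
                 block_map = block_map,
                 patch_edge = dicts[[1L]]$patch_edge),
            class = "sr_fed")
}

#' @export
print.sr_fed <- function(x, ...) {
  cat(sprintf("<sr_fed> %d atoms in %d blocks (patch %dx%d): %s\n",
              ncol(x$combined), length(x$blocks), x$patch_edge, x$patch_edge,
              paste(vapply(x$blocks, function(d)
                sprintf("class %d (%d)", d$class_label, ncol(d$atoms)), ""),
                collapse = ", ")))
  invisible(x)
}

#' Train per-class, per-channel dictionaries from a set of cases
#'
#' For each configured (modality, coding channel) and each class, pools the
#' mean-removed ROI patches of that class's cases and runs KSVD from the DCT
#' initialization; the two class dictionaries are then combined into one FED
#' per (modality, channel).
#'
#' @param cases list of `mm_case`.
#' @param config a [pipeline_config()].
#' @param seed seed forwarded to [ksvd_train()] (deterministic; kept for
#'   interface stability).
#' @return named list of `sr_fed`, keyed `"modality:channel"`.
#' @export
train_dictionaries <- function(cases, config, seed = config$seed) {
  labels <- vapply(cases, function(cs) cs$label, 1L)
  check_that(all(c(0L, 1L) %in% labels), "need cases from both classes")
  feds <- list()
  for (mod in names(config$modalities)) {
    for (ch in coding_channels(config$modalities[[mod]])) {
      dicts <- lapply(0:1, function(cl) {
        P <- do.call(cbind, lapply(cases[labels == cl], function(cs) {
          roi <- case_channel_roi(cs, mod, ch)
          extract_patches(roi, config$patch_edge, config$stride)$data
        }))
        init <- init_dct_dictionary(config$patch_edge, config$n_atoms,
                                    class_label = cl, modality = mod,
                                    channel = ch)
        ksvd_train(P, init, code_sparsity = config$omp_sparsity,
                   n_iters = config$ksvd_iters,
                   seed = derive_seed(seed, paste("ksvd", mod, ch, cl)))
      })
      feds[[paste(mod, ch, sep = ":")]] <- build_fed(dicts)
    }
  }
  feds
}

#' Persist / load a dictionary as CSV + JSON sidecar
#'
#' The CSV holds one atom per column (`atom0001`, ...); the JSON sidecar holds
#' `patch_edge`, `class_label`, `modality`, `channel` and the training RMSE
#' trace.
#'
#' @param dict an `sr_dictionary`.
#' @param path_prefix output path without extension; writes
#'   `<path_prefix>.csv` and `<path_prefix>.json`.
#' @return `write_dictionary` returns `path_prefix` invisibly;
#'   `read_dictionary` returns an `sr_dictionary`.
#' @export
write_dictionary <- function(dict, path_prefix) {
  # full double precision (%.17g) so reloaded dictionaries reproduce OMP
  # atom selections bit for bit
  A <- as.data.frame(apply(dict$atoms, 2, function(x) sprintf("%.17g", x)),
                     stringsAsFactors = FALSE)
  names(A) <- sprintf("atom%04d", seq_len(ncol(dict$atoms)))
  write.csv(A, paste0(path_prefix, ".csv"), row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(list(patch_edge = dict$patch_edge,
                            class_label = dict$class_label,
                            modality = dict$modality,
                            channel = dict$channel,
                            rmse = dict$rmse),
                       paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path_prefix) {
  A <- as.matrix(read.csv(paste0(path_prefix, ".csv")))
  dimnames(A) <- NULL
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  new_dictionary(A, meta$patch_edge, meta$class_label, meta$modality,
                 meta$channel, rmse = meta$rmse)
}
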