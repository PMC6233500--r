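#' Pipeline configuration
#'
#' Builds the single configuration object every pipeline stage reads its
#' parameters from. Defaults mirror the study design the package implements:
#' 8x8 patches and 256-atom dictionaries (a 64 x 256 dictionary per class per
#' channel), grayscale plus two pseudo-color modalities, mean-absolute pooling,
#' leakage-safe leave-one-out refitting.
#'
#' @param modalities named integer vector or list mapping modality name to the
#'   number of display channels (1 = grayscale, 3 = pseudo-color; pseudo-color
#'   modalities are coded through their HSV hue and value channels).
#' @param patch_edge patch edge length in pixels; patches are
#'   `patch_edge^2`-dimensional vectors.
#' @param n_atoms atoms per class dictionary (must be a perfect square for the
#'   DCT initialization).
#' @param omp_sparsity number of atoms OMP may select per patch, used both
#'   during KSVD training and at feature extraction.
#' @param ksvd_iters KSVD iterations.
#' @param stride patch-grid stride in pixels; defaults to `patch_edge`
#'   (non-overlapping tiling).
#' @param pooling `"mean"` (default) or `"max"` pooling of absolute
#'   coefficients over ROI patches.
#' @param selection list with `n_iterations`, `subsample_fraction`,
#'   `solver` (`"omp"` or `"lasso"`), `solver_sparsity` and `k_select`
#'   (`NA` = choose `min(n_cases - 1, 30)` at fit time).
#' @param svm list with `kernel` (`"linear"` or `"rbf"`), `C`, and `weighting`
#'   (`"balanced"` or `"none"`).
#' @param cv list with `refit_per_fold` (logical), `n_boot` and `ci_level` for
#'   the bootstrap AUC interval.
#' @param generator list of synthetic-generator settings: `image_edge`,
#'   `roi_edge`, `n_gen_atoms`, `gen_sparsity`, `noise_sigma`,
#'   `disjoint_support`.
#' @param seed master seed for every stochastic stage.
#' @return an object of class `pipeline_config` (a validated named list).
#' @export
#' @examples
#' cfg <- pipeline_config(modalities = c(gray = 1), n_atoms = 64)
#' cfg$n_atoms
pipeline_config <- function(modalities = c(gray = 1L, elasto = 3L, visco = 3L),
                            patch_edge = 8L,
                            n_atoms = 256L,
                            omp_sparsity = 5L,
                            ksvd_iters = 30L,
                            stride = NULL,
                            pooling = c("mean", "max"),
                            selection = list(),
                            svm = list(),
                            cv = list(),
                            generator = list(),
                            seed = 1L) {
  pooling <- match.arg(pooling)
  cfg <- list(
    modalities = modalities,
    patch_edge = patch_edge,
    n_atoms = n_atoms,
    omp_sparsity = omp_sparsity,
    ksvd_iters = ksvd_iters,
    stride = if (is.null(stride)) patch_edge else stride,
    pooling = pooling,
    selection = utils::modifyList(list(
      n_iterations = 50L, subsample_fraction = 0.8,
      solver = "omp", solver_sparsity = 10L, k_select = NA_integer_
    ), selection),
    svm = utils::modifyList(list(
      kernel = "linear", C = 1, weighting = "balanced"
    ), svm),
    cv = utils::modifyList(list(
      refit_per_fold = TRUE, n_boot = 2000L, ci_level = 0.95
    ), cv),
    generator = utils::modifyList(list(
      image_edge = 96L, roi_edge = 64L, n_gen_atoms = 32L,
      gen_sparsity = 3L, noise_sigma = 0.02, disjoint_support = FALSE
    ), generator),
    seed = seed
  )
  as_pipeline_config(cfg)
}

#' Coerce a plain list to a validated pipeline configuration
#'
#' Canonicalizes field types (integer counts, double rates, logical flags) so
#' that save/load round trips reproduce the object exactly.
#'
#' @param x a named list with the fields of [pipeline_config()].
#' @return a `pipeline_config` object.
#' @export
as_pipeline_config <- function(x) {
  check_that(is.list(x), "config must be a list")
  mods <- x$modalities
  if (is.list(mods)) mods <- unlist(mods)
  check_that(!is.null(names(mods)) && all(nzchar(names(mods))),
             "modalities must be named")
  check_that(all(mods %in% c(1L, 3L)), "modality channel counts must be 1 or 3")
  mods <- stats::setNames(as.integer(mods), names(mods))

  cfg <- list(
    modalities = mods,
    patch_edge = as.integer(x$patch_edge),
    n_atoms = as.integer(x$n_atoms),
    omp_sparsity = as.integer(x$omp_sparsity),
    ksvd_iters = as.integer(x$ksvd_iters),
    stride = as.integer(x$stride),
    pooling = as.character(x$pooling),
    selection = list(
      n_iterations = as.integer(x$selection$n_iterations),
      subsample_fraction = as.double(x$selection$subsample_fraction),
      solver = as.character(x$selection$solver),
      solver_sparsity = as.integer(x$selection$solver_sparsity),
      k_select = as.integer(x$selection$k_select)
    ),
    svm = list(
      kernel = as.character(x$svm$kernel),
      C = as.double(x$svm$C),
      weighting = as.character(x$svm$weighting)
    ),
    cv = list(
      refit_per_fold = as.logical(x$cv$refit_per_fold),
      n_boot = as.integer(x$cv$n_boot),
      ci_level = as.double(x$cv$ci_level)
    ),
    generator = list(
      image_edge = as.integer(x$generator$image_edge),
      roi_edge = as.integer(x$generator$roi_edge),
      n_gen_atoms = as.integer(x$generator$n_gen_atoms),
      gen_sparsity = as.integer(x$generator$gen_sparsity),
      noise_sigma = as.double(x$generator$noise_sigma),
      disjoint_support = as.logical(x$generator$disjoint_support)
    ),
    seed = as.integer(x$seed)
  )
  check_that(cfg$patch_edge >= 2L, "patch_edge must be >= 2")
  check_that(cfg$n_atoms >= 1L, "n_atoms must be positive")
  check_that(cfg$omp_sparsity >= 1L, "omp_sparsity must be >= 1")
  check_that(cfg$stride >= 1L, "stride must be >= 1")
  check_that(cfg$pooling %in% c("mean", "max"), "pooling must be mean or max")
  check_that(cfg$selection$solver %in% c("omp", "lasso"),
             "selection solver must be omp or lasso")
  check_that(cfg$svm$kernel %in% c("linear", "rbf"),
             "svm kernel must be linear or rbf")
  check_that(cfg$svm$weighting %in% c("balanced", "none"),
             "svm weighting must be balanced or none")
  check_that(cfg$generator$roi_edge %% cfg$patch_edge == 0L,
             "generator roi_edge must be a multiple of patch_edge")
  structure(cfg, class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' The on-disk form is a flat-ish YAML document; `load_config(save_config(cfg))`
#' returns an object identical to `cfg`.
#'
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns a
#'   `pipeline_config`.
#' @export
save_config <- function(cfg, path) {
  check_that(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  x <- unclass(cfg)
  x$modalities <- as.list(x$modalities)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  as_pipeline_config(yaml::read_yaml(path))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat("  modalities: ",
      paste(sprintf("%s(%dch)", names(x$modalities), x$modalities),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  dictionary: %d x %d per class per channel (patch %dx%d)\n",
              x$patch_edge^2, x$n_atoms, x$patch_edge, x$patch_edge))
  cat(sprintf("  OMP sparsity %d, KSVD iterations %d, pooling %s\n",
              x$omp_sparsity, x$ksvd_iters, x$pooling))
  cat(sprintf("  selection: %s, %d iterations, fraction %.2f, k = %s\n",
              x$selection$solver, x$selection$n_iterations,
              x$selection$subsample_fraction,
              ifelse(is.na(x$selection$k_select), "auto",
                     x$selection$k_select)))
  cat(sprintf("  SVM: %s kernel, C = %g, %s weights; refit per fold: %s\n",
              x$svm$kernel, x$svm$C, x$svm$weighting, x$cv$refit_per_fold))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# expected per-case feature vector length for a configuration
config_feature_length <- function(cfg, n_classes = 2L) {
  feature_vector_length(cfg$modalities, n_classes = n_classes,
                        n_atoms = cfg$n_atoms)
}
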