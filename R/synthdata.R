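# Synthetic two-class multi-modal texture generator.
#
# Real clinical ultrasound studies behind this kind of pipeline are not
# publicly deposited, so the generator emulates the statistical structure the
# pipeline assumes: square ROIs whose patches are sparse nonnegative
# combinations of class-specific smooth texture atoms plus Gaussian noise,
# rendered as grayscale images and as pseudo-color maps (elastography-like)
# through a fixed blue-to-red colormap whose HSV value channel is monotone in
# the underlying intensity.

# 2-D "same" filtering with zero padding (kernels here are symmetric, so
# convolution and correlation coincide; direct shifts beat FFT at these sizes)
conv2_same <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kern); kc <- ncol(kern)
  cr <- (kr + 1L) %/% 2L; cc <- (kc + 1L) %/% 2L
  pad <- matrix(0, nr + kr - 1L, nc + kc - 1L)
  pad[cr:(cr + nr - 1L), cc:(cc + nc - 1L)] <- img
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      out <- out + kern[a, b] *
        pad[a:(a + nr - 1L), b:(b + nc - 1L), drop = FALSE]
    }
  }
  out
}

# oriented anisotropic Gaussian smoothing kernel; class 0 smooths along rows
# (horizontal streaks), class 1 along columns, giving the two classes
# distinguishable texture statistics
oriented_kernel <- function(class_index, half = 2L, sigma_major = 2.0,
                            sigma_minor = 0.6) {
  g <- expand.grid(u = -half:half, v = -half:half)
  if (class_index == 0L) {
    k <- exp(-(g$v^2 / (2 * sigma_major^2) + g$u^2 / (2 * sigma_minor^2)))
  } else {
    k <- exp(-(g$u^2 / (2 * sigma_major^2) + g$v^2 / (2 * sigma_minor^2)))
  }
  k <- matrix(k, nrow = 2L * half + 1L)
  k / sum(k)
}

#' Create a class-specific texture model
#'
#' A texture model holds a bank of nonnegative, unit-norm smooth atoms from
#' which ROI patches are synthesized as sparse nonnegative combinations. Atoms
#' are random Gaussian fields smoothed with a class-dependent oriented kernel
#' (class 0: horizontal streaks; class 1: vertical), shifted to be nonnegative
#' and L2-normalized, so the two classes have distinguishable second-order
#' texture statistics.
#'
#' @param class_index 0 or 1.
#' @param patch_edge patch edge in pixels (>= 2).
#' @param n_gen_atoms number of generator atoms.
#' @param gen_sparsity atoms per synthesized patch (<= `n_gen_atoms`).
#' @param noise_sigma additive Gaussian noise standard deviation in intensity
#'   units (applied at synthesis time).
#' @param seed integer seed; the same arguments and seed give bitwise-identical
#'   atoms.
#' @param disjoint_support if `TRUE`, class 0 atoms are supported on the top
#'   half of the patch and class 1 atoms on the bottom half, making the two
#'   classes perfectly separable (useful for separability checks).
#' @return an object of class `texture_model`.
#' @export
#' @examples
#' tm <- make_texture_model(0L, patch_edge = 8, n_gen_atoms = 16,
#'                          gen_sparsity = 3, noise_sigma = 0, seed = 1)
#' colSums(tm$atoms^2)[1:3]  # unit norms
make_texture_model <- function(class_index, patch_edge = 8L,
                               n_gen_atoms = 32L, gen_sparsity = 3L,
                               noise_sigma = 0.02, seed = 1L,
                               disjoint_support = FALSE) {
  check_that(class_index %in% c(0L, 1L), "class_index must be 0 or 1")
  check_that(patch_edge >= 2L, "patch_edge must be >= 2")
  check_that(gen_sparsity >= 1L && n_gen_atoms >= gen_sparsity,
             "need n_gen_atoms >= gen_sparsity >= 1")
  check_that(noise_sigma >= 0, "noise_sigma must be nonnegative")

  kern <- oriented_kernel(as.integer(class_index))
  p <- as.integer(patch_edge)
  atoms <- local_seed(as.integer(seed), {
    vapply(seq_len(n_gen_atoms), function(a) {
      f <- matrix(rnorm(p * p), p, p)
      s <- conv2_same(f, kern)
      if (disjoint_support) {
        half <- p %/% 2L
        keep <- if (class_index == 0L) seq_len(half) else (half + 1L):p
        mask <- matrix(0, p, p)
        mask[keep, ] <- 1
        s <- s * mask
        s[keep, ] <- s[keep, ] - min(s[keep, ])
      } else {
        s <- s - min(s)
      }
      v <- as.vector(s)
      v / sqrt(sum(v^2))
    }, numeric(p * p))
  })
  structure(list(
    class_index = as.integer(class_index),
    atoms = atoms,
    patch_edge = p,
    gen_sparsity = as.integer(gen_sparsity),
    noise_sigma = as.double(noise_sigma),
    seed = as.integer(seed),
    disjoint_support = isTRUE(disjoint_support)
  ), class = "texture_model")
}

#' Fixed blue-to-red pseudo-color map
#'
#' Maps intensity `t` in `[0, 1]` to RGB: `R = t`, `G = 0.15 + 0.35 t`,
#' `B = 0.3 + 0.2 t`. Low intensities render bluish, high intensities reddish,
#' and the HSV value channel `max(R, G, B)` is strictly increasing in `t`, so
#' value-channel coding downstream sees a monotone transform of the underlying
#' intensity (mirroring clinical elastography renderings).
#'
#' @param t numeric vector/matrix of intensities in `[0, 1]`.
#' @return an array with a trailing dimension of 3 (RGB).
#' @export
pseudocolor_map <- function(t) {
  check_that(all(t >= -1e-9 & t <= 1 + 1e-9), "intensity must lie in [0, 1]")
  t <- pmin(pmax(t, 0), 1)
  d <- if (is.matrix(t)) dim(t) else length(t)
  arr <- array(0, c(d, 3L))
  n <- length(t)
  arr[seq_len(n)] <- t                       # R
  arr[n + seq_len(n)] <- 0.15 + 0.35 * t     # G
  arr[2L * n + seq_len(n)] <- 0.3 + 0.2 * t  # B
  arr
}

# quantize to the 8-bit grid so in-memory images match PNG round trips exactly
quantize8 <- function(x) round(x * 255) / 255

#' Synthesize one multi-modal case
#'
#' The ROI is tiled with non-overlapping patches, each drawn as a
#' `gen_sparsity`-sparse nonnegative combination of the label's model atoms
#' plus `N(0, noise_sigma^2)` noise, then clipped to `[0, 1]` and quantized to
#' the 8-bit grid. The background outside the ROI is uniform noise (the
#' pipeline only reads ROIs). Three-channel modalities are rendered through
#' [pseudocolor_map()]. The pre-clipping ROI intensities are kept in the
#' `preclip` field so exact-sparsity properties can be verified.
#'
#' The background, ROI position and patch-combination draws use streams that do
#' not depend on `label`, so two cases with the same seed and different labels
#' have identical backgrounds and ROI positions but different ROI textures.
#'
#' @param models list of two `texture_model`s (class 0, class 1).
#' @param modalities named integer vector: modality name -> display channels
#'   (1 or 3).
#' @param image_edge image edge in pixels.
#' @param roi_edge ROI edge in pixels; must be a multiple of the model patch
#'   edge and at most `image_edge`.
#' @param label case label, 0 or 1.
#' @param seed integer seed.
#' @param case_id case identifier string.
#' @return an object of class `mm_case` with fields `case_id`, `label`,
#'   `images` (named list; grayscale matrices or H x W x 3 arrays, values in
#'   `[0, 1]`), `rois` (named list of `c(row, col, edge)`), `patch_edge` and
#'   `preclip` (per-modality pre-clipping ROI intensity matrices, each
#'   carrying a `truth` attribute with the generating atom support and
#'   coefficients of every tile).
#' @export
synthesize_case <- function(models, modalities, image_edge = 96L,
                            roi_edge = 64L, label, seed,
                            case_id = sprintf("case_%d", seed)) {
  check_that(label %in% c(0L, 1L), "label must be 0 or 1")
  check_that(length(models) == 2L, "need one model per class")
  model <- models[[label + 1L]]
  p <- model$patch_edge
  check_that(roi_edge <= image_edge, "roi_edge must be <= image_edge")
  check_that(roi_edge %% p == 0L, "roi_edge must be a multiple of patch_edge")

  n_tiles <- roi_edge %/% p
  # label-independent streams: backgrounds/positions match across labels
  pos <- local_seed(derive_seed(seed, "roi-pos"), {
    c(row = sample(image_edge - roi_edge + 1L, 1L),
      col = sample(image_edge - roi_edge + 1L, 1L))
  })

  images <- list()
  rois <- list()
  preclip <- list()
  for (mod in names(modalities)) {
    bg <- local_seed(derive_seed(seed, paste0("bg-", mod)), {
      matrix(runif(image_edge^2), image_edge, image_edge)
    })
    roi <- local_seed(derive_seed(seed, paste0("roi-", mod)), {
      out <- matrix(0, roi_edge, roi_edge)
      truth <- list()
      amp <- 0.9 / (model$gen_sparsity * max(model$atoms))
      for (ti in seq_len(n_tiles)) {
        for (tj in seq_len(n_tiles)) {
          supp <- sample.int(ncol(model$atoms), model$gen_sparsity)
          coefs <- runif(model$gen_sparsity, 0.5, 1.5) * amp
          patch <- as.vector(model$atoms[, supp, drop = FALSE] %*% coefs)
          if (model$noise_sigma > 0) {
            patch <- patch + rnorm(length(patch), 0, model$noise_sigma)
          }
          rs <- (ti - 1L) * p + seq_len(p)
          cs <- (tj - 1L) * p + seq_len(p)
          out[rs, cs] <- matrix(patch, p, p)
          truth[[length(truth) + 1L]] <- list(tile = c(ti, tj),
                                              support = supp,
                                              coefs = coefs)
        }
      }
      attr(out, "truth") <- truth
      out
    })
    preclip[[mod]] <- roi
    roi_q <- quantize8(pmin(pmax(roi, 0), 1))
    img <- quantize8(bg)
    img[pos["row"] + seq_len(roi_edge) - 1L,
        pos["col"] + seq_len(roi_edge) - 1L] <- roi_q
    if (modalities[[mod]] == 3L) img <- quantize8(pseudocolor_map(img))
    images[[mod]] <- img
    rois[[mod]] <- c(row = unname(pos["row"]), col = unname(pos["col"]),
                     edge = as.integer(roi_edge))
  }
  structure(list(
    case_id = as.character(case_id),
    label = as.integer(label),
    images = images,
    rois = rois,
    patch_edge = p,
    preclip = preclip
  ), class = "mm_case")
}

#' @export
print.mm_case <- function(x, ...) {
  cat(sprintf("<mm_case %s> label %d, modalities: %s\n", x$case_id, x$label,
              paste(names(x$images), collapse = ", ")))
  invisible(x)
}

#' Generate a seeded two-class dataset
#'
#' Builds one texture model per class (seeds derived from the master seed),
#' synthesizes `n_per_class` cases per label, and optionally writes images
#' (8-bit PNG), a manifest CSV with header
#' `case_id,label,modality,path,roi_row,roi_col,roi_edge`, and the generator
#' configuration (YAML) to `out_dir`. Per-case seeds are derived
#' deterministically from the master seed and the case id, so the same master
#' seed reproduces the dataset byte for byte.
#'
#' @param n_per_class cases per class (>= 1).
#' @param config a [pipeline_config()]; the `generator` block and `modalities`
#'   define the synthesis conditions.
#' @param seed master seed; defaults to `config$seed`.
#' @param out_dir optional output directory; created if missing.
#' @return invisibly, a list with `cases` (list of `mm_case`), `manifest`
#'   (data frame) and `models`.
#' @export
#' @examples
#' cfg <- pipeline_config(modalities = c(gray = 1), n_atoms = 64,
#'                        generator = list(image_edge = 48, roi_edge = 32))
#' ds <- generate_dataset(2, cfg, seed = 1)
#' length(ds$cases)
generate_dataset <- function(n_per_class, config, seed = config$seed,
                             out_dir = NULL) {
  check_that(n_per_class >= 1L, "n_per_class must be >= 1")
  check_that(inherits(config, "pipeline_config"),
             "config must be a pipeline_config")
  g <- config$generator
  models <- lapply(0:1, function(cl) {
    make_texture_model(cl, patch_edge = config$patch_edge,
                       n_gen_atoms = g$n_gen_atoms,
                       gen_sparsity = g$gen_sparsity,
                       noise_sigma = g$noise_sigma,
                       seed = derive_seed(seed, paste0("model", cl)),
                       disjoint_support = g$disjoint_support)
  })
  labels <- rep(0:1, each = n_per_class)
  ids <- sprintf("case%03d", seq_along(labels))
  cases <- mapply(function(id, lab) {
    synthesize_case(models, config$modalities,
                    image_edge = g$image_edge, roi_edge = g$roi_edge,
                    label = lab, seed = derive_seed(seed, id), case_id = id)
  }, ids, labels, SIMPLIFY = FALSE)
  names(cases) <- ids

  rows <- do.call(rbind, lapply(cases, function(cs) {
    do.call(rbind, lapply(names(cs$images), function(mod) {
      data.frame(case_id = cs$case_id, label = cs$label, modality = mod,
                 path = file.path("images",
                                  sprintf("%s_%s.png", cs$case_id, mod)),
                 roi_row = cs$rois[[mod]]["row"],
                 roi_col = cs$rois[[mod]]["col"],
                 roi_edge = cs$rois[[mod]]["edge"],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL

  if (!is.null(out_dir)) {
    img_dir <- file.path(out_dir, "images")
    ok <- dir.exists(img_dir) || dir.create(img_dir, recursive = TRUE,
                                            showWarnings = FALSE)
    if (!ok || file.access(out_dir, 2L) != 0L) {
      stop("cannot write to directory: ", out_dir, call. = FALSE)
    }
    for (cs in cases) {
      for (mod in names(cs$images)) {
        png::writePNG(cs$images[[mod]],
                      file.path(out_dir, "images",
                                sprintf("%s_%s.png", cs$case_id, mod)))
      }
    }
    write.csv(rows, file.path(out_dir, "manifest.csv"), row.names = FALSE,
              quote = FALSE)
    save_config(config, file.path(out_dir, "config.yaml"))
  }
  invisible(list(cases = cases, manifest = rows, models = models))
}

#' Read a dataset written by [generate_dataset()] back into memory
#'
#' @param dir dataset directory containing `manifest.csv` and `images/`.
#' @param config optional `pipeline_config`; defaults to the `config.yaml`
#'   saved alongside the manifest.
#' @return list with `cases` and `manifest` (no `preclip` debug fields:
#'   images round-trip through 8-bit PNG).
#' @export
read_dataset <- function(dir, config = NULL) {
  man_path <- file.path(dir, "manifest.csv")
  check_that(file.exists(man_path), paste("no manifest at", man_path))
  manifest <- read.csv(man_path, stringsAsFactors = FALSE)
  if (is.null(config)) {
    cfg_path <- file.path(dir, "config.yaml")
    config <- if (file.exists(cfg_path)) load_config(cfg_path) else
      pipeline_config()
  }
  cases <- lapply(split(manifest, manifest$case_id), function(df) {
    images <- list()
    rois <- list()
    for (i in seq_len(nrow(df))) {
      img <- png::readPNG(file.path(dir, df$path[i]))
      images[[df$modality[i]]] <- img
      rois[[df$modality[i]]] <- c(row = df$roi_row[i], col = df$roi_col[i],
                                  edge = df$roi_edge[i])
    }
    structure(list(case_id = df$case_id[1], label = df$label[1],
                   images = images, rois = rois,
                   patch_edge = config$patch_edge, preclip = NULL),
              class = "mm_case")
  })
  cases <- cases[order(names(cases))]
  list(cases = cases, manifest = manifest)
}
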