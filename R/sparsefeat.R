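# Feature extraction: patch tiling, HSV channel splitting, OMP coding against
# the FED, and pooling of absolute coefficients into per-case features.

# coding channels for a modality with a given number of display channels:
# grayscale images are coded directly, pseudo-color images through the hue and
# value channels of an HSV conversion (saturation is discarded)
coding_channels <- function(n_display_channels) {
  if (n_display_channels == 1L) "gray" else c("hue", "value")
}

# crop the ROI of one modality from a case and return the requested coding
# channel as a 2-D matrix
case_channel_roi <- function(case, modality, channel) {
  img <- case$images[[modality]]
  if (is.null(img)) {
    stop("case ", case$case_id, " has no image for modality ", modality,
         call. = FALSE)
  }
  roi <- case$rois[[modality]]
  rows <- roi["row"] + seq_len(roi["edge"]) - 1L
  cols <- roi["col"] + seq_len(roi["edge"]) - 1L
  if (channel == "gray") {
    check_that(is.matrix(img), "gray channel requested from a color image")
    return(img[rows, cols, drop = FALSE])
  }
  check_that(length(dim(img)) == 3L, "hue/value requested from a gray image")
  hv <- split_hsv_channels(img[rows, cols, , drop = FALSE])
  hv[[channel]]
}

#' Tile an ROI into vectorized, mean-removed patches
#'
#' Extracts every fully contained `patch_edge` x `patch_edge` patch on the
#' stride grid (partial border patches dropped), vectorizes each patch in
#' row-major order, removes its mean (the DC component is stored separately —
#' texture, not brightness, is the signal of interest) and stacks the results
#' as columns.
#'
#' @param roi_image 2-D numeric matrix.
#' @param patch_edge patch edge in pixels.
#' @param stride grid stride in pixels (default: `patch_edge`,
#'   non-overlapping).
#' @param source optional provenance tag (case id, modality, channel).
#' @return an object of class `patch_matrix`: list with `data`
#'   (`patch_edge^2 x n_patches`), `means` (per-patch DC values),
#'   `patch_edge`, `source`.
#' @export
#' @examples
#' pm <- extract_patches(matrix(runif(256), 16, 16), 8)
#' ncol(pm$data)  # 4
extract_patches <- function(roi_image, patch_edge, stride = patch_edge,
                            source = NULL) {
  check_that(is.matrix(roi_image), "roi_image must be a 2-D matrix")
  p <- as.integer(patch_edge)
  check_that(nrow(roi_image) >= p && ncol(roi_image) >= p,
             "ROI is smaller than the patch")
  check_that(stride >= 1L, "stride must be >= 1")
  rows <- seq(1L, nrow(roi_image) - p + 1L, by = stride)
  cols <- seq(1L, ncol(roi_image) - p + 1L, by = stride)
  n <- length(rows) * length(cols)
  data <- matrix(0, p * p, n)
  idx <- 1L
  for (r in rows) {
    for (cc in cols) {
      patch <- roi_image[r:(r + p - 1L), cc:(cc + p - 1L)]
      data[, idx] <- as.vector(t(patch))  # row-major vectorization
      idx <- idx + 1L
    }
  }
  means <- colMeans(data)
  data <- sweep(data, 2, means)
  structure(list(data = data, means = means, patch_edge = p,
                 source = source),
            class = "patch_matrix")
}

#' Split a pseudo-color ROI into hue and value channels
#'
#' Standard RGB to HSV conversion (via [grDevices::rgb2hsv()]); hue is scaled
#' to `[0, 1]` and the hue of achromatic pixels (max = min) is 0 by
#' convention. Saturation is discarded.
#'
#' @param color_roi H x W x 3 array with channel values in `[0, 1]`.
#' @return list with matrices `hue` and `value`.
#' @export
#' @examples
#' px <- array(c(0.2, 0.4, 0.6), c(1, 1, 3))
#' split_hsv_channels(px)  # hue 0.5833..., value 0.6
split_hsv_channels <- function(color_roi) {
  check_that(length(dim(color_roi)) == 3L && dim(color_roi)[3L] == 3L,
             "color_roi must be an H x W x 3 array")
  check_that(all(color_roi >= -1e-9 & color_roi <= 1 + 1e-9),
             "channel values must lie in [0, 1]")
  d <- dim(color_roi)[1:2]
  rgb <- rbind(as.vector(color_roi[, , 1L]),
               as.vector(color_roi[, , 2L]),
               as.vector(color_roi[, , 3L]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  list(hue = matrix(hsv["h", ], d[1L], d[2L]),
       value = matrix(hsv["v", ], d[1L], d[2L]))
}

#' OMP sparse code of a single signal against a FED
#'
#' @param signal numeric vector of length `patch_dim`.
#' @param fed an `sr_fed`.
#' @param omp_sparsity maximum number of atoms.
#' @return an object of class `sparse_code`: list with `coefficients` (length
#'   = total atoms, exact zeros off the support) and `support` (selected atom
#'   indices).
#' @export
omp_code <- function(signal, fed, omp_sparsity) {
  check_that(length(signal) > 0, "signal must be non-empty")
  check_that(inherits(fed, "sr_fed"), "fed must be an sr_fed")
  check_that(length(signal) == nrow(fed$combined),
             "signal length must equal the patch dimension")
  w <- omp_encode(fed$combined, matrix(signal, ncol = 1L), omp_sparsity)[, 1L]
  structure(list(coefficients = w, support = which(w != 0)),
            class = "sparse_code")
}

#' Pool per-patch sparse codes into one per-case feature block
#'
#' `feature_j = mean_j |coefficient_j|` over the ROI patches (or the maximum,
#' with `pooling = "max"`); one value per FED atom.
#'
#' @param codes a list of `sparse_code` objects or the dense coefficient
#'   matrix returned by [omp_encode()] (atoms x patches).
#' @param fed the `sr_fed` the codes were computed against.
#' @param pooling `"mean"` or `"max"`.
#' @return numeric vector of length `ncol(fed$combined)`, all entries >= 0.
#' @export
pool_case_features <- function(codes, fed, pooling = c("mean", "max")) {
  pooling <- match.arg(pooling)
  if (is.list(codes) && !is.matrix(codes)) {
    check_that(length(codes) >= 1L, "need at least one code")
    lens <- vapply(codes, function(cd) length(cd$coefficients), 1L)
    check_that(length(unique(lens)) == 1L, "mismatched code lengths")
    codes <- do.call(cbind, lapply(codes, function(cd) cd$coefficients))
  }
  check_that(is.matrix(codes) && ncol(codes) >= 1L, "need at least one code")
  check_that(nrow(codes) == ncol(fed$combined),
             "code length must equal the FED atom count")
  if (pooling == "mean") rowMeans(abs(codes)) else
    apply(abs(codes), 1L, max)
}

#' Per-case feature vector length for a modality configuration
#'
#' `sum over modalities of n_classes * n_atoms * coded channels`, where a
#' grayscale modality contributes one coded channel and a pseudo-color
#' modality two (hue and value). With two classes and 256 atoms this gives
#' 512 features for grayscale alone, 1024 for one pseudo-color modality, 1536
#' for grayscale plus one pseudo-color modality, and 2560 for grayscale plus
#' two.
#'
#' @param modalities named integer vector: modality name -> display channels
#'   (1 or 3).
#' @param n_classes number of class dictionaries per channel.
#' @param n_atoms atoms per dictionary.
#' @return integer feature count.
#' @export
#' @examples
#' feature_vector_length(c(gray = 1, elasto = 3, visco = 3))  # 2560
feature_vector_length <- function(modalities, n_classes = 2L,
                                  n_atoms = 256L) {
  check_that(n_classes >= 1L && n_atoms >= 1L, "counts must be positive")
  if (is.list(modalities)) modalities <- unlist(modalities)
  check_that(all(modalities >= 1L), "counts must be positive")
  coded <- ifelse(modalities == 1L, 1L, 2L)
  as.integer(sum(n_classes * n_atoms * coded))
}

#' Extract the full feature vector of one case
#'
#' For every configured modality, each coding channel (gray, or hue and value
#' after HSV conversion) is tiled into mean-removed patches, sparse-coded with
#' OMP against that channel's own two-class FED, and pooled with
#' [pool_case_features()]; the per-channel blocks are concatenated in the
#' configured modality order.
#'
#' @param case an `mm_case`.
#' @param feds named list of `sr_fed`, keyed `"modality:channel"` (as returned
#'   by [train_dictionaries()]).
#' @param config a [pipeline_config()].
#' @return an object of class `sr_features`: list with `values` (nonnegative
#'   numeric vector), `layout` (data frame mapping spans to modality, channel
#'   and class block), `case_id`, `label`.
#' @export
extract_case_features <- function(case, feds, config) {
  values <- numeric(0)
  layout <- list()
  for (mod in names(config$modalities)) {
    if (is.null(case$images[[mod]])) {
      stop("case ", case$case_id, " is missing modality ", mod,
           call. = FALSE)
    }
    for (ch in coding_channels(config$modalities[[mod]])) {
      key <- paste(mod, ch, sep = ":")
      fed <- feds[[key]]
      if (is.null(fed)) stop("no FED for ", key, call. = FALSE)
      roi <- case_channel_roi(case, mod, ch)
      pm <- extract_patches(roi, config$patch_edge, config$stride,
                            source = list(case_id = case$case_id,
                                          modality = mod, channel = ch))
      W <- omp_encode(fed$combined, pm$data, config$omp_sparsity)
      block <- pool_case_features(W, fed, pooling = config$pooling)
      off <- length(values)
      bm <- fed$block_map
      for (b in unique(bm$block)) {
        rows <- bm$block == b
        layout[[length(layout) + 1L]] <- data.frame(
          modality = mod, channel = ch,
          class_label = bm$class_label[rows][1L],
          from = off + min(bm$index[rows]),
          to = off + max(bm$index[rows]), stringsAsFactors = FALSE)
      }
      values <- c(values, block)
    }
  }
  structure(list(values = values, layout = do.call(rbind, layout),
                 case_id = case$case_id, label = case$label),
            class = "sr_features")
}

#' Feature matrix for a list of cases
#'
#' @param cases list of `mm_case`.
#' @param feds named list of `sr_fed` (see [train_dictionaries()]).
#' @param config a [pipeline_config()].
#' @return list with `features` (cases x features matrix, columns
#'   `f0001...`), `case_id`, `label`, `layout`.
#' @export
features_for_cases <- function(cases, feds, config) {
  fv <- lapply(cases, extract_case_features, feds = feds, config = config)
  F <- do.call(rbind, lapply(fv, function(x) x$values))
  colnames(F) <- sprintf("f%04d", seq_len(ncol(F)))
  rownames(F) <- NULL
  list(features = F,
       case_id = unname(vapply(fv, function(x) x$case_id, "")),
       label = unname(vapply(fv, function(x) x$label, 1L)),
       layout = fv[[1L]]$layout)
}

#' Write / read a feature matrix as CSV with a JSON layout sidecar
#'
#' Columns `case_id,label,f0001,...`; the sidecar records which column spans
#' belong to which (modality, channel, class block).
#'
#' @param fm result of [features_for_cases()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.layout.json`.
#' @return `write_features` returns `path` invisibly; `read_features` the
#'   same structure as [features_for_cases()].
#' @export
write_features <- function(fm, path) {
  # full double precision so downstream selection reproduces in-memory runs
  # bit for bit after a CSV round trip
  vals <- apply(fm$features, 2, function(x) sprintf("%.17g", x))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  colnames(vals) <- colnames(fm$features)
  df <- data.frame(case_id = fm$case_id, label = fm$label,
                   vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(fm$layout)) {
    jsonlite::write_json(fm$layout, paste0(path, ".layout.json"),
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_that(all(c("case_id", "label") %in% names(df)),
             "feature CSV must have case_id and label columns")
  F <- as.matrix(df[, setdiff(names(df), c("case_id", "label")),
                    drop = FALSE])
  layout_path <- paste0(path, ".layout.json")
  layout <- if (file.exists(layout_path)) {
    jsonlite::read_json(layout_path, simplifyVector = TRUE)
  } else NULL
  list(features = F, case_id = df$case_id, label = as.integer(df$label),
       layout = layout)
}
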