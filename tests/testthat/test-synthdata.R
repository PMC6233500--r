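test_that("texture models are deterministic, unit-norm and class-distinct", {
  tm1 <- make_texture_model(0L, patch_edge = 8, n_gen_atoms = 16,
                            gen_sparsity = 3, noise_sigma = 0, seed = 1)
  tm2 <- make_texture_model(0L, patch_edge = 8, n_gen_atoms = 16,
                            gen_sparsity = 3, noise_sigma = 0, seed = 1)
  expect_identical(tm1$atoms, tm2$atoms)
  expect_true(all(abs(colSums(tm1$atoms^2) - 1) < 1e-8))

  # cross-class atom correlation below within-class (all pairs, both seeds)
  m0 <- make_texture_model(0L, seed = 1, noise_sigma = 0)
  m1 <- make_texture_model(1L, seed = 2, noise_sigma = 0)
  cor_mean <- function(A, B) {
    Az <- scale(A, scale = FALSE)
    Bz <- scale(B, scale = FALSE)
    M <- abs(stats::cor(Az, Bz))
    if (identical(dim(A), dim(B)) && isTRUE(all.equal(A, B))) {
      mean(M[upper.tri(M)])
    } else mean(M)
  }
  within <- (cor_mean(m0$atoms, m0$atoms) + cor_mean(m1$atoms, m1$atoms)) / 2
  across <- cor_mean(m0$atoms, m1$atoms)
  expect_lt(across, within)

  expect_error(make_texture_model(0L, patch_edge = 1),
               "patch_edge")
  expect_error(make_texture_model(0L, n_gen_atoms = 2, gen_sparsity = 3),
               "gen_sparsity")
})

test_that("noise-free single-atom patches are scalar multiples of one atom", {
  tm <- make_texture_model(0L, patch_edge = 8, n_gen_atoms = 8,
                           gen_sparsity = 1, noise_sigma = 0, seed = 3)
  models <- list(tm, make_texture_model(1L, patch_edge = 8, n_gen_atoms = 8,
                                        gen_sparsity = 1, noise_sigma = 0,
                                        seed = 4))
  cs <- synthesize_case(models, c(gray = 1L), image_edge = 48, roi_edge = 16,
                        label = 0L, seed = 5)
  roi <- cs$preclip$gray
  for (ti in 0:1) {
    for (tj in 0:1) {
      patch <- as.vector(roi[ti * 8 + 1:8, tj * 8 + 1:8])
      # project on each atom (atoms stored column-major over the patch)
      best <- min(vapply(seq_len(ncol(tm$atoms)), function(a) {
        v <- tm$atoms[, a]
        sum((patch - sum(patch * v) * v)^2)
      }, 1.0))
      expect_lt(best, 1e-16)
    }
  }
})

test_that("noise-free ROIs are exactly gen_sparsity-sparse pre-clipping", {
  cfg <- small_gray_config(generator = small_gray_generator(noise_sigma = 0))
  ds <- generate_dataset(2, cfg, seed = 9)
  p <- cfg$patch_edge
  for (cs in ds$cases) {
    model <- ds$models[[cs$label + 1L]]
    roi <- cs$preclip$gray
    truth <- attr(roi, "truth")
    expect_length(truth, (cfg$generator$roi_edge / p)^2)
    for (tile in truth) {
      rs <- (tile$tile[1] - 1L) * p + seq_len(p)
      cols <- (tile$tile[2] - 1L) * p + seq_len(p)
      patch <- as.vector(roi[rs, cols])
      # the recorded support is a witness: the best gen_sparsity-term
      # residual in the class dictionary can only be smaller
      A <- model$atoms[, tile$support, drop = FALSE]
      w <- qr.solve(A, patch)
      expect_lt(sqrt(sum((patch - A %*% w)^2)), 1e-8)
      expect_length(tile$support, cfg$generator$gen_sparsity)
    }
  }
})

test_that("labels change ROI content but not backgrounds or positions", {
  models <- list(make_texture_model(0L, noise_sigma = 0, seed = 1),
                 make_texture_model(1L, noise_sigma = 0, seed = 2))
  c0 <- synthesize_case(models, c(gray = 1L), image_edge = 48, roi_edge = 32,
                        label = 0L, seed = 7)
  c1 <- synthesize_case(models, c(gray = 1L), image_edge = 48, roi_edge = 32,
                        label = 1L, seed = 7)
  expect_identical(c0$rois, c1$rois)
  roi <- c0$rois$gray
  mask <- matrix(TRUE, 48, 48)
  mask[roi["row"] + seq_len(roi["edge"]) - 1L,
       roi["col"] + seq_len(roi["edge"]) - 1L] <- FALSE
  expect_identical(c0$images$gray[mask], c1$images$gray[mask])
  expect_false(identical(c0$images$gray[!mask], c1$images$gray[!mask]))
})

test_that("pseudo-color value channel is monotone in intensity", {
  ramp <- matrix(seq(0, 1, length.out = 256), nrow = 1)
  rgb <- pseudocolor_map(ramp)
  v <- split_hsv_channels(rgb)$value
  expect_true(all(diff(as.vector(v)) >= 0))
  expect_error(pseudocolor_map(matrix(1.5)), "\\[0, 1\\]")
})

test_that("generate_dataset writes a reproducible dataset with manifest", {
  cfg <- pipeline_config(modalities = c(gray = 1L, elasto = 3L, visco = 3L),
                         n_atoms = 64L,
                         generator = small_gray_generator())
  d1 <- file.path(tempdir(), "ds1")
  d2 <- file.path(tempdir(), "ds2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  out1 <- generate_dataset(3, cfg, seed = 21, out_dir = d1)
  out2 <- generate_dataset(3, cfg, seed = 21, out_dir = d2)

  expect_length(out1$cases, 6L)
  expect_equal(sum(vapply(out1$cases, function(cs) cs$label, 1L) == 0), 3L)
  expect_equal(nrow(out1$manifest), 18L)  # 3 modalities per case
  expect_identical(out1$manifest, out2$manifest)

  # byte-level reproducibility of every image file
  for (p in out1$manifest$path) {
    expect_identical(readBin(file.path(d1, p), "raw", 1e6),
                     readBin(file.path(d2, p), "raw", 1e6))
  }

  # round trip through PNG preserves images exactly (8-bit quantization at
  # synthesis time)
  back <- read_dataset(d1)
  expect_equal(back$cases[["case001"]]$images$gray,
               out1$cases[["case001"]]$images$gray, tolerance = 1e-12)
  expect_error(generate_dataset(2, cfg, seed = 1,
                                out_dir = "/proc/nope/impossible"))
})
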