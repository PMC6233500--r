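test_that("overcomplete DCT dictionary has the documented structure", {
  d <- init_dct_dictionary(8, 256)
  expect_equal(dim(d$atoms), c(64L, 256L))
  expect_true(all(abs(colSums(d$atoms^2) - 1) < 1e-8))
  # DC atom: constant 1/8
  expect_equal(d$atoms[, 1], rep(1 / 8, 64))
  # non-DC atoms are zero-mean
  expect_lt(max(abs(colMeans(d$atoms[, -1]))), 1e-12)

  # complete case: the 2-D DCT basis is orthonormal
  d2 <- init_dct_dictionary(2, 4)
  expect_equal(crossprod(d2$atoms), diag(4), tolerance = 1e-12)

  expect_error(init_dct_dictionary(8, 200), "perfect square")
  expect_error(init_dct_dictionary(8, 49), "sqrt")
})

test_that("OMP recovers single atoms, zero signals, and orthogonal residuals", {
  D <- random_dictionary(64, 256, seed = 1)
  fed <- build_fed(list(
    srtexture:::new_dictionary(D[, 1:128], 8, class_label = 0L),
    srtexture:::new_dictionary(D[, 129:256], 8, class_label = 1L)
  ))
  code <- omp_code(3 * fed$combined[, 17], fed, 5)
  expect_equal(code$support, 17L)
  expect_equal(code$coefficients[17], 3)
  expect_equal(sum(code$coefficients != 0), 1L)

  zero <- omp_code(rep(0, 64), fed, 5)
  expect_length(zero$support, 0L)
  expect_true(all(zero$coefficients == 0))

  # residual orthogonal to every selected atom after the final refit
  set.seed(4)
  for (i in 1:25) {
    x <- rnorm(64)
    w <- omp_encode(fed$combined, matrix(x, ncol = 1), 5)[, 1]
    r <- x - fed$combined %*% w
    sel <- which(w != 0)
    expect_lt(max(abs(crossprod(fed$combined[, sel, drop = FALSE], r))),
              1e-8 * sqrt(sum(x^2)))
  }
})

test_that("KSVD leaves exactly representable patches at zero error", {
  init <- init_dct_dictionary(8, 256)
  set.seed(2)
  idx <- sample(256, 300, replace = TRUE)
  X <- init$atoms[, idx] %*% diag(runif(300, 0.5, 2))
  d <- ksvd_train(X, init, code_sparsity = 1, n_iters = 2, use_min = 1)
  expect_lt(d$rmse[1], 1e-12)
  expect_lt(d$rmse[length(d$rmse)], 1e-12)
})

test_that("n_iters = 0 returns the initial dictionary unchanged", {
  init <- init_dct_dictionary(4, 16)
  X <- matrix(rnorm(16 * 40), 16)
  expect_identical(ksvd_train(X, init, n_iters = 0), init)
  expect_error(ksvd_train(matrix(numeric(0), 16, 0), init), "empty")
})

test_that("KSVD trains toward exactly sparse structure, monotonically", {
  G <- random_dictionary(64, 256, seed = 42)
  X <- sparse_signals(G, 1280, 3, seed = 42)
  expect_warning(
    d <- ksvd_train(X, init_dct_dictionary(8, 256), code_sparsity = 3,
                    n_iters = 8, tol_improve = 0),
    NA)
  r <- d$rmse
  expect_length(r, 9L)
  expect_true(all(diff(r) <= 1e-6))
  expect_lt(r[length(r)], r[1])
  # atom normalization preserved through training
  expect_lt(max(abs(colSums(d$atoms^2) - 1)), 1e-8)
  # no dead atoms after training
  expect_true(all(colSums(d$atoms^2) > 0.5))
})

test_that("FED assembly concatenates class blocks in order with a round-trip
           block map", {
  d0 <- init_dct_dictionary(8, 256, class_label = 0L, channel = "gray")
  d1 <- init_dct_dictionary(8, 256, class_label = 1L, channel = "gray")
  fed <- build_fed(list(d1, d0))  # order normalized internally
  expect_equal(ncol(fed$combined), 512L)
  expect_equal(fed$block_map$index[fed$block_map$class_label == 0], 1:256)
  expect_equal(fed$block_map$index[fed$block_map$class_label == 1], 257:512)
  # block-map round trip: every combined column equals its block atom
  for (j in c(1L, 200L, 257L, 512L)) {
    row <- fed$block_map[fed$block_map$index == j, ]
    expect_identical(fed$combined[, j],
                     fed$blocks[[row$block]]$atoms[, row$within])
  }

  single <- build_fed(list(d0))
  expect_identical(single$combined, d0$atoms)
  expect_equal(single$block_map$within, 1:256)

  expect_error(build_fed(list(d0, init_dct_dictionary(4, 16,
                                                      class_label = 1L))),
               "patch dimensions")
  expect_error(build_fed(list(d0, d0)), "duplicate")
})

test_that("coding against the full FED beats coding with a class zeroed out", {
  cfg <- small_gray_config(generator = small_gray_generator(noise_sigma = 0))
  ds <- generate_dataset(4, cfg, seed = 3)
  feds <- suppressWarnings(train_dictionaries(ds$cases, cfg))
  fed <- feds[["gray:gray"]]
  cs <- ds$cases[[1]]
  roi <- srtexture:::case_channel_roi(cs, "gray", "gray")
  pm <- extract_patches(roi, cfg$patch_edge)
  keep <- fed$block_map$class_label != cs$label
  crippled <- fed$combined[, keep, drop = FALSE]
  for (j in seq_len(ncol(pm$data))) {
    x <- pm$data[, j]
    w_full <- omp_encode(fed$combined, matrix(x, ncol = 1), 3)[, 1]
    w_part <- omp_encode(crippled, matrix(x, ncol = 1), 3)[, 1]
    r_full <- sum((x - fed$combined %*% w_full)^2)
    r_part <- sum((x - crippled %*% w_part)^2)
    expect_gte(r_part + 1e-12, r_full)
  }
})

test_that("dictionary CSV/JSON persistence round-trips", {
  d <- ksvd_train(sparse_signals(random_dictionary(16, 36, 5), 100, 2,
                                 seed = 5),
                  init_dct_dictionary(4, 36, class_label = 1L,
                                      modality = "gray", channel = "gray"),
                  code_sparsity = 2, n_iters = 2, use_min = 1)
  pfx <- file.path(tempdir(), "dict_test")
  on.exit(unlink(paste0(pfx, c(".csv", ".json"))))
  write_dictionary(d, pfx)
  back <- read_dictionary(pfx)
  expect_equal(back$atoms, d$atoms, tolerance = 1e-12)
  expect_identical(back$class_label, d$class_label)
  expect_identical(back$channel, d$channel)
  expect_equal(back$rmse, d$rmse, tolerance = 1e-12)
})
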