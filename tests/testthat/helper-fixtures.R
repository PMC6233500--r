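# Shared fixtures: small configurations, low-coherence frames and brute-force
# oracles used across the test files.

# desk-scale pipeline configuration: one grayscale modality, 64-atom
# dictionaries, 32 px ROIs
small_gray_config <- function(generator = small_gray_generator(),
                              cv = list(), selection = list(), ...) {
  pipeline_config(modalities = c(gray = 1), n_atoms = 64L, ksvd_iters = 5L,
                  omp_sparsity = 3L,
                  selection = utils::modifyList(
                    list(n_iterations = 20L, solver_sparsity = 8L,
                         k_select = 10L), selection),
                  cv = utils::modifyList(list(n_boot = 500L), cv),
                  generator = generator,
                  ...)
}

small_gray_generator <- function(noise_sigma = 0.02,
                                 disjoint_support = FALSE) {
  list(image_edge = 48L, roi_edge = 32L, n_gen_atoms = 32L,
       gen_sparsity = 3L, noise_sigma = noise_sigma,
       disjoint_support = disjoint_support)
}

# unit-norm frame with mutual coherence below mu_target, by alternating
# projection between the clipped Gram matrix and the rank-d manifold
make_incoherent_frame <- function(d, n_atoms, mu_target, seed) {
  set.seed(seed)
  D <- matrix(rnorm(d * n_atoms), d)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  for (i in 1:60) {
    G <- crossprod(D)
    if (max(abs(G - diag(n_atoms))) < mu_target) break
    Gc <- pmin(pmax(G, -mu_target * 0.95), mu_target * 0.95)
    diag(Gc) <- 1
    e <- eigen(Gc, symmetric = TRUE)
    D <- diag(sqrt(pmax(e$values[1:d], 0))) %*% t(e$vectors[, 1:d])
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  }
  D
}

mutual_coherence <- function(D) {
  G <- abs(crossprod(D))
  diag(G) <- 0
  max(G)
}

# brute-force best k-term approximation over all supports (oracle for OMP)
best_k_term <- function(D, x, k) {
  combs <- combn(ncol(D), k)
  best <- NULL
  bres <- Inf
  for (j in seq_len(ncol(combs))) {
    S <- combs[, j]
    w <- qr.solve(D[, S, drop = FALSE], x)
    r <- sum((x - D[, S, drop = FALSE] %*% w)^2)
    if (r < bres - 1e-14) {
      bres <- r
      best <- list(support = S, w = w)
    }
  }
  coefs <- numeric(ncol(D))
  coefs[best$support] <- best$w
  coefs
}

# random unit-norm dictionary
random_dictionary <- function(d, n_atoms, seed) {
  set.seed(seed)
  D <- matrix(rnorm(d * n_atoms), d)
  sweep(D, 2, sqrt(colSums(D^2)), "/")
}

# exactly k-sparse signals over a dictionary, coefficients in [0.5, 1.5]
sparse_signals <- function(D, n, k, seed, signs = FALSE) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    S <- sample(ncol(D), k)
    w <- runif(k, 0.5, 1.5)
    if (signs) w <- w * sample(c(-1, 1), k, replace = TRUE)
    as.vector(D[, S, drop = FALSE] %*% w)
  }, numeric(nrow(D)))
}

# relabel a list of cases with a permutation of the existing labels
permute_case_labels <- function(cases, seed) {
  labs <- vapply(cases, function(cs) cs$label, 1L)
  set.seed(seed)
  labs <- labs[sample(length(labs))]
  for (i in seq_along(cases)) cases[[i]]$label <- labs[i]
  cases
}
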