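#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the previous
#' RNG state, so library internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a child seed from a master seed and a string tag
#'
#' Deterministic, stable across platforms: a 31-ary polynomial hash of the tag
#' folded with the master seed modulo a prime below 2^31.
#'
#' @param master integer master seed.
#' @param tag character tag (e.g. a case id or stage name).
#' @return an integer seed in `[0, 2147483628]`.
#' @export
#' @examples
#' derive_seed(1L, "case001")
derive_seed <- function(master, tag) {
  stopifnot(length(master) == 1L, is.finite(master), length(tag) == 1L)
  p <- 2147483629  # prime < 2^31
  h <- as.double(master) %% p
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% p
  }
  as.integer(h)
}

# argument checking helper: stop with the caller's message unless cond
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# L2-normalize the columns of a matrix; zero columns left untouched
normalize_columns <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nz <- nrm > 0
  M[, nz] <- sweep(M[, nz, drop = FALSE], 2, nrm[nz], "/")
  M
}

# flip sign so that the first entry with |v| > tol is nonnegative
sign_fix <- function(v, tol = 1e-12) {
  idx <- which(abs(v) > tol)
  if (length(idx) && v[idx[1]] < 0) -v else v
}

# md5 fingerprint of an R object via its canonical JSON serialization
object_fingerprint <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(f))
}
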