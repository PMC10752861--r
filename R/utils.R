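# Internal helpers shared across modules.

#' @importFrom stats rnorm runif fft splinefun plogis optimize uniroot
#' @importFrom rlang .data
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps generators deterministic
# without clobbering the session RNG.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Clamp x into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Separable cubic-spline resampling of a matrix at arbitrary row/column
# query coordinates (tensor grid yq x xq, in source index units). Knots are
# the integer pixel grid; queries must stay inside it.
spline_sample_matrix <- function(img, yq, xq) {
  ny <- nrow(img); nx <- ncol(img)
  if (min(yq) < 1 || max(yq) > ny || min(xq) < 1 || max(xq) > nx)
    stopf("sampling window leaves the source image (rows %.2f..%.2f, cols %.2f..%.2f)",
          min(yq), max(yq), min(xq), max(xq))
  # pass 1: resample rows (y) for every source column
  tmp <- matrix(0, length(yq), nx)
  for (j in seq_len(nx)) {
    sf <- stats::splinefun(seq_len(ny), img[, j], method = "natural")
    tmp[, j] <- sf(yq)
  }
  # pass 2: resample columns (x) for every output row
  out <- matrix(0, length(yq), length(xq))
  for (i in seq_along(yq)) {
    sf <- stats::splinefun(seq_len(nx), tmp[i, ], method = "natural")
    out[i, ] <- sf(xq)
  }
  out
}

# Michelson contrast of a numeric array.
michelson_contrast <- function(x) {
  r <- range(x, finite = TRUE)
  if (sum(r) == 0) return(0)
  (r[2] - r[1]) / (r[2] + r[1])
}
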