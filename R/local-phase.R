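#' Gabor quadrature filter bank over a circular frequency domain
#'
#' Constructs the windowed-Fourier analysis machinery: a Gaussian window of
#' scale `sigma` (truncated at `3*sigma`) and a uniform Cartesian grid of
#' `n_freq x n_freq` spatial frequencies over `[-r, r]^2`, restricted to the
#' disc `0.1 < |omega| <= r` (phase is undefined at DC, so a small guard band
#' excludes it). Each retained frequency defines a quadrature pair of Gabor
#' receptive fields: an even cosine kernel and an odd sine kernel, whose
#' responses are the real and imaginary parts of the local Fourier
#' coefficient.
#'
#' Only the half-plane `wx > 0`, or `wx == 0 & wy > 0`, is materialized as
#' kernels: the coefficient at `-omega` is the complex conjugate of the one
#' at `omega` (`a` even, `b` odd), and downstream code reconstructs the full
#' disc from this symmetry.
#'
#' @param sigma Gaussian window scale, px. The window must average enough
#'   independent spectral speckle cells of the scene for the PMI angle to be
#'   stable; the default 12 px keeps per-cell angular errors well under 2
#'   degrees on band-limited textures.
#' @param r maximum radial frequency in rad/px, `0 < r <= pi` (the image
#'   Nyquist bandwidth). The aliasing-free speed range of the detector is
#'   `|v| <= pi/r` px/frame.
#' @param n_freq frequency grid resolution per axis (>= 4).
#' @param stride default spacing of detection centres, px.
#' @return An object of class `filter_bank`.
#' @export
build_filter_bank <- function(sigma = 12, r = 5 * pi / 8, n_freq = 16,
                              stride = 2) {
  if (r > pi) stopf("`r` must be <= pi rad/px (image Nyquist limit)")
  stopifnot(r > 0, sigma > 0, n_freq >= 4, stride >= 1)
  w1 <- seq(-r, r, length.out = n_freq)
  grid <- expand.grid(wx = w1, wy = w1)
  wmag <- sqrt(grid$wx^2 + grid$wy^2)
  keep <- wmag <= r & wmag > 0.1
  freqs <- tibble::tibble(wx = grid$wx[keep], wy = grid$wy[keep])
  half <- freqs$wx > 0 | (freqs$wx == 0 & freqs$wy > 0)
  fhalf <- freqs[half, ]
  # map each full-disc frequency to (half index, sign of conjugation)
  key <- function(wx, wy) paste(signif(wx, 12), signif(wy, 12))
  hidx <- match(ifelse(half, key(freqs$wx, freqs$wy),
                       key(-freqs$wx, -freqs$wy)),
                key(fhalf$wx, fhalf$wy))
  rad <- as.integer(ceiling(3 * sigma))
  off <- -rad:rad
  dx <- matrix(rep(off, each = length(off)), ncol = length(off))  # column offset
  dy <- matrix(rep(off, times = length(off)), ncol = length(off)) # row offset
  wnd <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
  nh <- nrow(fhalf)
  kc <- matrix(0, length(off)^2, nh)
  ks <- matrix(0, length(off)^2, nh)
  for (i in seq_len(nh)) {
    ph <- fhalf$wx[i] * dx + fhalf$wy[i] * dy
    kc[, i] <- as.vector(wnd * cos(ph))
    ks[, i] <- as.vector(wnd * sin(ph))
  }
  structure(list(sigma = sigma, r = r, n_freq = n_freq, stride = stride,
                 support_radius = rad,
                 freqs = freqs,          # full disc (tibble wx, wy)
                 half_index = hidx,      # full -> half mapping
                 half_sign = ifelse(half, 1, -1), # conjugation sign for b
                 freqs_half = fhalf,
                 grid_step = diff(w1)[1],
                 kernel_cos = kc, kernel_sin = ks,
                 kernel_dy = as.vector(dy), kernel_dx = as.vector(dx)),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> sigma = %g px, r = %.4g rad/px, %d disc frequencies (%d computed), support %d px\n",
              x$sigma, x$r, nrow(x$freqs), nrow(x$freqs_half),
              2 * x$support_radius + 1))
  invisible(x)
}

# Default detection centres: stride grid over the interior where the kernel
# support fits. Returns a tibble (x = col, y = row), 1-based.
default_centers <- function(frame_dim, bank, stride = bank$stride,
                            margin = bank$support_radius) {
  ys <- seq(margin + 1, frame_dim[1] - margin, by = stride)
  xs <- seq(margin + 1, frame_dim[2] - margin, by = stride)
  tidyr::expand_grid(y = ys, x = xs)
}

#' Quadrature (windowed-Fourier) coefficients of one frame
#'
#' Projects the frame onto the bank's Gaussian window at each centre and
#' evaluates the local Fourier coefficient at every half-plane frequency:
#' `a = sum u(x0+d) w(d) cos(omega'd)`, `b = -sum u(x0+d) w(d) sin(omega'd)`.
#' Amplitude is `sqrt(a^2 + b^2)` and local phase `atan2(b, a)`.
#'
#' @param frame numeric matrix (all values finite); dimensions must be at
#'   least the kernel support.
#' @param bank a [build_filter_bank()] object.
#' @param centers tibble with columns `x`, `y` (1-based pixel coordinates at
#'   least `support_radius` away from the border); default: stride grid over
#'   the valid interior.
#' @return An object of class `quadrature_field` with matrices `a`, `b`
#'   (centres x half-plane frequencies).
#' @export
compute_quadrature <- function(frame, bank, centers = NULL) {
  stopifnot(is.matrix(frame), inherits(bank, "filter_bank"))
  if (!all(is.finite(frame))) stopf("frame contains non-finite pixels")
  rad <- bank$support_radius
  if (any(dim(frame) < 2 * rad + 1))
    stopf("frame smaller than the kernel support (%d px)", 2 * rad + 1)
  if (is.null(centers)) centers <- default_centers(dim(frame), bank)
  if (min(centers$y) <= rad || max(centers$y) > nrow(frame) - rad ||
      min(centers$x) <= rad || max(centers$x) > ncol(frame) - rad)
    stopf("centers must be at least %d px away from the frame border", rad)
  nc <- nrow(centers)
  np <- length(bank$kernel_dy)
  a <- matrix(0, nc, nrow(bank$freqs_half))
  b <- matrix(0, nc, nrow(bank$freqs_half))
  chunk <- max(1L, floor(2e6 / np))
  for (s in seq(1, nc, by = chunk)) {
    idx <- s:min(s + chunk - 1, nc)
    patches <- matrix(0, length(idx), np)
    yy <- centers$y[idx]; xx <- centers$x[idx]
    for (p in seq_len(np))
      patches[, p] <- frame[cbind(yy + bank$kernel_dy[p], xx + bank$kernel_dx[p])]
    a[idx, ] <- patches %*% bank$kernel_cos
    b[idx, ] <- -(patches %*% bank$kernel_sin)
  }
  structure(list(a = a, b = b, centers = tibble::as_tibble(centers),
                 bank = bank),
            class = "quadrature_field")
}

#' @export
print.quadrature_field <- function(x, ...) {
  cat(sprintf("<quadrature_field> %d centres x %d frequencies, mean amplitude %.4g\n",
              nrow(x$a), ncol(x$a), mean(sqrt(x$a^2 + x$b^2))))
  invisible(x)
}

#' Local amplitude and phase of a quadrature field
#' @param q a [compute_quadrature()] result.
#' @return List with matrices `amplitude` and `phase` (phase in `(-pi, pi]`).
#' @export
local_phase <- function(q) {
  stopifnot(inherits(q, "quadrature_field"))
  list(amplitude = sqrt(q$a^2 + q$b^2), phase = atan2(q$b, q$a))
}

# Shared validation for a pair of quadrature fields.
check_same_bank <- function(q_t, q_prev) {
  b1 <- q_t$bank; b2 <- q_prev$bank
  if (!isTRUE(all.equal(b1$freqs_half, b2$freqs_half)) ||
      b1$sigma != b2$sigma || b1$r != b2$r)
    stopf("quadrature fields were computed on different filter banks")
  if (!identical(dim(q_t$a), dim(q_prev$a)) ||
      !isTRUE(all.equal(q_t$centers, q_prev$centers)))
    stopf("quadrature fields have mismatched centres")
}

#' Time derivative of the local phase (divisive-normalization form)
#'
#' The phase change between consecutive frames is obtained from the same two
#' Volterra-type terms that define the divisive form of the phase
#' derivative: a cross term `T1 = a(t-1) b(t) - a(t) b(t-1)` and a power
#' term `T2 = a(t) a(t-1) + b(t) b(t-1)`. The default `method = "atan"`
#' returns `atan2(T1, T2)`, the wrapped per-frame phase increment (exact for
#' increments within `(-pi, pi]`); its small-angle limit is the divisive
#' ratio itself, which is available literally as `method = "dnp"`:
#' `T1 / (a(t)^2 + b(t)^2 + eps)` with backward finite differences.
#'
#' Low-amplitude locations are softly gated by `m / (m + eps)` with
#' `m = A(t) A(t-1)` so the output is finite everywhere; the gate vanishes as
#' `eps -> 0`, preserving the amplitude invariance of phase.
#'
#' The result is expanded from the computed half-plane to the full frequency
#' disc using the odd symmetry `dphi/dt(-omega) = -dphi/dt(omega)`.
#'
#' @param q_t,q_prev [compute_quadrature()] fields of frames `t` and `t-1`
#'   on the same bank and centres.
#' @param eps regularizer; default `1e-6` of the mean per-frequency power
#'   (floored at `1e-12`) so the guard is scale-aware.
#' @param method `"atan"` (wrapped increment, default) or `"dnp"` (literal
#'   divisive ratio).
#' @return An object of class `phase_gradient_field`: matrix `dphi`
#'   (centres x full-disc frequencies, rad/frame), the frequency table and
#'   grid metadata.
#' @export
phase_derivative_dnp <- function(q_t, q_prev, eps = NULL,
                                 method = c("atan", "dnp")) {
  method <- match.arg(method)
  check_same_bank(q_t, q_prev)
  bank <- q_t$bank
  if (is.null(eps)) {
    pow <- colMeans(q_t$a^2 + q_t$b^2)
    eps <- pmax(1e-6 * pow, 1e-12)
    eps <- matrix(eps, nrow(q_t$a), length(eps), byrow = TRUE)
  } else {
    stopifnot(eps > 0)
  }
  t1 <- q_prev$a * q_t$b - q_t$a * q_prev$b
  if (method == "atan") {
    t2 <- q_t$a * q_prev$a + q_t$b * q_prev$b
    m <- sqrt(t1^2 + t2^2)
    dphi_half <- atan2(t1, t2) * (m / (m + eps))
  } else {
    dphi_half <- t1 / (q_t$a^2 + q_t$b^2 + eps)
  }
  dphi <- dphi_half[, bank$half_index, drop = FALSE] *
    matrix(bank$half_sign, nrow(dphi_half), length(bank$half_sign), byrow = TRUE)
  structure(list(dphi = dphi, freqs = bank$freqs, r = bank$r,
                 grid_step = bank$grid_step, n_freq = bank$n_freq,
                 centers = q_t$centers),
            class = "phase_gradient_field")
}

#' @export
print.phase_gradient_field <- function(x, ...) {
  cat(sprintf("<phase_gradient_field> %d centres x %d disc frequencies (r = %.4g rad/px)\n",
              nrow(x$dphi), ncol(x$dphi), x$r))
  invisible(x)
}

# Build a phase_gradient_field directly from a function f(wx, wy) -> value
# (used for analytic/planar fields in tests and examples).
phase_field_from_function <- function(bank, f) {
  vals <- matrix(f(bank$freqs$wx, bank$freqs$wy), nrow = 1)
  structure(list(dphi = vals, freqs = bank$freqs, r = bank$r,
                 grid_step = bank$grid_step, n_freq = bank$n_freq,
                 centers = tibble::tibble(x = NA_real_, y = NA_real_)),
            class = "phase_gradient_field")
}
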