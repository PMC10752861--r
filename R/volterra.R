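#' Discrete-time Volterra kernel set (up to second order)
#'
#' Kernels are parameterized by their DC sums — the only quantities entering
#' the steady-state responses — together with an exponential low-pass tap
#' shape `f(s) ~ exp(-s / tau)` (unit DC). The first-order kernel is
#' `dc1 * f`, the second-order kernel is separable, `dc2 * f(s1) f(s2)`.
#' Custom tap shapes may be supplied; taps must be causal (lags >= 0).
#'
#' @param dc0 zeroth-order (constant) term.
#' @param dc1,dc2 DC sums of the first/second-order kernels.
#' @param tau tap time constant in frames.
#' @param taps optional explicit tap shape (normalized internally to unit
#'   DC); overrides `tau`.
#' @param lags integer lags of the taps (default `0:(length(taps)-1)`); any
#'   negative lag is an error (non-causal).
#' @return Object of class `volterra_kernels`.
#' @export
volterra_kernels <- function(dc0 = 0, dc1 = 0, dc2 = 0, tau = 2,
                             taps = NULL, lags = NULL) {
  if (is.null(taps)) {
    n <- ceiling(8 * tau) + 1
    taps <- exp(-(seq_len(n) - 1) / tau)
    lags <- 0:(n - 1)
  }
  if (is.null(lags)) lags <- 0:(length(taps) - 1)
  if (any(lags < 0)) stopf("non-causal taps: negative lags are not allowed")
  if (length(lags) != length(taps)) stopf("`lags` and `taps` lengths differ")
  taps <- taps / sum(taps)
  structure(list(dc0 = dc0, dc1 = dc1, dc2 = dc2, taps = taps,
                 lags = as.integer(lags)),
            class = "volterra_kernels")
}

# First-order filtered signal sum(f_s * x_{t - lag_s}) with zero initial
# conditions; x is a channels x T matrix.
taps_filter <- function(x, taps, lags) {
  out <- matrix(0, nrow(x), ncol(x))
  for (k in seq_along(taps)) {
    l <- lags[k]
    if (l < ncol(x))
      out[, (l + 1):ncol(x)] <- out[, (l + 1):ncol(x)] +
        taps[k] * x[, 1:(ncol(x) - l), drop = FALSE]
  }
  out
}

#' Apply a Volterra processor to a signal
#'
#' Computes `dc0 + sum_s h1(s) x(t-s) + sum_{s1,s2} h2(s1,s2) x(t-s1)
#' x(t-s2)` per time step, with zero initial conditions before the first
#' sample. The separable second-order kernel makes the double sum the square
#' of the tap-filtered signal scaled by `dc2`.
#'
#' @param kernels a [volterra_kernels()] object.
#' @param x numeric vector (one channel) or channels x T matrix.
#' @return Same shape as `x`.
#' @export
volterra_apply <- function(kernels, x) {
  stopifnot(inherits(kernels, "volterra_kernels"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) < length(kernels$taps))
    stopf("signal shorter than the kernel memory (%d taps)", length(kernels$taps))
  fx <- taps_filter(x, kernels$taps, kernels$lags)
  out <- kernels$dc0 + kernels$dc1 * fx + kernels$dc2 * fx^2
  if (vec) drop(out) else out
}
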