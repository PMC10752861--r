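#' Band-limited random texture
#'
#' Generates a deterministic, seeded random texture by spectrally filtering
#' white Gaussian noise: the amplitude spectrum is kept flat up to a radial
#' spatial-frequency cutoff and rolled off with a raised-cosine taper, so the
#' image has non-degenerate contrast at every spatial frequency below the
#' cutoff. Intensities are rescaled to `range` (Michelson contrast 0.8 for
#' the default `[0.1, 0.9]`). Because the construction is Fourier-based the
#' texture is periodic, which [translate_sequence()] can exploit with
#' `wrap = TRUE`.
#'
#' @param seed integer RNG seed; identical seeds give bit-identical textures.
#' @param size image side length in pixels (>= 64).
#' @param cutoff radial frequency cutoff in rad/px (default `pi`, i.e.
#'   content up to the Nyquist bandwidth, like a natural photograph).
#' @param range length-2 intensity range of the output.
#' @return `size x size` numeric matrix of intensities.
#' @export
make_texture <- function(seed, size = 256, cutoff = pi,
                         range = c(0.1, 0.9)) {
  if (size < 64) stopf("`size` must be >= 64 (got %d)", size)
  stopifnot(cutoff > 0, cutoff <= pi, range[2] > range[1], range[1] >= 0)
  noise <- with_local_seed(seed, matrix(stats::rnorm(size * size), size, size))
  k <- c(0:floor(size / 2), -(ceiling(size / 2) - 1):-1) * (2 * pi / size)
  wr <- sqrt(outer(k^2, k^2, `+`))
  taper_lo <- 0.85 * cutoff
  mask <- ifelse(wr <= taper_lo, 1,
                 ifelse(wr >= cutoff, 0,
                        0.5 * (1 + cos(pi * (wr - taper_lo) / (cutoff - taper_lo)))))
  mask[1, 1] <- 0 # no DC: mean set explicitly below
  img <- Re(stats::fft(stats::fft(noise) * mask, inverse = TRUE)) / (size^2)
  lo <- min(img); hi <- max(img)
  range[1] + (img - lo) / (hi - lo) * (range[2] - range[1])
}

#' Translating image sequence with ground-truth flow
#'
#' Builds a video of a fixed scene translating at a constant velocity
#' `v = (vx, vy)` px/frame: frame `t` (0-based) shows the source content
#' shifted by `t * v`, i.e. the crop window slides by `-v` over the source.
#' Sub-pixel shifts use separable cubic-spline interpolation; integer shifts
#' reproduce the source samples exactly. The ground-truth flow attached to
#' the result equals `v` for every frame.
#'
#' @param image source image matrix. Must be large enough that the sliding
#'   window, plus an 8 px guard, stays inside it (`wrap = FALSE`), or is
#'   treated as periodic (`wrap = TRUE`, natural for [make_texture()] output).
#' @param v numeric length-2 velocity `(vx, vy)` in px/frame, `|v| <= 4`.
#' @param n_frames number of frames (>= 1).
#' @param out_size length-2 output `(H, W)`; default: the largest centred
#'   window that respects the margin (`wrap = FALSE`) or the source size
#'   (`wrap = TRUE`).
#' @param wrap sample the source periodically instead of requiring a margin.
#' @return A [frame_sequence()] with ground-truth flow.
#' @export
translate_sequence <- function(image, v, n_frames, out_size = NULL,
                               wrap = FALSE) {
  stopifnot(is.matrix(image), length(v) == 2, n_frames >= 1)
  if (sqrt(sum(v^2)) > 4) stopf("|v| must be <= 4 px/frame")
  vx <- v[1]; vy <- v[2]
  ny <- nrow(image); nx <- ncol(image)
  travel <- (n_frames - 1) * abs(c(vy, vx))
  if (wrap) {
    pad <- 8L
    if (is.null(out_size)) out_size <- c(ny, nx)
    if (out_size[1] > ny || out_size[2] > nx)
      stopf("out_size exceeds the (periodic) source size")
    ri <- ((seq_len(ny + 2 * pad) - pad - 1) %% ny) + 1
    ci <- ((seq_len(nx + 2 * pad) - pad - 1) %% nx) + 1
    big <- image[ri, ci]
    frames <- array(0, dim = c(out_size[1], out_size[2], n_frames))
    for (t in seq_len(n_frames)) {
      yq <- ((seq_len(out_size[1]) - 1 - (t - 1) * vy) %% ny) + 1 + pad
      xq <- ((seq_len(out_size[2]) - 1 - (t - 1) * vx) %% nx) + 1 + pad
      frames[, , t] <- spline_sample_matrix(big, yq, xq)
    }
  } else {
    margin <- ceiling(travel) + 8L
    if (is.null(out_size)) out_size <- c(ny, nx) - 2L * margin
    if (any(out_size < 16))
      stopf("source too small: window of %d x %d after a %d/%d px margin",
            out_size[1], out_size[2], margin[1], margin[2])
    oy0 <- floor((ny - out_size[1]) / 2)
    ox0 <- floor((nx - out_size[2]) / 2)
    frames <- array(0, dim = c(out_size[1], out_size[2], n_frames))
    for (t in seq_len(n_frames)) {
      frames[, , t] <- spline_sample_matrix(
        image,
        yq = seq_len(out_size[1]) + oy0 - (t - 1) * vy,
        xq = seq_len(out_size[2]) + ox0 - (t - 1) * vx)
    }
  }
  frame_sequence(frames,
                 flow = list(vx = rep(vx, n_frames), vy = rep(vy, n_frames)))
}

#' Brightness staircase
#'
#' Multiplies frame `t` (0-based) by `factor^floor(t / period)`: with the
#' defaults and 500 frames the light intensity steps up by a factor of 10
#' after every 100 frames, spanning 5 orders of magnitude.
#'
#' @param seq a [frame_sequence()].
#' @param factor per-step intensity multiplier (> 0).
#' @param period frames per step (>= 1).
#' @return A [frame_sequence()].
#' @export
brightness_staircase <- function(seq, factor = 10, period = 100) {
  stopifnot(inherits(seq, "frame_sequence"), factor > 0, period >= 1)
  out <- seq$frames
  for (t in seq_len(dim(out)[3]))
    out[, , t] <- out[, , t] * factor^((t - 1) %/% period)
  frame_sequence(out, dt = seq$dt, intensity_scale = seq$intensity_scale,
                 flow = seq$flow)
}

# Separable Gaussian blur with reflected borders (helper for the local mean
# in contrast_staircase).
gaussian_blur <- function(img, sigma) {
  rad <- ceiling(3 * sigma)
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2)); k <- k / sum(k)
  reflect_idx <- function(i, n) {
    i <- ((i - 1) %% (2 * n)) + 1
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  blur_rows <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      idx <- reflect_idx(seq_len(n) + (j - rad - 1), n)
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    out
  }
  t(blur_rows(t(blur_rows(img))))
}

#' Contrast staircase
#'
#' Within step `l = floor(t / period)` (0-based), pixel deviations from a
#' local mean (Gaussian blur, `sigma = 16` px) are scaled by `factor^l` and
#' the result is clipped at 0, so the local Michelson contrast doubles per
#' step for the default `factor = 2` while the local mean is preserved up to
#' clipping.
#'
#' @inheritParams brightness_staircase
#' @param sigma scale of the Gaussian local mean, px.
#' @return A [frame_sequence()].
#' @export
contrast_staircase <- function(seq, factor = 2, period = 100, sigma = 16) {
  stopifnot(inherits(seq, "frame_sequence"), factor > 0)
  out <- seq$frames
  for (t in seq_len(dim(out)[3])) {
    g <- factor^((t - 1) %/% period)
    if (g != 1) {
      m <- gaussian_blur(out[, , t], sigma)
      out[, , t] <- pmax(m + g * (out[, , t] - m), 0)
    }
  }
  frame_sequence(out, dt = seq$dt, intensity_scale = seq$intensity_scale,
                 flow = seq$flow)
}

#' Photoreceptor saturation sigmoid
#'
#' Static photoreceptor encoding: a logistic function of `log10(intensity)`
#' centred at `half_point`, mapping intensity into (0, 1) with the 0.1-0.9
#' output span covering `decades_linear` decades of input. Emulates the
#' saturating intensity-response curve of fly photoreceptors (and vertebrate
#' cones) with a ~2-decade quasi-linear range.
#'
#' @param seq a [frame_sequence()] with nonnegative intensities.
#' @param half_point input intensity mapped to output 0.5 (> 0).
#' @param decades_linear width of the 0.1-0.9 output span, in decades.
#' @return A [frame_sequence()] with intensities in `[0, 1)`.
#' @export
photoreceptor_sigmoid <- function(seq, half_point, decades_linear = 2) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (!is.numeric(half_point) || half_point <= 0)
    stopf("`half_point` must be > 0")
  kappa <- log(81) / decades_linear # 0.9 output at half_point * 10^(d/2)
  f <- function(m) stats::plogis(kappa * (log10(pmax(m, 0)) - log10(half_point)))
  out <- map_frames(seq, f)
  out$intensity_scale <- "sigmoid-encoded"
  out
}

#' Additive white Gaussian noise at a prescribed SNR
#'
#' Adds zero-mean Gaussian noise with variance `mean(u^2) * 10^(-snr_db/10)`
#' so that `10*log10(signal power / noise power) = snr_db`. `snr_db = Inf`
#' returns the input unchanged. The output is not clipped, so very noisy
#' sequences may contain negative values.
#'
#' @param seq a [frame_sequence()].
#' @param snr_db target signal-to-noise ratio in dB (may be `Inf`).
#' @param seed optional integer seed for reproducible noise.
#' @return A [frame_sequence()].
#' @export
add_awgn <- function(seq, snr_db, seed = NULL) {
  stopifnot(inherits(seq, "frame_sequence"), is.numeric(snr_db))
  if (is.infinite(snr_db)) return(seq)
  p_sig <- mean(seq$frames^2)
  sd_n <- sqrt(p_sig * 10^(-snr_db / 10))
  noise_of <- function() array(stats::rnorm(length(seq$frames), sd = sd_n),
                               dim = dim(seq$frames))
  noise <- if (is.null(seed)) noise_of() else with_local_seed(seed, noise_of())
  frame_sequence(seq$frames + noise, dt = seq$dt,
                 intensity_scale = seq$intensity_scale, flow = seq$flow)
}

#' Uniform quantization of a frame sequence
#'
#' Emulates a finite-bit-depth sensor/recording: intensities are clipped to
#' `[0, max_value]` and rounded to `2^bits` uniform levels.
#'
#' @param seq a [frame_sequence()].
#' @param bits bit depth (default 8).
#' @param max_value full-scale intensity.
#' @return A [frame_sequence()].
#' @export
quantize_bits <- function(seq, bits = 8, max_value = 1) {
  stopifnot(inherits(seq, "frame_sequence"), bits >= 1)
  n <- 2^bits - 1
  map_frames(seq, function(m) round(clamp(m / max_value, 0, 1) * n) / n * max_value)
}
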