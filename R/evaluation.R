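#' Angular error between estimated and true velocity
#'
#' The planar inter-vector angle `acos(<v_est, v_true> / (|v_est||v_true|))`
#' in degrees. Pairs where the estimate is (numerically) zero while the
#' truth is not are "missed" detections and return `NA` — they are excluded
#' from error means and accounted for by a detection rate instead.
#'
#' @param vx_est,vy_est,vx_true,vy_true velocity components, px/frame
#'   (vectorized).
#' @return Angular error(s) in degrees, in `[0, 180]`; `NA` for misses.
#' @export
angular_error <- function(vx_est, vy_est, vx_true, vy_true) {
  ne <- sqrt(vx_est^2 + vy_est^2)
  nt <- sqrt(vx_true^2 + vy_true^2)
  dotp <- vx_est * vx_true + vy_est * vy_true
  out <- acos(clamp(dotp / (ne * nt), -1, 1)) * 180 / pi
  out[ne == 0 | nt == 0 | !is.finite(out)] <- NA_real_
  out
}

#' End-point error between estimated and true velocity
#'
#' Euclidean norm of the vector difference, px/frame.
#'
#' @inheritParams angular_error
#' @return End-point error(s), `>= 0`.
#' @export
endpoint_error <- function(vx_est, vy_est, vx_true, vy_true) {
  sqrt((vx_est - vx_true)^2 + (vy_est - vy_true)^2)
}

#' Polar benchmark of the phase-based detector
#'
#' Reproduces the ground-truth translation protocol: a seeded band-limited
#' texture is translated at every combination of `n_angles` equally spaced
#' directions and the given speeds (sub-pixel shifts by cubic-spline
#' interpolation, periodic sampling), the detector runs at a grid of
#' interior centres, and the mean angular error (AE) and end-point error
#' (EPE) are aggregated per (direction, speed) cell. Cells with speeds
#' above the aliasing bound `pi/r` are flagged. Misses (PMI below the
#' detection threshold) are excluded from the error means and reported as a
#' detection fraction.
#'
#' @param speeds speeds in px/frame, each in (0, 4).
#' @param n_angles number of motion directions (>= 8), equally spaced over
#'   `[0, 2*pi)`.
#' @param seed texture seed (the texture is shared by all cells).
#' @param texture_size side of the square texture, px.
#' @param n_frames frames generated per cell.
#' @param pairs frame indices evaluated (pair `(t-1, t)`); default the two
#'   central pairs, after any filter transients.
#' @param bank,op detector configuration ([build_filter_bank()],
#'   [radon_operator()]).
#' @param eval_stride spacing of evaluated centres, px.
#' @param tau detection threshold on the PMI.
#' @return Object of class `polar_benchmark`: per-cell summary (`$cells`),
#'   per-estimate table (`$estimates`) and the configuration. Use
#'   [generics::tidy()] / [generics::glance()] / [ggplot2::autoplot()].
#' @export
run_polar_benchmark <- function(speeds = seq(0.25, 2, by = 0.25),
                                n_angles = 16, seed = 0,
                                texture_size = 256, n_frames = 10,
                                pairs = NULL,
                                bank = build_filter_bank(), op = NULL,
                                eval_stride = 8, tau = NULL) {
  stopifnot(all(speeds > 0), all(speeds < 4), n_angles >= 8)
  if (is.null(op)) op <- radon_operator(bank)
  if (is.null(pairs)) {
    mid <- ceiling(n_frames / 2)
    pairs <- c(mid, mid + 1)
  }
  img <- make_texture(seed, texture_size)
  centers <- default_centers(c(texture_size, texture_size), bank,
                             stride = eval_stride)
  angles <- seq(0, 2 * pi, length.out = n_angles + 1)[seq_len(n_angles)]
  grid <- tidyr::expand_grid(angle = angles, speed = speeds)
  v_alias <- max_unaliased_speed(bank$r)
  est <- purrr::pmap_dfr(grid, function(angle, speed) {
    v <- speed * c(cos(angle), sin(angle))
    seq <- translate_sequence(img, v, n_frames, wrap = TRUE)
    d <- detect_motion(seq, bank, op, centers = centers, pairs = pairs,
                       tau = tau)
    d$true_vx <- v[1]; d$true_vy <- v[2]
    d$angle_true <- angle; d$speed_true <- speed
    d
  })
  est$ae_deg <- angular_error(est$vx, est$vy, est$true_vx, est$true_vy)
  est$epe <- endpoint_error(est$vx, est$vy, est$true_vx, est$true_vy)
  cells <- est |>
    dplyr::group_by(angle_true, speed_true) |>
    dplyr::summarise(
      mean_ae_deg = mean(.data$ae_deg[.data$detected], na.rm = TRUE),
      mean_epe = mean(.data$epe[.data$detected], na.rm = TRUE),
      n = dplyr::n(),
      detected_frac = mean(.data$detected),
      .groups = "drop") |>
    dplyr::mutate(angle_deg = .data$angle_true * 180 / pi,
                  aliased = .data$speed_true > v_alias)
  structure(list(cells = cells, estimates = est,
                 config = list(speeds = speeds, n_angles = n_angles,
                               seed = seed, texture_size = texture_size,
                               n_frames = n_frames, pairs = pairs,
                               eval_stride = eval_stride, r = bank$r,
                               alias_bound = v_alias)),
            class = "polar_benchmark")
}

#' @export
print.polar_benchmark <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<polar_benchmark> %d cells (%d directions x %d speeds), r = %.4g rad/px\n",
              nrow(x$cells), x$config$n_angles, length(x$config$speeds),
              x$config$r))
  cat(sprintf("  unaliased cells (speed <= %.3g): mean AE %.3f deg, mean EPE %.4f px/frame\n",
              x$config$alias_bound, g$mean_ae_deg, g$mean_epe))
  invisible(x)
}

#' Brightness-staircase cascade benchmark
#'
#' Evaluates end-to-end motion detection while the scene brightness steps
#' up by `factor` every `period` frames over `n_levels` levels. The first
#' stage is either a static photoreceptor sigmoid (`gain_variant = "none"`,
#' saturating at extreme levels) or a gain-control DNP that replaces it
#' (`"mvp_fb"` or `"adaptive"`). The first-stage output is then passed
#' through a finite-precision sensor model (uniform `bits`-bit quantization
#' plus a small Gaussian noise floor) before phase-based detection, so the
#' loss of contrast at saturated levels is observable. Detection runs on
#' the last frames of each level (after adaptation transients) and is
#' summarized per brightness level.
#'
#' @param gain_variant `"none"`, `"mvp_fb"` or `"adaptive"`.
#' @param seed texture / noise seed.
#' @param v translation velocity (px/frame).
#' @param period frames per brightness level.
#' @param factor brightness multiplier per level.
#' @param n_levels number of levels (default 5, spanning 5 decades).
#' @param frame_size side of the evaluated frames, px.
#' @param base_scale intensity scale of the level-0 frames.
#' @param params gain-control [dnp_params()].
#' @param bank,op detector configuration.
#' @param bits,noise_sd sensor model: quantization depth and absolute noise
#'   standard deviation (on the unit-range first-stage output).
#' @param eval_stride spacing of evaluated centres, px.
#' @return Object of class `cascade_benchmark` with `$levels` (per-level
#'   summary tibble) and `$estimates`.
#' @export
run_cascade_benchmark <- function(gain_variant = c("none", "mvp_fb", "adaptive"),
                                  seed = 0, v = c(0.5, 0), period = 100,
                                  factor = 10, n_levels = 5,
                                  frame_size = 128, base_scale = 10,
                                  params = dnp_params(),
                                  bank = build_filter_bank(), op = NULL,
                                  bits = 8, noise_sd = 1.5 / 255,
                                  eval_stride = 4) {
  gain_variant <- match.arg(gain_variant)
  if (is.null(op)) op <- radon_operator(bank)
  n_total <- period * n_levels
  img <- make_texture(seed, 128) * base_scale
  seq0 <- translate_sequence(img, v, n_total,
                             out_size = c(frame_size, frame_size),
                             wrap = TRUE)
  seq_stair <- brightness_staircase(seq0, factor = factor, period = period)
  front <- switch(gain_variant,
    none = photoreceptor_sigmoid(
      seq_stair, half_point = exp(mean(log(pmax(seq_stair$frames, 1e-12))))),
    mvp_fb = dnp_simulate(seq_stair, params, variant = "mvp_fb"),
    adaptive = adaptive_simulate(seq_stair, params,
                                 solver = "quasi_steady")$v)
  sensed <- quantize_bits(front, bits = bits)
  noise <- with_local_seed(seed + 1L,
    array(stats::rnorm(length(sensed$frames), sd = noise_sd),
          dim = dim(sensed$frames)))
  sensed <- frame_sequence(sensed$frames + noise, flow = seq0$flow)
  centers <- default_centers(c(frame_size, frame_size), bank,
                             stride = eval_stride)
  eval_t <- unlist(lapply(seq_len(n_levels), function(l)
    c(l * period - 1, l * period)))
  est <- detect_motion(sensed, bank, op, centers = centers, pairs = eval_t)
  est$level <- (est$t - 1) %/% period
  est$ae_deg <- angular_error(est$vx, est$vy, v[1], v[2])
  est$epe <- endpoint_error(est$vx, est$vy, v[1], v[2])
  levels <- est |>
    dplyr::group_by(level) |>
    dplyr::summarise(
      detected_frac = mean(.data$detected),
      mean_ae_deg = mean(.data$ae_deg[.data$detected], na.rm = TRUE),
      mean_epe = mean(.data$epe[.data$detected], na.rm = TRUE),
      mean_speed = mean(.data$speed),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(brightness = base_scale * factor^.data$level,
                  gain_variant = gain_variant)
  structure(list(levels = levels, estimates = est,
                 config = list(gain_variant = gain_variant, seed = seed,
                               v = v, period = period, factor = factor,
                               n_levels = n_levels, bits = bits,
                               noise_sd = noise_sd)),
            class = "cascade_benchmark")
}

#' @export
print.cascade_benchmark <- function(x, ...) {
  cat(sprintf("<cascade_benchmark> gain_variant = \"%s\", %d levels x%g brightness steps\n",
              x$config$gain_variant, x$config$n_levels, x$config$factor))
  print(x$levels)
  invisible(x)
}

#' Step-edge test image
#'
#' A vertical step edge between two intensity levels, used to probe
#' contrast handling of the gain-control stage.
#'
#' @param size side length, px.
#' @param lo,hi intensities left/right of the edge.
#' @return `size x size` matrix.
#' @export
edge_image <- function(size = 32, lo = 2, hi = 8) {
  m <- matrix(lo, size, size)
  m[, (size %/% 2 + 1):size] <- hi
  m
}
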