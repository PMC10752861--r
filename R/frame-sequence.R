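#' Frame sequences: stacks of 2-D intensity frames
#'
#' A `frame_sequence` holds an ordered stack of grayscale frames as an
#' `H x W x T` array of light intensities, together with the frame interval
#' (frames are the time unit, `dt = 1`) and a free-form label for the
#' intensity scale. Pixel coordinates follow image conventions: `x` is the
#' column index increasing rightward, `y` is the row index increasing
#' downward. Optionally carries the ground-truth optic flow of the sequence
#' (constant per frame for global translation).
#'
#' @param frames numeric `H x W x T` array (a single matrix is promoted to
#'   `T = 1`). All values must be finite.
#' @param dt frame interval; the package works in units of frames, so the
#'   default (and only meaningful value for the detectors) is 1.
#' @param intensity_scale label such as `"linear"` or `"gamma-2.2"`.
#' @param flow optional ground truth: a list with numeric vectors `vx`, `vy`
#'   of length `T` (px/frame).
#'
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, dt = 1, intensity_scale = "linear",
                           flow = NULL) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stopf("`frames` must be an H x W x T array")
  if (!all(is.finite(frames))) stopf("all intensities must be finite")
  if (!is.null(flow)) {
    stopifnot(is.list(flow), length(flow$vx) == dim(frames)[3],
              length(flow$vy) == dim(frames)[3])
  }
  structure(list(frames = frames, dt = dt,
                 intensity_scale = intensity_scale, flow = flow),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d frames of %d x %d px (%s)\n",
              d[3], d[1], d[2], x$intensity_scale))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$frames), max(x$frames)))
  if (!is.null(x$flow))
    cat(sprintf("  ground-truth flow attached (|v| in [%.3g, %.3g] px/frame)\n",
                min(sqrt(x$flow$vx^2 + x$flow$vy^2)),
                max(sqrt(x$flow$vx^2 + x$flow$vy^2))))
  invisible(x)
}

#' @export
dim.frame_sequence <- function(x) dim(x$frames)

#' Number of frames in a sequence
#' @param seq a [frame_sequence()].
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[3]

#' Extract one frame as a matrix
#' @param seq a [frame_sequence()].
#' @param t frame index (1-based).
#' @return `H x W` numeric matrix.
#' @export
get_frame <- function(seq, t) {
  stopifnot(t >= 1, t <= n_frames(seq))
  seq$frames[, , t]
}

# Apply a per-frame transformation f(matrix) -> matrix, keeping metadata.
map_frames <- function(seq, f, ...) {
  out <- seq$frames
  for (t in seq_len(dim(out)[3])) out[, , t] <- f(out[, , t], ...)
  frame_sequence(out, dt = seq$dt, intensity_scale = seq$intensity_scale,
                 flow = seq$flow)
}
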