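#' Read a directory of PNG/TIFF frames as a frame sequence
#'
#' Frames are read in lexicographic filename order; integer 8/16-bit images
#' come back scaled to `[0, 1]`. Colour frames are collapsed to luminance
#' by channel averaging. Optionally applies inverse gamma to recover linear
#' intensity from gamma-encoded material.
#'
#' @param path directory containing `.png`, `.tif` or `.tiff` files.
#' @param inverse_gamma if non-`NULL` (e.g. 2.2), pixel values are raised
#'   to this power and the result labelled `"linear"`.
#' @return A [frame_sequence()].
#' @export
read_frames <- function(path, inverse_gamma = NULL) {
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stopf("no PNG/TIFF frames found in %s", path)
  read1 <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE))
      png::readPNG(f) else tiff::readTIFF(f)
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
    img
  }
  mats <- lapply(files, read1)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("frames have mixed shapes")
  frames <- array(unlist(mats), dim = c(dims[, 1], length(mats)))
  scale_lab <- "linear"
  if (!is.null(inverse_gamma)) frames <- frames^inverse_gamma
  else scale_lab <- "as-read"
  frame_sequence(frames, intensity_scale = scale_lab)
}

#' Write a frame sequence as numbered image files
#'
#' @param seq a [frame_sequence()].
#' @param path output directory (created if missing).
#' @param format `"png"` (8-bit) or `"tiff"` (16-bit).
#' @param max_value full-scale intensity; defaults to the sequence maximum.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(seq, path, format = c("png", "tiff"),
                         max_value = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(seq, "frame_sequence"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (is.null(max_value)) max_value <- max(seq$frames)
  files <- character(n_frames(seq))
  for (t in seq_len(n_frames(seq))) {
    m <- clamp(seq$frames[, , t] / max_value, 0, 1)
    f <- file.path(path, sprintf("frame_%05d.%s", t,
                                 if (format == "png") "png" else "tiff"))
    if (format == "png") png::writePNG(m, f)
    else tiff::writeTIFF(m, f, bits.per.sample = 16)
    files[t] <- f
  }
  invisible(files)
}

FLO_MAGIC <- 202021.25
FLO_UNKNOWN <- 1e9

#' Write a flow field in Middlebury .flo format
#'
#' Layout: the float magic 202021.25, int32 width and height, then
#' row-major interleaved float32 `(vx, vy)` pairs; file size is
#' `12 + 8*W*H` bytes. `NA` flow is an error unless `mask_na = TRUE`, in
#' which case it is written as the conventional "unknown" sentinel (1e9).
#'
#' @param vx,vy numeric H x W matrices.
#' @param path output file.
#' @param mask_na replace `NA` with the unknown-flow sentinel.
#' @return Invisibly, `path`.
#' @export
write_flow <- function(vx, vy, path, mask_na = FALSE) {
  stopifnot(is.matrix(vx), identical(dim(vx), dim(vy)))
  if (anyNA(vx) || anyNA(vy)) {
    if (!mask_na) stopf("flow field contains NA; set mask_na = TRUE to write the unknown sentinel")
    vx[is.na(vx)] <- FLO_UNKNOWN
    vy[is.na(vy)] <- FLO_UNKNOWN
  }
  if (!all(is.finite(vx)) || !all(is.finite(vy)))
    stopf("flow field contains non-finite values")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FLO_MAGIC, con, size = 4, endian = "little")
  writeBin(as.integer(c(ncol(vx), nrow(vx))), con, size = 4,
           endian = "little")
  inter <- rbind(as.vector(t(vx)), as.vector(t(vy)))
  writeBin(as.vector(inter), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a Middlebury .flo flow field
#'
#' @param path .flo file.
#' @return List with matrices `vx`, `vy`; unknown-flow sentinels (>= 1e9)
#'   are returned as `NA`.
#' @export
read_flow <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, numeric(), 1, size = 4, endian = "little")
  if (abs(magic - FLO_MAGIC) > 1e-3) stopf("not a .flo file (bad magic)")
  wh <- readBin(con, integer(), 2, size = 4, endian = "little")
  dat <- readBin(con, numeric(), 2 * wh[1] * wh[2], size = 4,
                 endian = "little")
  vx <- matrix(dat[c(TRUE, FALSE)], wh[2], wh[1], byrow = TRUE)
  vy <- matrix(dat[c(FALSE, TRUE)], wh[2], wh[1], byrow = TRUE)
  vx[abs(vx) >= FLO_UNKNOWN] <- NA
  vy[abs(vy) >= FLO_UNKNOWN] <- NA
  list(vx = vx, vy = vy)
}
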