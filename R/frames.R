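#' Read an image file as a grayscale frame
#'
#' Frames are plain numeric matrices (rows = image rows, columns = image
#' columns) with intensities in `[0, 255]`. RGB inputs are collapsed to
#' grayscale by the per-pixel channel maximum by default — under an
#' infra-red flash the streaks are near-white, so the maximum preserves
#' them best — or by Rec. 709 luminance.
#'
#' @param path PNG or TIFF file path (JPEG decoding is not supported).
#' @param rgb `"max"` (default) or `"luminance"`.
#' @return Numeric matrix in `[0, 255]`.
#' @export
read_frame <- function(path, rgb = c("max", "luminance")) {
  rgb <- match.arg(rgb)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("read_frame: unsupported image format '", ext,
         "' (PNG and TIFF are supported)", call. = FALSE)
  )
  if (length(dim(img)) == 3) {
    img <- if (rgb == "max") {
      pmax(img[, , 1], img[, , 2], img[, , 3])
    } else {
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    }
  }
  img * 255
}

#' Write a frame to a PNG file
#'
#' @param frame Numeric matrix in `[0, 255]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  png::writePNG(pmin(pmax(frame, 0), 255) / 255, path)
  invisible(path)
}

#' Read an ordered frame sequence from a directory
#'
#' Frame order is the lexicographic filename sort, matching how video
#' decomposition tools number their output.
#'
#' @param dir Directory containing the frames.
#' @param pattern Filename regexp (default PNG/TIFF).
#' @inheritParams read_frame
#' @return List of frames.
#' @export
frames_from_dir <- function(dir, pattern = "\\.(png|tiff?)$",
                            rgb = c("max", "luminance")) {
  rgb <- match.arg(rgb)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0) {
    stop("frames_from_dir: no frames found in ", dir, call. = FALSE)
  }
  lapply(files, read_frame, rgb = rgb)
}

.check_frame <- function(f) {
  if (!is.matrix(f) || !is.numeric(f)) {
    stop("expected a numeric matrix frame", call. = FALSE)
  }
  if (nrow(f) < 8 || ncol(f) < 8) {
    stop("frame must be at least 8 x 8 pixels", call. = FALSE)
  }
  invisible(f)
}
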