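# Plate image container and raster I/O.
#
# Conventions used across the whole package:
#  * coordinates are (x = column, y = row), 0-based, pixel centers at
#    integers; an R matrix element m[y + 1, x + 1] is the pixel (x, y);
#  * channel values are 8-bit (0-255);
#  * grayscale is ITU-R BT.601 luminance: round(0.299 R + 0.587 G + 0.114 B);
#  * hue is stored in degrees on the 0-360 convention (undefined hue of
#    achromatic pixels is set to 0), saturation in [0, 1].

#' Construct a plate image from an RGB raster
#'
#' Builds the `plate_image` container every pipeline stage consumes: the RGB
#' raster plus derived grayscale (BT.601 luminance) and HSV hue/saturation
#' views.
#'
#' @param rgb numeric or integer H x W x 3 array with values in `[0, 255]`.
#' @param source_path optional origin of the raster, kept for reporting.
#' @return a `plate_image` with fields `rgb`, `gray` (integer matrix),
#'   `hue` (degrees, 0-360), `sat`, `width`, `height`, `source_path`.
#' @export
plate_image <- function(rgb, source_path = "") {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    cfu_error("cfuseg_format_error", "rgb must be an H x W x 3 array")
  if (min(rgb) < 0 || max(rgb) > 255)
    cfu_error("cfuseg_format_error", "rgb channel values must lie in [0, 255]")
  storage.mode(rgb) <- "integer"
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  R <- matrix(rgb[, , 1], H, W)
  G <- matrix(rgb[, , 2], H, W)
  B <- matrix(rgb[, , 3], H, W)
  gray <- matrix(as.integer(round(0.299 * R + 0.587 * G + 0.114 * B)), H, W)
  hs <- rgb_to_hue_sat(R, G, B)
  structure(list(
    rgb = rgb, gray = gray, hue = hs$hue, sat = hs$sat,
    width = ncol(gray), height = nrow(gray), source_path = source_path
  ), class = "plate_image")
}

# vectorized RGB (0-255 matrices) -> hue (deg) / saturation
rgb_to_hue_sat <- function(R, G, B) {
  M <- pmax(R, G, B); m <- pmin(R, G, B); C <- M - m
  h <- matrix(0, nrow(R), ncol(R))
  nz <- C > 0
  iR <- nz & M == R
  iG <- nz & M == G & !iR
  iB <- nz & M == B & !iR & !iG
  h[iR] <- ((G[iR] - B[iR]) / C[iR]) %% 6
  h[iG] <- (B[iG] - R[iG]) / C[iG] + 2
  h[iB] <- (R[iB] - G[iB]) / C[iB] + 4
  s <- matrix(0, nrow(R), ncol(R))
  s[M > 0] <- C[M > 0] / M[M > 0]
  list(hue = 60 * h, sat = s)
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image %d x %d px%s>\n", x$width, x$height,
              if (nzchar(x$source_path)) paste0(" from ", x$source_path) else ""))
  invisible(x)
}

#' Load a plate photograph
#'
#' Reads an 8-bit RGB PNG or JPEG file and wraps it as a [plate_image()].
#' Grayscale images are refused: downstream color classification needs the
#' chroma channels. TIFF is not supported in this build (no reader available).
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @return a `plate_image`.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    cfu_error("cfuseg_io_error", "path must be a single file path")
  if (!file.exists(path))
    cfu_error("cfuseg_io_error", sprintf("cannot read image: '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    cfu_error("cfuseg_format_error",
              sprintf("unsupported image format '.%s' for '%s' (PNG/JPEG only)", ext, path))
  )
  if (length(dim(arr)) == 2L)
    cfu_error("cfuseg_format_error",
              sprintf("'%s' is single-channel; an RGB image is required", path))
  if (dim(arr)[3] == 4L) arr <- arr[, , 1:3, drop = FALSE] # drop alpha
  if (dim(arr)[3] != 3L)
    cfu_error("cfuseg_format_error",
              sprintf("'%s' has %d channels; 3 expected", path, dim(arr)[3]))
  plate_image(round(arr * 255), source_path = path)
}

#' Write a plate image as PNG
#'
#' @param image a `plate_image`.
#' @param path output path.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "plate_image"))
  ok <- tryCatch({
    png::writePNG(image$rgb / 255, target = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    cfu_error("cfuseg_io_error", sprintf("cannot write image to '%s'", path))
  invisible(path)
}

#' Median-filter denoising
#'
#' Replaces every pixel by the median of its `kernel` x `kernel`
#' neighborhood, with edge replication at the borders. Applied to a
#' `plate_image`, each RGB channel is filtered and the grayscale and hue
#' views are recomputed; applied to a matrix, the filtered matrix is
#' returned.
#'
#' @param image a `plate_image` or an integer matrix.
#' @param kernel odd window width, default 3.
#' @return object of the same kind as `image`.
#' @export
denoise_median <- function(image, kernel = 3L) {
  kernel <- check_odd_kernel(kernel, "median kernel")
  if (is.matrix(image)) {
    m <- image
    storage.mode(m) <- "integer"
    return(.median_filter_cpp(m, kernel))
  }
  stopifnot(inherits(image, "plate_image"))
  out <- image$rgb
  for (ch in 1:3)
    out[, , ch] <- .median_filter_cpp(
      matrix(image$rgb[, , ch], image$height, image$width), kernel)
  plate_image(out, source_path = image$source_path)
}
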