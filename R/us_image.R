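#' Ultrasound image container
#'
#' A `us_image` is a numeric matrix of intensities on the internal `[0, 1]`
#' scale, the latent (sharp) image or blurred observation of the deblurring
#' model.  All solver entry points require at least 8 x 8 pixels.
#'
#' @param x numeric matrix with finite values in `[0, 1]`.
#' @return An object of class `us_image` (a numeric matrix).
#' @examples
#' img <- us_image(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
us_image <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || length(dim(x)) != 2L)
    stop("`x` must be a numeric matrix", call. = FALSE)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x)))
    stop("intensities must be finite", call. = FALSE)
  if (min(x) < 0 || max(x) > 1)
    stop("intensities must lie in [0, 1]; rescale before constructing",
         call. = FALSE)
  structure(x, class = c("us_image", "matrix", "array"))
}

#' @export
print.us_image <- function(x, ...) {
  cat(sprintf("<us_image> %d x %d, intensity range [%.4f, %.4f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
as.matrix.us_image <- function(x, ...) {
  unclass(x)
}

#' @rdname us_image
#' @export
is_us_image <- function(x) inherits(x, "us_image")

#' @export
plot.us_image <- function(x, ..., main = NULL) {
  m <- unclass(x)
  graphics::image(t(m)[, nrow(m):1, drop = FALSE], col = grDevices::gray.colors(256, 0, 1),
                  zlim = c(0, 1), asp = nrow(m) / ncol(m), axes = FALSE, main = main, ...)
  invisible(x)
}

# internal: plain matrix view, validated shape for solver entry points
as_pixel_matrix <- function(img, min_side = 1L) {
  m <- unclass(as.matrix(img))
  if (nrow(m) < min_side || ncol(m) < min_side)
    stop(sprintf("image must be at least %d x %d pixels", min_side, min_side),
         call. = FALSE)
  m
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Read a grayscale image as a `us_image`
#'
#' Reads an 8- or 16-bit PNG or TIFF.  Intensities are scaled to `[0, 1]` by
#' the bit-depth maximum (the underlying readers already do this).  RGB input
#' is reduced to a single channel by the standard luma weighting
#' (0.299 R + 0.587 G + 0.114 B) with a message, since the solver operates on
#' single-channel ultrasound; an alpha channel is dropped.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return A [us_image].
#' @seealso [write_us_image()]
#' @export
read_us_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  )
  if (length(dim(a)) == 3L) {
    nchan <- dim(a)[3]
    if (nchan >= 3L) {
      message("RGB input reduced to grayscale by luma weighting")
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]  # gray + alpha
    }
  }
  us_image(clip01(a))
}

#' Write a `us_image` to disk
#'
#' Quantizes to the requested bit depth and writes PNG or TIFF.  Reading the
#' file back reproduces the image within one quantization step
#' (`1/255` or `1/65535`).  16-bit output is available for TIFF only; the PNG
#' writer used here always emits 8-bit samples.
#'
#' @param img a [us_image].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth 8 or 16 (16 requires TIFF).
#' @return `path`, invisibly.
#' @export
write_us_image <- function(img, path, bit_depth = 8L) {
  m <- as_pixel_matrix(img)
  if (!bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  maxv <- 2^bit_depth - 1
  q <- round(m * maxv) / maxv
  ok <- switch(ext,
    png = {
      if (bit_depth == 16L)
        stop("16-bit PNG writing is not supported; use TIFF", call. = FALSE)
      png::writePNG(q, path)
      TRUE
    },
    tif = ,
    tiff = {
      tiff::writeTIFF(q, path, bits.per.sample = as.integer(bit_depth))
      TRUE
    },
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  )
  if (!isTRUE(ok) || !file.exists(path))
    stop(sprintf("failed to write image to '%s'", path), call. = FALSE)
  invisible(path)
}
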