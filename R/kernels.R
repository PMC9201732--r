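#' Blur kernel (point-spread function)
#'
#' A `blur_kernel` is a small non-negative matrix with odd side lengths
#' (so the center is unambiguous, at `((k-1)/2, (k-1)/2)` 0-based) whose
#' entries sum to one.
#'
#' @param w numeric matrix of non-negative weights with odd side lengths.
#'   The matrix is renormalized to unit mass if it is within `1e-8` of it;
#'   otherwise supply `normalize = TRUE` to force renormalization.
#' @param normalize divide by the total mass regardless of how far it is
#'   from one.
#' @return An object of class `blur_kernel`.
#' @examples
#' kernel_delta(5)
#' kernel_gaussian(7, sigma = 1.2)
#' kernel_motion(9, length = 7, angle = 30)
#' @export
blur_kernel <- function(w, normalize = FALSE) {
  w <- as.matrix(w)
  storage.mode(w) <- "double"
  if (nrow(w) %% 2L == 0L || ncol(w) %% 2L == 0L)
    stop("kernel side lengths must be odd", call. = FALSE)
  if (anyNA(w) || any(!is.finite(w)) || any(w < 0))
    stop("kernel weights must be finite and non-negative", call. = FALSE)
  s <- sum(w)
  if (s <= 0) stop("kernel has zero mass", call. = FALSE)
  if (normalize || abs(s - 1) <= 1e-8) w <- w / s
  else stop("kernel weights must sum to 1 (or pass normalize = TRUE)",
            call. = FALSE)
  structure(w, class = c("blur_kernel", "matrix", "array"))
}

#' @export
print.blur_kernel <- function(x, ...) {
  cat(sprintf("<blur_kernel> %d x %d, support mass at center %.3f\n",
              nrow(x), ncol(x), x[(nrow(x) + 1) / 2, (ncol(x) + 1) / 2]))
  invisible(x)
}

#' @rdname blur_kernel
#' @param size odd side length in pixels.
#' @export
kernel_delta <- function(size = 3L) {
  w <- matrix(0, size, size)
  w[(size + 1) / 2, (size + 1) / 2] <- 1
  blur_kernel(w)
}

#' @rdname blur_kernel
#' @param sigma Gaussian standard deviation in pixels.
#' @export
kernel_gaussian <- function(size, sigma) {
  r <- (size - 1) / 2
  d <- outer((-r:r)^2, (-r:r)^2, "+")
  blur_kernel(exp(-d / (2 * sigma^2)), normalize = TRUE)
}

#' @rdname blur_kernel
#' @param length motion extent in pixels (<= `size`).
#' @param angle motion direction in degrees, counter-clockwise from the
#'   positive x (column) axis.
#' @export
kernel_motion <- function(size, length, angle = 0) {
  if (length > size) stop("motion length exceeds kernel size", call. = FALSE)
  r <- (size - 1) / 2
  w <- matrix(0, size, size)
  th <- angle * pi / 180
  half <- (length - 1) / 2
  # rasterize the segment with bilinear splatting for sub-pixel ends
  ts <- if (length <= 1) 0 else seq(-half, half, length.out = max(2L, ceiling(length * 8)))
  for (t in ts) {
    x <- t * cos(th); y <- -t * sin(th)       # image rows grow downward
    i <- y + r + 1; j <- x + r + 1
    i0 <- floor(i); j0 <- floor(j); fi <- i - i0; fj <- j - j0
    for (di in 0:1) for (dj in 0:1) {
      ii <- i0 + di; jj <- j0 + dj
      if (ii >= 1 && ii <= size && jj >= 1 && jj <= size)
        w[ii, jj] <- w[ii, jj] +
          (if (di == 0) 1 - fi else fi) * (if (dj == 0) 1 - fj else fj)
    }
  }
  blur_kernel(w, normalize = TRUE)
}

# internal: TRUE when the kernel is (numerically) a centered delta
is_delta_kernel <- function(kernel, tol = 1e-12) {
  k <- unclass(kernel)
  ctr <- k[(nrow(k) + 1) / 2, (ncol(k) + 1) / 2]
  abs(ctr - 1) <= tol && sum(abs(k)) - ctr <= tol
}

#' Write / read a kernel as a plain-text matrix
#'
#' Plain whitespace-separated text, one kernel row per line; a portable,
#' diffable companion to the PNG rendering of the kernel.
#'
#' @param kernel a [blur_kernel].
#' @param path output (input) path.
#' @return `write_kernel_txt` returns `path` invisibly; `read_kernel_txt`
#'   returns a [blur_kernel].
#' @export
write_kernel_txt <- function(kernel, path) {
  write.table(unclass(kernel), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_txt
#' @export
read_kernel_txt <- function(path) {
  blur_kernel(as.matrix(read.table(path)), normalize = TRUE)
}
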