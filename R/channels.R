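#' Extreme-channel operators
#'
#' The dark channel of an image is the per-pixel minimum intensity over a
#' square patch centered at the pixel; the bright channel is the per-pixel
#' maximum.  The *secondary sparse* channels iterate the operator twice
#' (min-of-min / max-of-max), which equals a single extremum filter of twice
#' the patch radius.  Sharp images with genuinely dark (vessel lumen) and
#' bright (fascia) structure have sparse dark channels and sparse bright-channel
#' complements; blurring destroys that sparsity, which is what the deblurring
#' prior exploits.
#'
#' Patches are clipped at the image boundary (no padding values participate),
#' so border extrema come only from real pixels.  Ties are broken by the first
#' occurrence in row-major patch scan order, making the recorded
#' argmin/argmax maps — and hence [selection_operator()] — deterministic.
#'
#' @param img a [us_image] or numeric matrix in `[0, 1]`.
#' @param patch_size odd window side length (>= 1); `1` returns the image.
#' @return An object of class `channel_map`: a list with `values` (matrix,
#'   same shape as `img`), `arg_row` / `arg_col` (1-based coordinates of the
#'   attaining pixel), `patch_size` and `type`.
#' @examples
#' img <- us_image(matrix(runif(100), 10, 10))
#' d <- dark_channel(img, 3)
#' all(d$values <= unclass(img))
#' @export
dark_channel <- function(img, patch_size) {
  channel_extremum(img, patch_size, maximum = FALSE, type = "dark")
}

#' @rdname dark_channel
#' @export
bright_channel <- function(img, patch_size) {
  channel_extremum(img, patch_size, maximum = TRUE, type = "bright")
}

channel_extremum <- function(img, patch_size, maximum, type) {
  m <- as_pixel_matrix(img)
  check_patch_size(patch_size)
  if (patch_size == 1L) {
    res <- list(values = m,
                arg_row = matrix(rep(seq_len(nrow(m)), ncol(m)), nrow(m)),
                arg_col = matrix(rep(seq_len(ncol(m)), each = nrow(m)), nrow(m)))
  } else {
    res <- patch_extremum_cpp(m, as.integer(patch_size), maximum)
  }
  structure(c(res, list(patch_size = as.integer(patch_size), type = type)),
            class = "channel_map")
}

check_patch_size <- function(patch_size) {
  if (length(patch_size) != 1L || patch_size < 1L || patch_size %% 2L == 0L)
    stop("`patch_size` must be a single odd integer >= 1", call. = FALSE)
}

#' @export
print.channel_map <- function(x, ...) {
  cat(sprintf("<channel_map> %s, patch %d, %d x %d, mean value %.4f\n",
              x$type, x$patch_size, nrow(x$values), ncol(x$values),
              mean(x$values)))
  invisible(x)
}

#' @rdname dark_channel
#' @details
#' `secondary_sparse_dark()` and `secondary_sparse_bright()` apply the
#' corresponding channel operator to its own output; the recorded extremum
#' coordinates are composed through both stages, so they point into the
#' original image (within the doubled effective patch radius).
#' @export
secondary_sparse_dark <- function(img, patch_size) {
  compose_secondary(dark_channel, img, patch_size, "secondary_dark")
}

#' @rdname dark_channel
#' @export
secondary_sparse_bright <- function(img, patch_size) {
  compose_secondary(bright_channel, img, patch_size, "secondary_bright")
}

compose_secondary <- function(op, img, patch_size, type) {
  first <- op(img, patch_size)
  second <- op(us_image(clip01(first$values)), patch_size)
  # compose the selection: the second stage's extremum sits in the first
  # stage's value grid; chase it back to the source pixel.
  idx2 <- cbind(as.vector(second$arg_row), as.vector(second$arg_col))
  arg_row <- matrix(first$arg_row[idx2], nrow(first$values))
  arg_col <- matrix(first$arg_col[idx2], nrow(first$values))
  structure(list(values = second$values, arg_row = arg_row, arg_col = arg_col,
                 patch_size = as.integer(patch_size), type = type),
            class = "channel_map")
}

#' Frozen selection operator of a channel map
#'
#' Linearizes a patch-extremum operator at its recorded argmin/argmax: each
#' output pixel becomes a linear selection of exactly one source pixel.  This
#' is the linearization used by the latent-image subproblem, where the
#' channel term becomes quadratic once the selection is frozen.
#'
#' @param chan a `channel_map` from [dark_channel()] and friends.
#' @param dim the `c(rows, cols)` of the source image the map was built from.
#' @return A sparse 0/1 matrix (class `dgCMatrix`) of dimension
#'   `prod(dim) x prod(dim)`, one unit entry per row; applying it to
#'   `as.vector(img)` reproduces `as.vector(chan$values)` exactly.
#' @export
selection_operator <- function(chan, dim) {
  if (!inherits(chan, "channel_map"))
    stop("`chan` must be a channel_map", call. = FALSE)
  if (length(dim) != 2L || any(dim(chan$values) != dim))
    stop("`dim` does not match the image the channel was computed from",
         call. = FALSE)
  n <- prod(dim)
  src <- (as.vector(chan$arg_col) - 1L) * dim[1] + as.vector(chan$arg_row)
  Matrix::sparseMatrix(i = seq_len(n), j = src, x = 1, dims = c(n, n))
}
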