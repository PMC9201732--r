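#' Mean squared error between two images
#'
#' Mean over all pixels of the squared intensity difference.
#'
#' @param a,b [us_image]s (or matrices) of identical shape.
#' @return A single non-negative number (squared intensity units).
#' @export
img_mse <- function(a, b) {
  A <- as_pixel_matrix(a); B <- as_pixel_matrix(b)
  if (any(dim(A) != dim(B))) stop("image shapes differ", call. = FALSE)
  mean((A - B)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_i^2 / MSE)` in decibels.  Identical images (MSE 0) return
#' `Inf`, the legitimate round-trip sentinel, never an error.  On the
#' internal intensity scale the peak `max_i` is 1; pass `max_i = 255` (etc.)
#' for integer-scale comparisons.
#'
#' @inheritParams img_mse
#' @param max_i peak intensity value (> 0).
#' @return PSNR in dB, possibly `Inf`.
#' @export
img_psnr <- function(a, b, max_i = 1.0) {
  if (max_i <= 0) stop("`max_i` must be positive", call. = FALSE)
  m <- img_mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(max_i^2 / m)
}

#' PSNR quality band
#'
#' Maps a PSNR value (dB) to the conventional quality bands: above 40 dB
#' excellent (very close to the original), 30--40 dB good (distortion
#' detectable but acceptable), 20--30 dB poor, below 20 dB unacceptable.
#' Boundary values go to the higher band, except exact 40 dB which is "good"
#' (excellence requires *higher than* 40 dB); so 40 -> good, 30 -> good,
#' 20 -> poor.
#'
#' @param psnr_db PSNR in dB (vectorized); `Inf` grades excellent.
#' @return Character vector over `{excellent, good, poor, unacceptable}`.
#' @export
quality_grade <- function(psnr_db) {
  ifelse(psnr_db > 40, "excellent",
         ifelse(psnr_db >= 30, "good",
                ifelse(psnr_db >= 20, "poor", "unacceptable")))
}

#' Structural similarity index
#'
#' Windowed product of luminance, contrast and structure comparisons
#' \eqn{l^\alpha c^\beta s^\gamma}, averaged over sliding windows (valid
#' positions only).  Defaults are the canonical parameterization: an 11 x 11
#' Gaussian window with \eqn{\sigma = 1.5}, stabilizers
#' \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2}, \eqn{C_3 = C_2 / 2} with
#' \eqn{L} the peak intensity, and unit exponents, under which the product
#' reduces to the standard two-term SSIM.
#'
#' SSIM is often described as lying in `[0, 1]`; negative values are
#' mathematically possible (anti-correlated structure) and are returned
#' as computed.
#'
#' @inheritParams img_mse
#' @param exponents numeric `c(alpha, beta, gamma)`.
#' @param max_i peak intensity value.
#' @param window_size odd Gaussian window side.
#' @param sigma Gaussian window standard deviation.
#' @return A single number in `[-1, 1]`.
#' @export
img_ssim <- function(a, b, exponents = c(1, 1, 1), max_i = 1.0,
                     window_size = 11L, sigma = 1.5) {
  A <- as_pixel_matrix(a); B <- as_pixel_matrix(b)
  if (any(dim(A) != dim(B))) stop("image shapes differ", call. = FALSE)
  if (min(dim(A)) < window_size)
    stop("image smaller than the SSIM window", call. = FALSE)
  if (length(exponents) != 3L || any(!is.finite(exponents)))
    stop("`exponents` must be three finite numbers", call. = FALSE)
  w <- unclass(kernel_gaussian(window_size, sigma))
  mu_a <- filter2_valid_cpp(A, w); mu_b <- filter2_valid_cpp(B, w)
  var_a <- pmax(filter2_valid_cpp(A * A, w) - mu_a^2, 0)
  var_b <- pmax(filter2_valid_cpp(B * B, w) - mu_b^2, 0)
  cov_ab <- filter2_valid_cpp(A * B, w) - mu_a * mu_b
  sd_a <- sqrt(var_a); sd_b <- sqrt(var_b)
  C1 <- (0.01 * max_i)^2; C2 <- (0.03 * max_i)^2; C3 <- C2 / 2
  l <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  cc <- (2 * sd_a * sd_b + C2) / (var_a + var_b + C2)
  s <- (cov_ab + C3) / (sd_a * sd_b + C3)
  mean(l^exponents[1] * cc^exponents[2] * s^exponents[3])
}

#' Full image-quality report
#'
#' @inheritParams img_ssim
#' @return A list of class `quality_report` with `mse`, `psnr` (dB, possibly
#'   `Inf`), `ssim` and `grade`.
#' @export
quality_report <- function(a, b, max_i = 1.0) {
  p <- img_psnr(a, b, max_i)
  structure(list(mse = img_mse(a, b), psnr = p,
                 ssim = img_ssim(a, b, max_i = max_i),
                 grade = quality_grade(p)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("  MSE %.6g | PSNR %s dB | SSIM %.4f | grade: %s\n",
              x$mse, if (is.finite(x$psnr)) sprintf("%.3f", x$psnr) else "inf",
              x$ssim, x$grade))
  invisible(x)
}
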