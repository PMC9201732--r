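# Internal Fourier helpers shared by the latent-image and kernel solves.
# All solver-side convolutions are circular on edge-tapered images; the
# direct clipped-border convolution lives in apply_blur() and the C++ layer.

fft2 <- function(x) stats::fft(x)

ifft2_real <- function(X) Re(stats::fft(X, inverse = TRUE)) / length(X)

# Optical transfer function of a small PSF: zero-pad to `dims` and circularly
# shift so the kernel center lands at (1, 1).
psf2otf <- function(kern, dims) {
  kern <- unclass(kern)
  nr <- dims[1]; nc <- dims[2]
  kr <- nrow(kern); kc <- ncol(kern)
  if (kr > nr || kc > nc)
    stop("kernel larger than image", call. = FALSE)
  big <- matrix(0, nr, nc)
  idx_r <- ((seq_len(kr) - 1L) - (kr - 1L) %/% 2L) %% nr + 1L
  idx_c <- ((seq_len(kc) - 1L) - (kc - 1L) %/% 2L) %% nc + 1L
  big[idx_r, idx_c] <- kern
  fft2(big)
}

# Circular forward differences (x = column direction, y = row direction).
grad_x <- function(m) m[, c(2:ncol(m), 1L), drop = FALSE] - m
grad_y <- function(m) m[c(2:nrow(m), 1L), , drop = FALSE] - m

otf_dx <- function(dims) {
  D <- matrix(0, dims[1], dims[2]); D[1, 1] <- -1; D[1, dims[2]] <- 1
  fft2(D)
}

otf_dy <- function(dims) {
  D <- matrix(0, dims[1], dims[2]); D[1, 1] <- -1; D[dims[1], 1] <- 1
  fft2(D)
}

# Blend the border of `m` toward its circularly blurred version with a
# raised-cosine ramp, suppressing wrap-around ringing in Fourier solves.
edge_taper <- function(m, kernel) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(kernel); kc <- ncol(kernel)
  wr <- min(max(2L, kr), floor(nr / 4))
  wc <- min(max(2L, kc), floor(nc / 4))
  if (wr < 1L || wc < 1L) return(m)
  ramp <- function(n, w) {
    a <- rep(1, n)
    t <- 0.5 * (1 - cos(pi * (seq_len(w) - 0.5) / w))
    a[seq_len(w)] <- t
    a[n + 1 - seq_len(w)] <- t
    a
  }
  alpha <- outer(ramp(nr, wr), ramp(nc, wc))
  blurred <- ifft2_real(psf2otf(kernel, c(nr, nc)) * fft2(m))
  alpha * m + (1 - alpha) * blurred
}

# Bilinear resize (center-aligned), used for the image pyramid and kernel
# upsampling.  Returns a plain matrix.
resize_bilinear <- function(m, new_nr, new_nc) {
  m <- unclass(m)
  nr <- nrow(m); nc <- ncol(m)
  if (new_nr == nr && new_nc == nc) return(m)
  interp_mat <- function(n_out, n_in) {
    if (n_in == 1L) return(matrix(1, n_out, 1))
    src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    src <- pmin(pmax(src, 1), n_in)
    lo <- pmin(floor(src), n_in - 1L)
    f <- src - lo
    W <- matrix(0, n_out, n_in)
    W[cbind(seq_len(n_out), lo)] <- W[cbind(seq_len(n_out), lo)] + (1 - f)
    W[cbind(seq_len(n_out), lo + 1L)] <- W[cbind(seq_len(n_out), lo + 1L)] + f
    W
  }
  interp_mat(new_nr, nr) %*% m %*% t(interp_mat(new_nc, nc))
}

# Fast additive-noise estimate (Immerkaer): sigma from the Laplacian
# residual, which annihilates locally linear structure.
estimate_noise_sigma <- function(m) {
  L <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  r <- filter2_valid_cpp(unclass(m), L)
  sqrt(pi / 2) * mean(abs(r)) / 6
}

# Gaussian anti-alias filter ahead of decimation by factor `sc` (< 1);
# the usual sigma = 0.5 * sqrt(1/sc^2 - 1) rule.
antialias <- function(m, sc) {
  if (sc >= 1) return(m)
  sigma <- 0.5 * sqrt(1 / sc^2 - 1)
  if (sigma < 0.3) return(m)
  k <- oddify(2 * ceiling(2 * sigma) + 1)
  conv2_clip_cpp(m, unclass(kernel_gaussian(k, sigma)))
}

# Total-variation smoothing (identity data term) by the same half-quadratic
# soft-threshold iteration as the restoration pass; used to prefilter
# speckle before kernel estimation.
tv_smooth <- function(m, lam, niter = 8L) {
  if (lam <= 0) return(m)
  dims <- dim(m)
  Dx <- otf_dx(dims); Dy <- otf_dy(dims)
  GtG <- Mod(Dx)^2 + Mod(Dy)^2
  FZ <- fft2(m)
  M <- m
  for (it in seq_len(niter)) {
    beta <- 2 * lam * 2^(it - 1)
    gx <- grad_x(M); gy <- grad_y(M)
    mag <- sqrt(gx^2 + gy^2)
    shrink <- pmax(mag - lam / (2 * beta), 0) / pmax(mag, 1e-12)
    num <- FZ + beta * (Conj(Dx) * fft2(gx * shrink) + Conj(Dy) * fft2(gy * shrink))
    M <- clip01(ifft2_real(num / (1 + beta * GtG)))
  }
  M
}

oddify <- function(k) {
  k <- max(3L, as.integer(round(k)))
  if (k %% 2L == 0L) k + 1L else k
}
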