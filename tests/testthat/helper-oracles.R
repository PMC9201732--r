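# Independent brute-force oracles used across the suite.  These are written
# as plain nested loops, deliberately sharing no code with the package
# internals they check.

# patch extremum by explicit double loop over every in-bounds patch pixel
oracle_extremum <- function(m, patch, maximum = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  r <- (patch - 1) / 2
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (ii in max(1, i - r):min(nr, i + r))
        for (jj in max(1, j - r):min(nc, j + r))
          vals <- c(vals, m[ii, jj])
      out[i, j] <- if (maximum) max(vals) else min(vals)
    }
  }
  out
}

# direct convolution with clipped borders and renormalized kernel mass
oracle_conv <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(k); kc <- ncol(k)
  rr <- (kr - 1) / 2; rc <- (kc - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0; mass <- 0
      for (a in seq_len(kr)) {
        for (b in seq_len(kc)) {
          ii <- i - (a - 1 - rr); jj <- j - (b - 1 - rc)
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
            acc <- acc + k[a, b] * m[ii, jj]
            mass <- mass + k[a, b]
          }
        }
      }
      out[i, j] <- acc / mass
    }
  }
  out
}

oracle_mse <- function(a, b) {
  acc <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a)))
      acc <- acc + (a[i, j] - b[i, j])^2
  acc / (nrow(a) * ncol(a))
}

# windowed SSIM by direct per-window statistics (Gaussian weights), valid
# windows only, canonical stabilizers, exponents (1, 1, 1)
oracle_ssim <- function(a, b, win = 11, sigma = 1.5, L = 1) {
  r <- (win - 1) / 2
  d <- outer((-r:r)^2, (-r:r)^2, "+")
  w <- exp(-d / (2 * sigma^2)); w <- w / sum(w)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2; C3 <- C2 / 2
  nr <- nrow(a); nc <- ncol(a)
  vals <- c()
  for (i in (r + 1):(nr - r)) {
    for (j in (r + 1):(nc - r)) {
      pa <- a[(i - r):(i + r), (j - r):(j + r)]
      pb <- b[(i - r):(i + r), (j - r):(j + r)]
      mua <- sum(w * pa); mub <- sum(w * pb)
      va <- max(sum(w * pa^2) - mua^2, 0)
      vb <- max(sum(w * pb^2) - mub^2, 0)
      cab <- sum(w * pa * pb) - mua * mub
      l <- (2 * mua * mub + C1) / (mua^2 + mub^2 + C1)
      cc <- (2 * sqrt(va) * sqrt(vb) + C2) / (va + vb + C2)
      s <- (cab + C3) / (sqrt(va) * sqrt(vb) + C3)
      vals <- c(vals, l * cc * s)
    }
  }
  mean(vals)
}

# normalized cross-correlation of two kernels, maximized over small integer
# shifts (kernels are identifiable only up to a translation)
aligned_ncc <- function(kt, ke, max_shift = 3) {
  pad_to <- function(k, s) {
    out <- matrix(0, s, s)
    r <- (s - nrow(k)) %/% 2
    out[r + seq_len(nrow(k)), r + seq_len(ncol(k))] <- k
    out
  }
  s <- max(nrow(kt), nrow(ke)) + 2 * max_shift
  A <- pad_to(unclass(kt), s); B <- pad_to(unclass(ke), s)
  best <- -1
  for (dr in -max_shift:max_shift) {
    for (dc in -max_shift:max_shift) {
      Bs <- matrix(0, s, s)
      sr <- seq_len(s) + dr; sc <- seq_len(s) + dc
      ok_r <- sr >= 1 & sr <= s; ok_c <- sc >= 1 & sc <= s
      Bs[ok_r, ok_c] <- B[sr[ok_r], sc[ok_c]]
      v <- sum(A * Bs) / sqrt(sum(A^2) * sum(Bs^2))
      if (is.finite(v) && v > best) best <- v
    }
  }
  best
}

random_image <- function(nr, nc) us_image(matrix(runif(nr * nc), nr, nc))
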