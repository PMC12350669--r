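# independent oracles used across test files

# quaternion-based rotation matrix (independent of the Rodrigues path)
quaternion_rotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  w <- cos(angle / 2)
  q <- a * sin(angle / 2)
  x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# naive double-loop SSIM with a Gaussian window (reference implementation)
ssim_naive <- function(a, b, sigma = 1.5) {
  r <- max(1, ceiling(3 * sigma))
  k1 <- exp(-0.5 * ((-r:r) / sigma)^2)
  k1 <- k1 / sum(k1)
  w <- outer(k1, k1)
  C1 <- 0.01^2; C2 <- 0.03^2
  nr <- nrow(a); nc <- ncol(a)
  reflect <- function(i, n) {
    while (any(bad <- i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  s <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    ri <- reflect(i + (-r:r), nr)
    for (j in seq_len(nc)) {
      cj <- reflect(j + (-r:r), nc)
      wa <- a[ri, cj]; wb <- b[ri, cj]
      ma <- sum(w * wa); mb <- sum(w * wb)
      va <- sum(w * wa^2) - ma^2; vb <- sum(w * wb^2) - mb^2
      cab <- sum(w * wa * wb) - ma * mb
      s[i, j] <- ((2 * ma * mb + C1) * (2 * cab + C2)) /
        ((ma^2 + mb^2 + C1) * (va + vb + C2))
    }
  }
  mean(s)
}

# 4x4 homogeneous affine applied to an n x 3 point matrix
apply_affine <- function(A, pts) {
  out <- cbind(pts, 1) %*% t(A)
  out[, 1:3, drop = FALSE]
}

# small axis-aligned grid helper
unit_grid <- function(n, spacing = 1, origin = c(0, 0, 0)) {
  hr_grid(rep(n, 3), origin = origin, spacing = rep(spacing, 3))
}
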