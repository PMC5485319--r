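# Independent oracles, kept deliberately naive: direct sums and explicit
# loops, sharing no code with the package internals.

# Direct nonuniform DFT: s(k) = sum_x I(x) exp(-2 pi i k . x), x centered.
oracle_nudft <- function(img, kx, ky) {
  N <- nrow(img)
  c0 <- N %/% 2
  xs <- (seq_len(N) - 1) - c0
  s <- complex(length.out = length(kx))
  for (m in seq_along(kx)) {
    ph <- exp(-2i * pi * (outer(xs * kx[m], xs * ky[m], "+")))
    s[m] <- sum(img * ph)
  }
  s
}

# Brute-force symmetric GLCM by enumerating every pixel pair at the offset.
oracle_glcm <- function(q, levels, dr, dc) {
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (c in seq_len(ncol(q))) {
      r2 <- r + dr
      c2 <- c + dc
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        P[q[r, c], q[r2, c2]] <- P[q[r, c], q[r2, c2]] + 1
        P[q[r2, c2], q[r, c]] <- P[q[r2, c2], q[r, c]] + 1
      }
    }
  }
  P / sum(P)
}

# The 13 Haralick statistics from a normalized symmetric GLCM, written as
# plain loops over the matrix entries (log base 2 for entropies, matching
# the package convention).
oracle_haralick <- function(P) {
  Ng <- nrow(P)
  px <- rowSums(P)
  py <- colSums(P)
  mx <- sum(seq_len(Ng) * px)
  my <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - my)^2 * py))
  psum <- numeric(2 * Ng)
  pdif <- numeric(Ng)
  f1 <- f5 <- f9 <- 0
  f3num <- 0
  f4 <- 0
  for (i in seq_len(Ng)) {
    for (j in seq_len(Ng)) {
      p <- P[i, j]
      f1 <- f1 + p^2
      f5 <- f5 + p / (1 + (i - j)^2)
      if (p > 0) f9 <- f9 - p * log2(p)
      f3num <- f3num + i * j * p
      f4 <- f4 + (i - mx)^2 * p
      psum[i + j] <- psum[i + j] + p
      pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
    }
  }
  f2 <- sum((0:(Ng - 1))^2 * pdif)
  f3 <- if (sx > 0 && sy > 0) (f3num - mx * my) / (sx * sy) else 0
  ks <- seq_along(psum)
  f6 <- sum(ks * psum)
  f7 <- sum((ks - f6)^2 * psum)
  f8 <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  kd <- 0:(Ng - 1)
  dmean <- sum(kd * pdif)
  f10 <- sum((kd - dmean)^2 * pdif)
  f11 <- -sum(pdif[pdif > 0] * log2(pdif[pdif > 0]))
  hxy1 <- 0
  hxy2 <- 0
  for (i in seq_len(Ng)) {
    for (j in seq_len(Ng)) {
      q <- px[i] * py[j]
      if (q > 0) {
        hxy2 <- hxy2 - q * log2(q)
        if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(q)
      }
    }
  }
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9))))
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13)
}

# min-max quantization to 1..levels, mirroring the documented convention
oracle_quantize <- function(x, levels) {
  lo <- min(x)
  hi <- max(x)
  if (hi > lo) {
    pmin(floor((x - lo) / (hi - lo) * levels) + 1L, levels)
  } else {
    array(1L, dim(x))
  }
}

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# quick small phantom slice for transform tests
test_slice <- function(seed = 1, n = 64) {
  central_slice(make_brain_phantom(seed, c(n, n, 32)))
}
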