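# Forward and adjoint Fourier transforms between images and k-space samples.
#
# The forward transform evaluates the centered nonuniform discrete Fourier
# sum  s(k) = sum_x I(x) exp(-2 pi i k . x)  with pixel indices x relative to
# the image center floor(N/2). Cartesian trajectories whose coordinates fall
# on the integer frequency grid use the FFT directly and are exact; other
# trajectories use Kaiser-Bessel gridding (oversampling 2, kernel width 8),
# accurate to well below 1e-6 relative error per sample.

new_kspace <- function(samples, trajectory) {
  stopifnot(is.matrix(samples),
            nrow(samples) == trajectory$n_samples,
            ncol(samples) == trajectory$n_readouts)
  if (!all(is.finite(Re(samples))) || !all(is.finite(Im(samples)))) {
    stop_invalid("k-space samples must be finite")
  }
  structure(list(samples = samples, trajectory = trajectory),
            class = "mri_kspace")
}

#' @export
print.mri_kspace <- function(x, ...) {
  cat("<mri_kspace> ", x$trajectory$n_readouts, " readouts x ",
      x$trajectory$n_samples, " samples (", x$trajectory$geometry, ")\n",
      sep = "")
  invisible(x)
}

# ---- gridding kernel -------------------------------------------------------

KB_OS <- 2        # grid oversampling factor
KB_WIDTH <- 8     # kernel full width in oversampled grid units

kb_beta <- function(W = KB_WIDTH, os = KB_OS) {
  pi * sqrt((W / os)^2 * (os - 0.5)^2 - 0.8)
}

# Kaiser-Bessel kernel, support |u| <= W/2; scaled Bessel avoids overflow.
kb_kernel <- function(u, W = KB_WIDTH, beta = kb_beta()) {
  t <- 1 - (2 * u / W)^2
  out <- numeric(length(u))
  ok <- t > 0
  a <- beta * sqrt(t[ok])
  out[ok] <- exp(a - beta) * besselI(a, 0, expon.scaled = TRUE) /
    besselI(beta, 0, expon.scaled = TRUE)
  out
}

# Continuous Fourier transform of the kernel; used for deapodization.
kb_ft <- function(xi, W = KB_WIDTH, beta = kb_beta()) {
  z2 <- beta^2 - (pi * W * xi)^2
  sq <- sqrt(abs(z2))
  out <- ifelse(z2 > 0, sinh(sq) / sq, sin(sq) / pmax(sq, .Machine$double.eps))
  out * W * exp(-beta) / besselI(beta, 0, expon.scaled = TRUE)
}

# Centered 2D FFT: returns S with S[i, j] = sum_x I(x) e^{-2 pi i mu.x / G},
# mu = (i,j) - 1 - floor(G/2), x centered likewise. Pure index permutation
# around stats::fft, hence exact.
cfft2 <- function(x, inverse = FALSE) {
  G <- nrow(x)
  c0 <- G %/% 2
  idx <- ((seq_len(G) - 1 + c0) %% G) + 1
  xs <- x[idx, idx, drop = FALSE]
  F <- stats::fft(xs, inverse = inverse)
  mu <- ((seq_len(G) - 1 - c0) %% G) + 1
  F[mu, mu, drop = FALSE]
}

# Inverse of cfft2's index mappings, for the adjoint path.
cfft2_adjoint <- function(F) {
  G <- nrow(F)
  c0 <- G %/% 2
  mu <- ((seq_len(G) - 1 - c0) %% G) + 1
  Fs <- matrix(0+0i, G, G)
  Fs[mu, mu] <- F
  b <- stats::fft(Fs, inverse = TRUE)
  idx <- ((seq_len(G) - 1 + c0) %% G) + 1
  bs <- matrix(0+0i, G, G)
  bs[idx, idx] <- b
  bs
}

# Centered Dirichlet kernel D(k) = sum_x exp(-2 pi i k x), x = -c0..N-1-c0.
dirichlet_kernel <- function(k, N) {
  c0 <- N %/% 2
  out <- complex(length.out = length(k))
  z <- abs(k) < 1e-14
  out[z] <- N
  kk <- k[!z]
  out[!z] <- exp(2i * pi * kk * c0) *
    (1 - exp(-2i * pi * kk * N)) / (1 - exp(-2i * pi * kk))
  out
}

# Response of the density-weighted round trip to a plane wave of frequency
# f = (fx, fy): reconstructing w * forward(e^{2 pi i f.x}) returns the wave
# scaled by  sum_k w_k |D(kx - fx) D(ky - fy)|^2 / N^2  (before the global
# reconstruction scale). Used to calibrate weights and scale in closed form.
recon_gain <- function(w, kx, ky, N, f) {
  d2 <- Mod(dirichlet_kernel(kx - f[1], N) *
            dirichlet_kernel(ky - f[2], N))^2
  sum(w * d2) / N^2
}

# Global scale for the density-compensated adjoint, chosen so that a round
# trip on a constant image preserves its mean exactly; with the calibrated
# center weights of density_weights() this also normalizes the mid-band
# response.
recon_scale <- function(trajectory, weights) {
  N <- trajectory$grid_size
  1 / recon_gain(as.vector(weights), as.vector(trajectory$kx),
                 as.vector(trajectory$ky), N, c(0, 0))
}

# TRUE if every coordinate falls on the integer grid k = m / grid_size.
on_cartesian_grid <- function(trajectory) {
  N <- trajectory$grid_size
  mx <- trajectory$kx * N
  my <- trajectory$ky * N
  max(abs(mx - round(mx)), abs(my - round(my))) < 1e-9
}

# ---- forward ---------------------------------------------------------------

#' Forward transform: image to k-space samples
#'
#' Evaluates the centered Fourier sum of the image at every trajectory
#' coordinate, in readout-major order. On-grid Cartesian trajectories use the
#' FFT (exact); non-Cartesian trajectories use Kaiser-Bessel gridding.
#'
#' @param image An `mri_image` (real or complex) with square data matching
#'   `trajectory$grid_size`.
#' @param trajectory An `mri_trajectory`.
#' @return An `mri_kspace`.
#' @export
forward_transform <- function(image, trajectory) {
  stopifnot(inherits(image, "mri_image"), inherits(trajectory, "mri_trajectory"))
  N <- trajectory$grid_size
  if (nrow(image$data) != N || ncol(image$data) != N) {
    stop_invalid("image dimensions (%d x %d) must equal trajectory grid_size (%d)",
                 nrow(image$data), ncol(image$data), N)
  }
  img <- image$data
  if (!is.complex(img)) img <- img + 0i
  if (on_cartesian_grid(trajectory)) {
    F <- cfft2(img)
    c0 <- N %/% 2
    ix <- round(trajectory$kx * N) + c0 + 1
    iy <- round(trajectory$ky * N) + c0 + 1
    s <- matrix(F[cbind(as.vector(ix), as.vector(iy))],
                trajectory$n_samples, trajectory$n_readouts)
  } else {
    s <- nufft_forward(img, as.vector(trajectory$kx),
                       as.vector(trajectory$ky))
    s <- matrix(s, trajectory$n_samples, trajectory$n_readouts)
  }
  new_kspace(s, trajectory)
}

nufft_forward <- function(img, kx, ky, os = KB_OS, W = KB_WIDTH) {
  N <- nrow(img)
  G <- os * N
  beta <- kb_beta(W, os)
  c0 <- N %/% 2
  cG <- G %/% 2
  x <- (seq_len(N) - 1) - c0
  ap <- kb_ft(x / G, W, beta)
  d <- img / outer(ap, ap)
  big <- matrix(0+0i, G, G)
  big[(cG - c0) + seq_len(N), (cG - c0) + seq_len(N)] <- d
  F <- cfft2(big)
  ux <- kx * G
  uy <- ky * G
  hw <- W / 2
  fx <- floor(ux)
  fy <- floor(uy)
  s <- complex(length.out = length(kx))
  for (jx in seq_len(W)) {
    mx <- fx - hw + jx
    wx <- kb_kernel(ux - mx, W, beta)
    ix <- ((mx + cG) %% G) + 1
    for (jy in seq_len(W)) {
      my <- fy - hw + jy
      wy <- kb_kernel(uy - my, W, beta)
      iy <- ((my + cG) %% G) + 1
      s <- s + wx * wy * F[(iy - 1) * G + ix]
    }
  }
  s
}

nufft_adjoint <- function(s, kx, ky, N, os = KB_OS, W = KB_WIDTH) {
  G <- os * N
  beta <- kb_beta(W, os)
  c0 <- N %/% 2
  cG <- G %/% 2
  ux <- kx * G
  uy <- ky * G
  hw <- W / 2
  fx <- floor(ux)
  fy <- floor(uy)
  M <- length(s)
  big_idx <- numeric(M * W * W)
  big_re <- numeric(M * W * W)
  big_im <- numeric(M * W * W)
  at <- 0L
  for (jx in seq_len(W)) {
    mx <- fx - hw + jx
    wx <- kb_kernel(ux - mx, W, beta)
    ix <- ((mx + cG) %% G) + 1
    for (jy in seq_len(W)) {
      my <- fy - hw + jy
      wy <- kb_kernel(uy - my, W, beta)
      iy <- ((my + cG) %% G) + 1
      w <- wx * wy
      rng <- at + seq_len(M)
      big_idx[rng] <- (iy - 1) * G + ix
      big_re[rng] <- w * Re(s)
      big_im[rng] <- w * Im(s)
      at <- at + M
    }
  }
  acc <- rowsum(cbind(big_re, big_im), big_idx)
  ii <- as.integer(rownames(acc))
  Fre <- numeric(G * G)
  Fim <- numeric(G * G)
  Fre[ii] <- acc[, 1]
  Fim[ii] <- acc[, 2]
  F <- matrix(complex(real = Fre, imaginary = Fim), G, G)
  b <- cfft2_adjoint(F)
  img <- b[(cG - c0) + seq_len(N), (cG - c0) + seq_len(N)]
  x <- (seq_len(N) - 1) - c0
  ap <- kb_ft(x / G, W, beta)
  img / outer(ap, ap)
}

# ---- adjoint / reconstruction ---------------------------------------------

#' Density-compensated adjoint reconstruction: samples to image
#'
#' Computes the density-weighted adjoint
#' `x(r) = scale * sum_k w(k) s(k) exp(+2 pi i k . r)`. For a fully sampled
#' on-grid Cartesian trajectory this is the exact inverse DFT. For radial and
#' spiral trajectories the ramp weights make the adjoint approximate an
#' inverse; the scale factor is the covered k-space area divided by the
#' weight sum, so a round trip on a constant image preserves its mean.
#' The returned image is complex; take the magnitude downstream.
#'
#' @param kdata An `mri_kspace`.
#' @param weights An `mri_density` computed from the same trajectory
#'   (defaults to [density_weights()] of the data's trajectory).
#' @return An `mri_image` with complex data.
#' @export
adjoint_reconstruct <- function(kdata, weights = NULL) {
  stopifnot(inherits(kdata, "mri_kspace"))
  traj <- kdata$trajectory
  if (is.null(weights)) weights <- density_weights(traj)
  stopifnot(inherits(weights, "mri_density"))
  wt <- weights$trajectory
  if (!identical(dim(weights$weights), dim(kdata$samples)) ||
      !identical(wt$geometry, traj$geometry) ||
      !isTRUE(all.equal(wt$kx, traj$kx)) ||
      !isTRUE(all.equal(wt$ky, traj$ky))) {
    stop_invalid("weights are not aligned with the k-space trajectory")
  }
  N <- traj$grid_size
  ws <- weights$weights * kdata$samples
  scale <- recon_scale(traj, weights$weights)
  if (on_cartesian_grid(traj)) {
    c0 <- N %/% 2
    ix <- round(traj$kx * N) + c0 + 1
    iy <- round(traj$ky * N) + c0 + 1
    F <- matrix(0+0i, N, N)
    F[cbind(as.vector(ix), as.vector(iy))] <- as.vector(ws)
    img <- cfft2(F, inverse = TRUE) * scale
  } else {
    img <- nufft_adjoint(as.vector(ws), as.vector(traj$kx),
                         as.vector(traj$ky), N)
    img <- img * scale
  }
  image2d(img)
}

#' Magnitude of a complex reconstruction
#'
#' @param image An `mri_image`.
#' @return An `mri_image` with non-negative real data.
#' @export
magnitude <- function(image) {
  stopifnot(inherits(image, "mri_image"))
  image2d(Mod(image$data), image$spacing)
}
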