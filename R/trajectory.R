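# Sampling trajectories for 2D k-space acquisition.
#
# Coordinates are in normalized cycles per field-of-view, each component in
# [-0.5, 0.5], with image indices centered at floor(N/2) so the Cartesian
# case coincides with the standard centered FFT. A trajectory is an ordered
# list of readouts (lines, spokes, or interleaves); readout order equals
# acquisition order.

new_trajectory <- function(geometry, kx, ky, grid_size, params = list()) {
  stopifnot(is.matrix(kx), all(dim(kx) == dim(ky)))
  if (any(abs(kx) > 0.5 + 1e-12) || any(abs(ky) > 0.5 + 1e-12)) {
    stop_invalid("trajectory coordinates must lie in [-0.5, 0.5]")
  }
  structure(list(geometry = geometry,
                 kx = kx, ky = ky,  # n_samples x n_readouts, readout-major
                 grid_size = as.integer(grid_size),
                 n_readouts = ncol(kx),
                 n_samples = nrow(kx),
                 params = params),
            class = "mri_trajectory")
}

#' @export
print.mri_trajectory <- function(x, ...) {
  cat("<mri_trajectory> ", x$geometry, ": ", x$n_readouts, " readouts x ",
      x$n_samples, " samples, grid ", x$grid_size, "\n", sep = "")
  invisible(x)
}

#' Cartesian line-by-line sampling trajectory
#'
#' Readout `i` (0-based) is the horizontal line at
#' `ky = (i - floor(n_lines/2)) / n_lines`, with `kx` sweeping
#' `(j - floor(n_samples/2)) / n_samples`. Acquisition order is line-index
#' order (most-negative `ky` first), so the central line is acquired at 50%
#' of the scan.
#'
#' @param n_lines Number of phase-encoding lines (>= 2).
#' @param n_samples Samples per line (>= 2).
#' @param grid_size Target image dimension; defaults to `n_samples`.
#' @return An `mri_trajectory`.
#' @export
make_cartesian_trajectory <- function(n_lines, n_samples = n_lines,
                                      grid_size = n_samples) {
  if (!is_count(n_lines, 2) || !is_count(n_samples, 2)) {
    stop_invalid("n_lines and n_samples must be integers >= 2")
  }
  kxv <- ((seq_len(n_samples) - 1) - n_samples %/% 2) / n_samples
  kyv <- ((seq_len(n_lines) - 1) - n_lines %/% 2) / n_lines
  kx <- matrix(kxv, nrow = n_samples, ncol = n_lines)
  ky <- matrix(kyv, nrow = n_samples, ncol = n_lines, byrow = TRUE)
  new_trajectory("cartesian", kx, ky, grid_size,
                 list(n_lines = n_lines, n_samples = n_samples))
}

#' Radial spoke sampling trajectory
#'
#' Readout `j` (0-based) is a full-diameter spoke at angle
#' `theta_j = j * pi / n_spokes`, radius sweeping
#' `(t - floor(n_samples/2)) / n_samples`; every spoke passes through the
#' k-space center.
#'
#' @param n_spokes Number of spokes (>= 1).
#' @param n_samples Samples per spoke (>= 2).
#' @param grid_size Target image dimension; defaults to `n_samples`.
#' @return An `mri_trajectory`.
#' @export
make_radial_trajectory <- function(n_spokes, n_samples = n_spokes,
                                   grid_size = n_samples) {
  if (!is_count(n_spokes, 1) || !is_count(n_samples, 2)) {
    stop_invalid("n_spokes must be >= 1 and n_samples >= 2")
  }
  theta <- (seq_len(n_spokes) - 1) * pi / n_spokes
  r <- ((seq_len(n_samples) - 1) - n_samples %/% 2) / n_samples
  kx <- outer(r, cos(theta))
  ky <- outer(r, sin(theta))
  new_trajectory("radial", kx, ky, grid_size,
                 list(n_spokes = n_spokes, n_samples = n_samples))
}

#' Archimedean spiral sampling trajectory
#'
#' Readout `j` (0-based) is the spiral
#' `k(t) = 0.5 t (cos phi, sin phi)` with
#' `phi = 2 pi n_turns t + 2 pi j / n_interleaves`, `t` in `[0, 1]` at
#' `n_samples` points; each interleave starts at the k-space center and ends
#' at the Nyquist edge `|k| = 0.5`.
#'
#' @param n_interleaves Number of interleaves (>= 1).
#' @param n_samples Samples per interleave (>= 8).
#' @param n_turns Number of spiral turns (> 0).
#' @param grid_size Target image dimension.
#' @return An `mri_trajectory`.
#' @export
make_spiral_trajectory <- function(n_interleaves, n_samples, n_turns = 8,
                                   grid_size = 256) {
  if (!is_count(n_interleaves, 1) || !is_count(n_samples, 8) ||
      !is.numeric(n_turns) || n_turns <= 0) {
    stop_invalid("need n_interleaves >= 1, n_samples >= 8, n_turns > 0")
  }
  t <- seq(0, 1, length.out = n_samples)
  kx <- matrix(0, n_samples, n_interleaves)
  ky <- matrix(0, n_samples, n_interleaves)
  for (j in seq_len(n_interleaves)) {
    phi <- 2 * pi * n_turns * t + 2 * pi * (j - 1) / n_interleaves
    kx[, j] <- 0.5 * t * cos(phi)
    ky[, j] <- 0.5 * t * sin(phi)
  }
  new_trajectory("spiral", kx, ky, grid_size,
                 list(n_interleaves = n_interleaves, n_samples = n_samples,
                      n_turns = n_turns))
}

#' Density-compensation weights for a trajectory
#'
#' Cartesian sampling is uniform, so all weights are 1. For radial and spiral
#' sampling, sample density falls off as `1/|k|`, so the ramp rule assigns
#' weight proportional to `|k|`, with each exact-center sample assigned half
#' the weight of the first non-zero radius present in the trajectory. Weights
#' are normalized so their sum equals the number of samples.
#'
#' @param trajectory An `mri_trajectory`.
#' @return An object of class `mri_density` with field `weights`
#'   (an `n_samples` x `n_readouts` matrix) and the trajectory.
#' @export
density_weights <- function(trajectory) {
  stopifnot(inherits(trajectory, "mri_trajectory"))
  radius <- sqrt(trajectory$kx^2 + trajectory$ky^2)
  if (trajectory$geometry == "cartesian") {
    w <- matrix(1, nrow(radius), ncol(radius))
  } else {
    w <- radius
    zero <- radius < 1e-12
    if (any(zero) && any(!zero)) {
      # Every spoke/interleave passes through k = 0, so the center is
      # sampled once per readout. The ramp fixes the relative weights of
      # all non-center samples; the joint weight of the center samples is
      # the one free parameter and is chosen so that the reconstruction
      # responds to a constant image exactly as it does to mid-band
      # content (see recon_gain): a fixed half-ring weight per duplicate
      # over-weights the center and brightens reconstructions.
      N <- trajectory$grid_size
      kxv <- as.vector(trajectory$kx)
      kyv <- as.vector(trajectory$ky)
      band <- vapply(list(c(0.2173, 0.1292), c(-0.1354, 0.2711),
                          c(0.3082, -0.0709)),
                     function(f) recon_gain(w, kxv, kyv, N, f), 0)
      dc_nc <- recon_gain(w, kxv, kyv, N, c(0, 0))
      total <- (mean(band) - dc_nc) * N^2 / N^4
      w[zero] <- max(total, 0) / sum(zero)
    } else if (all(zero)) {
      w[] <- 1
    }
    w <- w * (length(w) / sum(w))
  }
  structure(list(weights = w, trajectory = trajectory),
            class = "mri_density")
}

#' Serialize a trajectory (and optional k-space data) to JSON
#'
#' @param trajectory An `mri_trajectory`.
#' @param path Output path.
#' @param kdata Optional `mri_kspace` whose samples are stored alongside.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, kdata = NULL) {
  obj <- list(geometry = trajectory$geometry,
              grid_size = trajectory$grid_size,
              params = trajectory$params,
              n_readouts = trajectory$n_readouts,
              n_samples = trajectory$n_samples,
              kx = as.vector(trajectory$kx),
              ky = as.vector(trajectory$ky))
  if (!is.null(kdata)) {
    obj$samples_re <- as.vector(Re(kdata$samples))
    obj$samples_im <- as.vector(Im(kdata$samples))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized trajectory from JSON
#'
#' @param path Path written by [write_trajectory()].
#' @return A list with elements `trajectory` and (if stored) `kdata`.
#' @export
read_trajectory <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kx <- matrix(obj$kx, obj$n_samples, obj$n_readouts)
  ky <- matrix(obj$ky, obj$n_samples, obj$n_readouts)
  traj <- new_trajectory(obj$geometry, kx, ky, obj$grid_size,
                         as.list(obj$params))
  out <- list(trajectory = traj)
  if (!is.null(obj$samples_re)) {
    s <- matrix(complex(real = obj$samples_re, imaginary = obj$samples_im),
                obj$n_samples, obj$n_readouts)
    out$kdata <- new_kspace(s, traj)
  }
  out
}
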