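# Motion models and k-space artefact synthesis.
#
# Bulk motion is a sudden rigid-body repositioning: part of the k-space of
# the still subject is exchanged for the k-space of the rigidly moved
# subject, whole readouts at a time. Respiratory motion is a sinusoidal
# superior-inferior heart translation: successive readouts come from volumes
# at successive positions in the breathing cycle.

#' Construct a rigid 6-DOF transform
#'
#' @param rotation Three rotation angles in degrees about the x, y, z axes,
#'   applied about the volume center in x-then-y-then-z order.
#' @param translation 3D translation vector in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  rotation <- as.double(rotation)
  translation <- as.double(translation)
  if (length(rotation) != 3 || length(translation) != 3 ||
      !all(is.finite(c(rotation, translation)))) {
    stop_invalid("rotation and translation must be finite length-3 vectors")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rot (deg):", format(x$rotation, digits = 4),
      " trans (mm):", format(x$translation, digits = 4), "\n")
  invisible(x)
}

rotation_matrix <- function(deg) {
  a <- deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

# Trilinear interpolation of a 3D array at fractional voxel positions
# (1-based continuous indices); out-of-field positions return `fill`.
trilinear_sample <- function(arr, xi, yi, zi, fill = 0) {
  d <- dim(arr)
  out <- rep(fill, length(xi))
  ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  if (!any(ok)) return(out)
  x <- xi[ok]; y <- yi[ok]; z <- zi[ok]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  ix <- function(a, b, cc) ((cc - 1) * d[2] + (b - 1)) * d[1] + a
  v000 <- arr[ix(x0, y0, z0)];     v100 <- arr[ix(x0 + 1, y0, z0)]
  v010 <- arr[ix(x0, y0 + 1, z0)]; v110 <- arr[ix(x0 + 1, y0 + 1, z0)]
  v001 <- arr[ix(x0, y0, z0 + 1)]; v101 <- arr[ix(x0 + 1, y0, z0 + 1)]
  v011 <- arr[ix(x0, y0 + 1, z0 + 1)]
  v111 <- arr[ix(x0 + 1, y0 + 1, z0 + 1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

voxel_grid_mm <- function(shape, spacing) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  list(
    x = (rep(seq_len(nx), times = ny * nz) - cx) * spacing[1],
    y = (rep(rep(seq_len(ny), each = nx), times = nz) - cy) * spacing[2],
    z = (rep(seq_len(nz), each = nx * ny) - cz) * spacing[3],
    center = c(cx, cy, cz)
  )
}

#' Resample a volume under a rigid transform
#'
#' Applies rotation about the volume center followed by translation, using
#' trilinear interpolation; regions mapped from outside the field of view are
#' filled with 0.
#'
#' @param volume An `mri_volume`.
#' @param transform A `rigid_transform`.
#' @return An `mri_volume` of the same shape.
#' @export
rigid_transform_volume <- function(volume, transform) {
  stopifnot(inherits(volume, "mri_volume"), inherits(transform, "rigid_transform"))
  shape <- dim(volume$data)
  sp <- volume$spacing
  g <- voxel_grid_mm(shape, sp)
  # inverse map: source = R^-1 (target - t), in mm about the center
  Rinv <- t(rotation_matrix(transform$rotation))
  tx <- g$x - transform$translation[1]
  ty <- g$y - transform$translation[2]
  tz <- g$z - transform$translation[3]
  sx <- Rinv[1, 1] * tx + Rinv[1, 2] * ty + Rinv[1, 3] * tz
  sy <- Rinv[2, 1] * tx + Rinv[2, 2] * ty + Rinv[2, 3] * tz
  sz <- Rinv[3, 1] * tx + Rinv[3, 2] * ty + Rinv[3, 3] * tz
  xi <- sx / sp[1] + g$center[1]
  yi <- sy / sp[2] + g$center[2]
  zi <- sz / sp[3] + g$center[3]
  out <- trilinear_sample(volume$data, xi, yi, zi)
  volume3d(array(out, shape), sp)
}

#' Draw a random bulk-motion transform
#'
#' Each translation component is uniform in `[-b, b]` with
#' `b = max_translation_mm`; if the resulting vector norm exceeds the bound,
#' the vector is rescaled onto it, so the displacement of the origin never
#' exceeds `max_translation_mm`. Each rotation angle is uniform in
#' `[-max_rotation_deg, max_rotation_deg]`. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param max_translation_mm Translation bound in mm (default 3.64).
#' @param max_rotation_deg Rotation bound in degrees (default 5).
#' @return A `rigid_transform`.
#' @export
sample_bulk_transform <- function(seed, max_translation_mm = 3.64,
                                  max_rotation_deg = 5) {
  if (max_translation_mm < 0 || max_rotation_deg < 0) {
    stop_invalid("motion bounds must be non-negative")
  }
  with_seed(derive_seed(seed, 303), {
    tr <- runif(3, -max_translation_mm, max_translation_mm)
    nrm <- sqrt(sum(tr^2))
    if (nrm > max_translation_mm && nrm > 0) {
      tr <- tr * (max_translation_mm / nrm)
    }
    rot <- runif(3, -max_rotation_deg, max_rotation_deg)
    rigid_transform(rot, tr)
  })
}

#' Construct a motion schedule
#'
#' @param assignment Integer vector mapping each readout (in acquisition
#'   order) to a 0-based motion-state index; state 0 is rest.
#' @param n_states Number of distinct motion states.
#' @return An object of class `motion_schedule`.
#' @export
motion_schedule <- function(assignment, n_states) {
  assignment <- as.integer(assignment)
  if (any(assignment < 0) || any(assignment >= n_states)) {
    stop_invalid("state indices must lie in [0, n_states)")
  }
  structure(list(assignment = assignment, n_states = as.integer(n_states)),
            class = "motion_schedule")
}

# round half away from zero; reproduces "2/256 of the scan -> two lines"
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Rectangular-pulse bulk-motion schedule
#'
#' The subject moves to a second position after `offset_fraction` of the
#' acquisition and returns after a further `exchange_fraction`: readouts with
#' 0-based index in `[round(offset * n), round(offset * n) + round(exchange * n))`
#' are in state 1 (moved), all others in state 0. Rounding is half away from
#' zero, so a fraction of `2/256` over 256 readouts marks exactly two lines.
#'
#' @param n_readouts Number of readouts in the trajectory.
#' @param offset_fraction Fraction of the scan completed before motion starts.
#' @param exchange_fraction Fraction of the scan spent in the moved state.
#' @return A `motion_schedule` with two states.
#' @export
bulk_schedule <- function(n_readouts, offset_fraction, exchange_fraction) {
  if (!is_count(n_readouts, 1)) stop_invalid("n_readouts must be >= 1")
  if (offset_fraction < 0 || offset_fraction > 1 ||
      exchange_fraction < 0 || exchange_fraction > 1 ||
      offset_fraction + exchange_fraction > 1 + 1e-12) {
    stop_invalid("fractions must lie in [0, 1] with offset + exchange <= 1")
  }
  start <- round_half_away(offset_fraction * n_readouts)
  len <- round_half_away(exchange_fraction * n_readouts)
  a <- integer(n_readouts)
  if (len > 0) {
    idx <- seq(start, min(start + len - 1, n_readouts - 1))
    a[idx + 1] <- 1L
  }
  motion_schedule(a, 2L)
}

#' Sinusoidal respiratory model
#'
#' @param n_cycles Breathing cycles completed during one acquisition.
#' @param max_displacement_mm Peak superior heart translation in mm
#'   (default 7).
#' @param n_states Number of quantized displacement levels (default 8).
#' @return An object of class `respiratory_model`.
#' @export
respiratory_model <- function(n_cycles = 4, max_displacement_mm = 7,
                              n_states = 8) {
  if (n_cycles < 0 || max_displacement_mm < 0 || !is_count(n_states, 1)) {
    stop_invalid("need n_cycles >= 0, max_displacement_mm >= 0, n_states >= 1")
  }
  structure(list(n_cycles = n_cycles,
                 max_displacement_mm = max_displacement_mm,
                 n_states = as.integer(n_states)),
            class = "respiratory_model")
}

#' Respiratory motion schedule from the sinusoidal model
#'
#' The continuous displacement at readout `t` (0-based) is
#' `d(t) = max * (1 - cos(2 pi n_cycles t / n_readouts)) / 2`, ranging from 0
#' (full inhale, rest position) to `max` (full exhale). Displacements are
#' quantized to `n_states` equispaced levels; the schedule maps each readout
#' to its level.
#'
#' @param n_readouts Number of readouts.
#' @param model A `respiratory_model`.
#' @return A list with `schedule` (a `motion_schedule`) and `displacements`
#'   (mm per state, state 0 first).
#' @export
respiratory_schedule <- function(n_readouts, model) {
  stopifnot(inherits(model, "respiratory_model"))
  if (!is_count(n_readouts, 1)) stop_invalid("n_readouts must be >= 1")
  t <- seq_len(n_readouts) - 1
  d <- model$max_displacement_mm *
    (1 - cos(2 * pi * model$n_cycles * t / n_readouts)) / 2
  if (model$max_displacement_mm == 0 || model$n_cycles == 0) {
    return(list(schedule = motion_schedule(integer(n_readouts), 1L),
                displacements = 0))
  }
  ns <- model$n_states
  levels_mm <- seq(0, model$max_displacement_mm, length.out = ns)
  state <- round((d / model$max_displacement_mm) * (ns - 1))
  if (ns == 1) state <- integer(n_readouts)
  list(schedule = motion_schedule(state, ns),
       displacements = levels_mm)
}

# Iterative 6-neighborhood dilation of a logical 3D array, recording the
# iteration at which each voxel joined (0 inside the original mask).
dilate_with_distance <- function(mask, radius) {
  d <- dim(mask)
  dist <- array(Inf, d)
  dist[mask] <- 0
  cur <- mask
  if (radius > 0) {
    for (i in seq_len(radius)) {
      nb <- array(FALSE, d)
      nb[-1, , ] <- nb[-1, , ] | cur[-d[1], , ]
      nb[-d[1], , ] <- nb[-d[1], , ] | cur[-1, , ]
      nb[, -1, ] <- nb[, -1, ] | cur[, -d[2], ]
      nb[, -d[2], ] <- nb[, -d[2], ] | cur[, -1, ]
      nb[, , -1] <- nb[, , -1] | cur[, , -d[3]]
      nb[, , -d[3]] <- nb[, , -d[3]] | cur[, , -1]
      added <- nb & !cur
      dist[added] <- i
      cur <- cur | nb
    }
  }
  list(mask = cur, dist = dist)
}

#' Translate the heart region superiorly within a volume
#'
#' Inside a dilated heart mask (dilation radius =
#' `ceil(displacement in voxels) + 2`), content is resampled from the
#' position shifted inferiorly by `displacement_mm`, so the heart appears
#' moved superiorly (+z). Outside the dilated mask the volume is unchanged;
#' a linear feather over the dilation band blends the moved content into the
#' static surround to prevent seams.
#'
#' @param volume An `mri_volume`.
#' @param mask A `heart_mask` congruent with `volume`.
#' @param displacement_mm Superior displacement in mm (>= 0).
#' @return An `mri_volume`.
#' @export
translate_heart <- function(volume, mask, displacement_mm) {
  stopifnot(inherits(volume, "mri_volume"), inherits(mask, "heart_mask"))
  if (!identical(dim(volume$data), dim(mask$data))) {
    stop_invalid("mask shape does not match volume shape")
  }
  if (displacement_mm < 0) stop_invalid("displacement must be >= 0")
  if (displacement_mm == 0) return(volume)
  d <- dim(volume$data)
  dz_vox <- displacement_mm / volume$spacing[3]
  radius <- as.integer(ceiling(dz_vox)) + 2L
  dil <- dilate_with_distance(mask$data, radius)
  # feather: 1 in the original mask, falling linearly to 0 at the band edge
  w <- pmax(0, 1 - dil$dist / (radius + 1))
  w[!dil$mask] <- 0
  # shifted content: sample at z - dz (linear interpolation along z)
  z0 <- floor(dz_vox)
  fz <- dz_vox - z0
  shift_z <- function(arr, s) {
    out <- array(0, d)
    if (s < d[3]) {
      out[, , (s + 1):d[3]] <- arr[, , seq_len(d[3] - s)]
    }
    out
  }
  moved <- (1 - fz) * shift_z(volume$data, as.integer(z0)) +
    fz * shift_z(volume$data, as.integer(z0) + 1L)
  out <- (1 - w) * volume$data + w * moved
  volume3d(out, volume$spacing)
}

#' Merge k-space data from several motion states
#'
#' For each readout `r`, all samples of readout `r` are taken from
#' `states[[schedule(r) + 1]]`; exchange granularity is whole readouts
#' (lines, spokes, or interleaves).
#'
#' @param states List of `mri_kspace` objects sharing one trajectory.
#' @param schedule A `motion_schedule` whose length equals the readout count.
#' @return An `mri_kspace` on the shared trajectory.
#' @export
merge_kspace <- function(states, schedule) {
  stopifnot(inherits(schedule, "motion_schedule"), length(states) >= 1)
  traj <- states[[1]]$trajectory
  for (s in states) {
    stopifnot(inherits(s, "mri_kspace"))
    if (!isTRUE(all.equal(s$trajectory$kx, traj$kx)) ||
        !isTRUE(all.equal(s$trajectory$ky, traj$ky))) {
      stop_invalid("all k-space states must share one trajectory")
    }
  }
  if (length(schedule$assignment) != traj$n_readouts) {
    stop_invalid("schedule length (%d) must equal readout count (%d)",
                 length(schedule$assignment), traj$n_readouts)
  }
  if (max(schedule$assignment) >= length(states)) {
    stop_invalid("schedule references state %d but only %d states given",
                 max(schedule$assignment), length(states))
  }
  out <- states[[1]]$samples
  for (st in unique(schedule$assignment)) {
    if (st == 0) next
    cols <- which(schedule$assignment == st)
    out[, cols] <- states[[st + 1]]$samples[, cols]
  }
  new_kspace(out, traj)
}

#' Simulate a bulk-motion artefact on the central slice
#'
#' The five-step strategy: (1) rigid-transform the volume; (2) extract the
#' central axial slice of both volumes; (3) forward-transform both slices;
#' (4) merge the two k-spaces, exchanging the readouts acquired while the
#' subject was moved; (5) reconstruct the joint k-space by the
#' density-compensated adjoint. Both returned images are magnitude images on
#' the trajectory grid; `clean` is the reconstruction of the unmodified
#' k-space.
#'
#' @param volume An `mri_volume` whose in-plane dimensions equal the
#'   trajectory grid.
#' @param transform A `rigid_transform` describing the moved position.
#' @param trajectory An `mri_trajectory`.
#' @param offset_fraction Scan fraction completed before motion starts.
#' @param exchange_fraction Scan fraction spent in the moved position.
#' @return A list with magnitude images `clean` and `corrupted`.
#' @export
simulate_bulk_artefact <- function(volume, transform, trajectory,
                                   offset_fraction, exchange_fraction) {
  pair <- bulk_kspace_pair(volume, transform, trajectory)
  sched <- bulk_schedule(trajectory$n_readouts, offset_fraction,
                         exchange_fraction)
  reconstruct_pair(pair$clean, merge_kspace(list(pair$clean, pair$moved), sched))
}

# clean and moved k-space of the central slice; reused across schedules
bulk_kspace_pair <- function(volume, transform, trajectory) {
  moved_vol <- rigid_transform_volume(volume, transform)
  s_clean <- central_slice(volume)
  s_moved <- central_slice(moved_vol)
  list(clean = forward_transform(s_clean, trajectory),
       moved = forward_transform(s_moved, trajectory))
}

reconstruct_pair <- function(k_clean, k_corrupt) {
  w <- density_weights(k_clean$trajectory)
  list(clean = magnitude(adjoint_reconstruct(k_clean, w)),
       corrupted = magnitude(adjoint_reconstruct(k_corrupt, w)))
}

#' Simulate a respiratory-motion artefact on a cardiac volume
#'
#' Builds one heart-translated volume per quantized displacement state,
#' extracts central slices, forward-transforms each, merges them per the
#' sinusoidal respiratory schedule, and reconstructs.
#'
#' @param volume An `mri_volume`.
#' @param mask A `heart_mask` congruent with `volume`.
#' @param trajectory An `mri_trajectory`.
#' @param model A `respiratory_model`.
#' @return A list with magnitude images `clean` and `corrupted`.
#' @export
simulate_respiratory_artefact <- function(volume, mask, trajectory, model) {
  rs <- respiratory_schedule(trajectory$n_readouts, model)
  k_states <- lapply(rs$displacements, function(dmm) {
    v <- translate_heart(volume, mask, dmm)
    forward_transform(central_slice(v), trajectory)
  })
  merged <- merge_kspace(k_states, rs$schedule)
  reconstruct_pair(k_states[[1]], merged)
}
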