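test_that("rigid transform: identity, integer shift, rotation geometry", {
  v <- make_brain_phantom(1, c(48, 48, 32))
  id <- rigid_transform()
  expect_lt(max(abs(rigid_transform_volume(v, id)$data - v$data)), 1e-12)

  # pure translation by exactly one voxel in +x shifts the array by one index
  tx <- rigid_transform(translation = c(1, 0, 0) * v$spacing[1])
  out <- rigid_transform_volume(v, tx)
  expect_equal(out$data[2:48, , ], v$data[1:47, , ], tolerance = 1e-12)
  expect_true(all(out$data[1, , ] == 0))

  # 90 deg rotation about z moves an off-center cube as coordinate rotation
  cube <- array(0, c(64, 64, 16))
  cube[44:47, 31:34, 8:9] <- 1        # center ~ (45.5, 32.5, 8.5)
  vol <- volume3d(cube)
  rot <- rigid_transform(rotation = c(0, 0, 90))
  out <- rigid_transform_volume(vol, rot)
  com <- function(a) {
    w <- which(a > 0.5, arr.ind = TRUE)
    colMeans(w)
  }
  # rotation center (32.5, 32.5); source offset (13, 0) -> target offset
  # after Rz(90): (x,y) -> (-y, x), so (13, 0) -> (0, 13)
  got <- com(out$data)
  expect_lt(max(abs(got - c(32.5, 45.5, 8.5))), 1)
})

test_that("bulk transform draws respect bounds, determinism, uniform law", {
  t1 <- sample_bulk_transform(9)
  t2 <- sample_bulk_transform(9)
  expect_identical(t1, t2)
  for (s in 1:200) {
    tf <- sample_bulk_transform(s)
    expect_lte(sqrt(sum(tf$translation^2)), 3.64 * (1 + 1e-12))
    expect_true(all(abs(tf$rotation) <= 5))
  }
  angles <- vapply(1:2000, function(s) sample_bulk_transform(s)$rotation[1], 0)
  ks <- stats::ks.test(angles, "punif", -5, 5)
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_bulk_transform(1, max_translation_mm = -1),
               "non-negative")
})

test_that("bulk schedule marks the exchanged readout block exactly", {
  s <- bulk_schedule(256, 0.5, 2 / 256)
  expect_identical(which(s$assignment == 1L) - 1L, c(128L, 129L))

  expect_true(all(bulk_schedule(100, 0.3, 0)$assignment == 0L))

  s <- bulk_schedule(256, 0.2, 0.2)
  moved <- which(s$assignment == 1L) - 1L
  expect_equal(length(moved), 51)
  expect_equal(min(moved), 51)
  expect_equal(max(moved), 101)

  expect_error(bulk_schedule(256, 0.9, 0.2), "fractions")
})

test_that("respiratory schedule follows the sinusoid with quantized states", {
  m <- respiratory_model(n_cycles = 4, max_displacement_mm = 7, n_states = 8)
  rs <- respiratory_schedule(256, m)
  d <- rs$displacements[rs$schedule$assignment + 1]
  # exactly 4 maxima at the peak displacement
  peaks <- which(diff(sign(diff(d))) < 0) + 1
  t <- 0:255
  cont <- 7 * (1 - cos(2 * pi * 4 * t / 256)) / 2
  expect_equal(sum(cont == 7), 4)
  expect_equal(max(d), 7)
  # quantization error bounded by half a level step
  expect_lte(max(abs(d - cont)), 7 / 14 + 1e-12)

  rs0 <- respiratory_schedule(256, respiratory_model(n_cycles = 0))
  expect_true(all(rs0$schedule$assignment == 0L))
  expect_equal(rs0$displacements, 0)
})

test_that("translate_heart moves only the dilated mask region", {
  p <- make_cardiac_phantom(5, c(48, 48, 32))
  v <- p$volume
  m <- p$mask

  expect_identical(translate_heart(v, m, 0)$data, v$data)

  disp <- 3
  out <- translate_heart(v, m, disp)
  radius <- as.integer(ceiling(disp / v$spacing[3])) + 2L
  dil <- mrartefact:::dilate_with_distance(m$data, radius)
  expect_identical(out$data[!dil$mask], v$data[!dil$mask])

  # deep inside the mask, an integer-voxel displacement is an index shift
  ero <- mrartefact:::dilate_with_distance(!m$data, radius + 1)
  core <- !ero$mask   # voxels further than radius+1 from the mask border
  if (any(core)) {
    idx <- which(core, arr.ind = TRUE)
    idx <- idx[idx[, 3] > disp, , drop = FALSE]
    shifted <- v$data[cbind(idx[, 1], idx[, 2], idx[, 3] - disp)]
    expect_equal(out$data[idx], shifted, tolerance = 1e-12)
  }
  expect_error(translate_heart(v, heart_mask(array(TRUE, c(8, 8, 8))), 1),
               "shape")
})

test_that("merge_kspace exchanges whole readouts by schedule", {
  tr <- make_cartesian_trajectory(4, 8)
  s0 <- mrartefact:::new_kspace(matrix(1 + 0i, 8, 4), tr)
  s1 <- mrartefact:::new_kspace(matrix(2 + 0i, 8, 4), tr)

  all0 <- merge_kspace(list(s0, s1), motion_schedule(c(0, 0, 0, 0), 2))
  expect_identical(all0$samples, s0$samples)

  twin <- merge_kspace(list(s0, s0), motion_schedule(c(0, 1, 1, 0), 2))
  expect_identical(twin$samples, s0$samples)

  mix <- merge_kspace(list(s0, s1), motion_schedule(c(0, 1, 1, 0), 2))
  expect_identical(mix$samples[, c(1, 4)], s0$samples[, c(1, 4)])
  expect_identical(mix$samples[, c(2, 3)], s1$samples[, c(2, 3)])

  expect_error(merge_kspace(list(s0), motion_schedule(c(0, 1, 1, 0), 2)),
               "state")
  expect_error(merge_kspace(list(s0, s1), motion_schedule(c(0, 1), 2)),
               "length")
})

test_that("bulk artefact simulation is the documented five-step composition", {
  v <- make_brain_phantom(3, c(48, 48, 32))
  tf <- sample_bulk_transform(4)
  tr <- make_cartesian_trajectory(48, 48)
  got <- simulate_bulk_artefact(v, tf, tr, 0.25, 0.25)

  # manual composition, step by step
  moved <- rigid_transform_volume(v, tf)
  k0 <- forward_transform(central_slice(v), tr)
  k1 <- forward_transform(central_slice(moved), tr)
  sched <- bulk_schedule(48, 0.25, 0.25)
  merged <- merge_kspace(list(k0, k1), sched)
  w <- density_weights(tr)
  want_clean <- magnitude(adjoint_reconstruct(k0, w))
  want_corr <- magnitude(adjoint_reconstruct(merged, w))
  expect_identical(got$clean$data, want_clean$data)
  expect_identical(got$corrupted$data, want_corr$data)
})

test_that("zero motion leaves the reconstruction unchanged", {
  v <- make_brain_phantom(2, c(48, 48, 32))
  tf <- sample_bulk_transform(5)
  tr <- make_cartesian_trajectory(48, 48)

  r0 <- simulate_bulk_artefact(v, tf, tr, 0.3, 0)
  expect_lt(rel_l2(r0$corrupted$data, r0$clean$data), 1e-10)

  rid <- simulate_bulk_artefact(v, rigid_transform(), tr, 0.2, 0.4)
  expect_lt(rel_l2(rid$corrupted$data, rid$clean$data), 1e-10)
})

test_that("respiratory simulation: null cases and heart-ROI artefact energy", {
  p <- make_cardiac_phantom(6, c(48, 48, 32))
  tr <- make_cartesian_trajectory(48, 48)

  r0 <- simulate_respiratory_artefact(p$volume, p$mask, tr,
                                      respiratory_model(n_cycles = 0))
  expect_lt(rel_l2(r0$corrupted$data, r0$clean$data), 1e-10)

  rz <- simulate_respiratory_artefact(p$volume, p$mask, tr,
                                      respiratory_model(4, 0))
  expect_lt(rel_l2(rz$corrupted$data, rz$clean$data), 1e-10)

  # 4 cycles at 7 mm must deposit artefact energy in the heart ROI well
  # above the no-motion reconstruction error (factor frozen from a
  # reference run: observed ratio ~ 1e5 against a 1e-12 floor)
  rr <- simulate_respiratory_artefact(p$volume, p$mask, tr,
                                      respiratory_model(4, 7, 8))
  z <- dim(p$mask$data)[3] %/% 2 + 1
  roi <- p$mask$data[, , z]
  art <- sqrt(sum((rr$corrupted$data[roi] - rr$clean$data[roi])^2))
  base <- sqrt(sum((r0$corrupted$data[roi] - r0$clean$data[roi])^2))
  expect_gt(art, 100 * max(base, 1e-12))
})

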