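# Seeded synthetic phantoms and NIfTI I/O.
#
# Volumes follow a fixed axis convention: x = left-right, y =
# anterior-posterior, z = inferior-superior, so "superior" displacement is
# +z and the central axial slice is at 0-based index floor(depth/2).

AXES_CONVENTION <- "x=left-right, y=anterior-posterior, z=inferior-superior"

#' Construct a 3D volume object
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Per-axis voxel size in mm (length 3, strictly positive).
#' @return An object of class `mri_volume` with fields `data`, `spacing`,
#'   and `axes`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop_invalid("volume data must be a 3D array")
  }
  if (any(dim(data) < 8)) stop_invalid("all volume dimensions must be >= 8")
  if (!all(is.finite(data))) stop_invalid("volume intensities must be finite")
  spacing <- as.double(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop_invalid("spacing must be three strictly positive values (mm)")
  }
  structure(list(data = data, spacing = spacing, axes = AXES_CONVENTION),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  cat("<mri_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range [", format(min(x$data)), ", ",
      format(max(x$data)), "]\n", sep = "")
  invisible(x)
}

#' Construct a binary heart mask congruent with a volume
#'
#' @param data 3D logical (or 0/1) array, same shape as its parent volume.
#' @param spacing Per-axis voxel size in mm.
#' @return An object of class `heart_mask`.
#' @export
heart_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop_invalid("mask data must be a 3D array")
  }
  data <- array(as.logical(data), dim(data))
  if (!any(data)) stop_invalid("heart mask must be non-empty")
  structure(list(data = data, spacing = as.double(spacing)),
            class = "heart_mask")
}

#' Construct a 2D image object
#'
#' @param data 2D numeric or complex matrix.
#' @param spacing Per-axis pixel size in mm (length 2).
#' @return An object of class `mri_image`.
#' @export
image2d <- function(data, spacing = c(1, 1)) {
  if (!is.matrix(data)) stop_invalid("image data must be a matrix")
  if (any(dim(data) < 8)) stop_invalid("image dimensions must be >= 8")
  structure(list(data = data, spacing = as.double(spacing)),
            class = "mri_image")
}

#' @export
print.mri_image <- function(x, ...) {
  cat("<mri_image> ", paste(dim(x$data), collapse = " x "), " pixels (",
      if (is.complex(x$data)) "complex" else "real", ")\n", sep = "")
  invisible(x)
}

# Membership of grid points in a rotated ellipsoid.  cx etc. in voxel units.
ellipsoid_field <- function(X, Y, Z, cx, cy, cz, a, b, c, phi = 0) {
  dx <- X - cx
  dy <- Y - cy
  dz <- Z - cz
  if (phi != 0) {
    rx <- cos(phi) * dx + sin(phi) * dy
    ry <- -sin(phi) * dx + cos(phi) * dy
    dx <- rx
    dy <- ry
  }
  (dx / a)^2 + (dy / b)^2 + (dz / c)^2
}

# Smooth per-seed texture: low-resolution white noise trilinearly upsampled.
smooth_texture <- function(shape, coarse = 8) {
  cs <- pmax(4L, as.integer(ceiling(shape / coarse)))
  g <- array(rnorm(prod(cs)), cs)
  # upsample by linear interpolation along each axis
  up_axis <- function(arr, axis, n_out) {
    n_in <- dim(arr)[axis]
    pos <- seq(1, n_in, length.out = n_out)
    lo <- pmin(floor(pos), n_in)
    hi <- pmin(lo + 1, n_in)
    w <- pos - lo
    idx <- function(i) {
      ix <- list(seq_len(dim(arr)[1]), seq_len(dim(arr)[2]), seq_len(dim(arr)[3]))
      ix[[axis]] <- i
      do.call(`[`, c(list(arr), ix, list(drop = FALSE)))
    }
    a_lo <- idx(lo)
    a_hi <- idx(hi)
    wshape <- c(1L, 1L, 1L)
    wshape[axis] <- n_out
    warr <- array(rep(w, each = prod(dim(a_lo)[seq_len(axis - 1)])),
                  dim(a_lo))
    a_lo * (1 - warr) + a_hi * warr
  }
  for (ax in 1:3) g <- up_axis(g, ax, shape[ax])
  g
}

#' Generate a brain-like phantom volume
#'
#' Builds a head-shaped bright ellipsoid with internal detail structures
#' (lateral-ventricle-like bright lobes, a deep mid-intensity nucleus, and a
#' small dark blob) surrounded by background of almost no intensity, emulating
#' a T2-weighted head scan. All geometry is jittered per seed so distinct
#' seeds give distinct anatomy; the generator is a pure function of
#' `(seed, shape)`.
#'
#' @param seed Integer seed.
#' @param shape Integer triple of volume dimensions, each >= 32.
#' @param spacing Voxel size in mm, default 1 mm isotropic.
#' @return An `mri_volume` with intensities in `[0, 1]`.
#' @export
make_brain_phantom <- function(seed, shape = c(256, 256, 64),
                               spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 32)) {
    stop_invalid("brain phantom shape must have three dimensions, each >= 32")
  }
  with_seed(derive_seed(seed, 101), {
    nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
    X <- array(rep(seq_len(nx), times = ny * nz), shape)
    Y <- array(rep(rep(seq_len(ny), each = nx), times = nz), shape)
    Z <- array(rep(seq_len(nz), each = nx * ny), shape)

    jit <- function(lo, hi) runif(1, lo, hi)
    cx <- nx / 2 + jit(-0.02, 0.02) * nx
    cy <- ny / 2 + jit(-0.02, 0.02) * ny
    cz <- nz / 2 + jit(-0.03, 0.03) * nz
    ax <- nx * jit(0.345, 0.385)
    ay <- ny * jit(0.41, 0.45)
    az <- nz * jit(0.40, 0.45)
    phi <- jit(-0.08, 0.08)

    head <- ellipsoid_field(X, Y, Z, cx, cy, cz, ax, ay, az, phi)
    vol <- array(0, shape)
    inside <- head <= 1
    # skull shell bright rim, brain interior moderate
    vol[inside] <- 0.45
    shell <- inside & head > 0.88
    vol[shell] <- 0.8

    # lumpy cortical texture inside the head
    tex <- smooth_texture(shape, coarse = 10)
    vol[inside] <- vol[inside] + 0.06 * tex[inside]

    # lateral-ventricle-like bright lobes (CSF is bright on T2)
    for (sgn in c(-1, 1)) {
      vx <- cx + sgn * nx * jit(0.08, 0.12)
      vy <- cy + ny * jit(-0.05, 0.02)
      vz <- cz + nz * jit(-0.04, 0.04)
      vent <- ellipsoid_field(X, Y, Z, vx, vy, vz,
                              nx * jit(0.035, 0.05), ny * jit(0.09, 0.13),
                              nz * jit(0.10, 0.16), phi + sgn * jit(0.15, 0.3))
      vol[vent <= 1] <- 0.92
    }

    # deep mid-intensity nucleus
    nuc <- ellipsoid_field(X, Y, Z, cx + nx * jit(-0.03, 0.03),
                           cy + ny * jit(0.08, 0.14), cz,
                           nx * jit(0.05, 0.08), ny * jit(0.05, 0.08),
                           nz * jit(0.08, 0.14))
    vol[nuc <= 1] <- 0.62

    # small dark blob (detail structure that blurs under motion)
    blob <- ellipsoid_field(X, Y, Z, cx + nx * jit(-0.16, -0.10),
                            cy + ny * jit(-0.18, -0.10),
                            cz + nz * jit(-0.05, 0.05),
                            nx * jit(0.012, 0.02), ny * jit(0.012, 0.02),
                            nz * jit(0.03, 0.06))
    vol[blob <= 1] <- 0.06

    # magnitude-style acquisition noise over the whole volume (SNR ~ 45 for
    # tissue at 0.45), leaving the exterior at almost no intensity
    vol <- abs(vol + rnorm(length(vol), 0, 0.01))

    vol <- pmin(vol, 1)
    volume3d(vol, spacing)
  })
}

#' Generate a cardiac-like phantom volume with a heart mask
#'
#' Builds a textured torso (non-zero background, unlike the brain case)
#' containing a two-chamber heart: two ring-shaped myocardium regions around
#' brighter blood pools, emulating short-axis left and right ventricles. The
#' heart position and in-plane orientation are jittered per seed. The returned
#' mask covers the heart structure.
#'
#' @inheritParams make_brain_phantom
#' @return A list with elements `volume` (an `mri_volume`) and `mask`
#'   (a `heart_mask`).
#' @export
make_cardiac_phantom <- function(seed, shape = c(256, 256, 64),
                                 spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 32)) {
    stop_invalid("cardiac phantom shape must have three dimensions, each >= 32")
  }
  with_seed(derive_seed(seed, 202), {
    nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
    X <- array(rep(seq_len(nx), times = ny * nz), shape)
    Y <- array(rep(rep(seq_len(ny), each = nx), times = nz), shape)
    Z <- array(rep(seq_len(nz), each = nx * ny), shape)

    jit <- function(lo, hi) runif(1, lo, hi)

    # torso: broad elliptical cylinder of soft tissue with texture
    tx <- nx / 2 + jit(-0.01, 0.01) * nx
    ty <- ny / 2 + jit(-0.01, 0.01) * ny
    torso <- ((X - tx) / (0.46 * nx))^2 + ((Y - ty) / (0.40 * ny))^2
    vol <- array(0.12, shape)
    tex <- smooth_texture(shape, coarse = 12)
    vol <- vol + 0.03 * tex
    in_torso <- torso <= 1
    vol[in_torso] <- 0.32 + 0.08 * tex[in_torso]

    # heart: two ellipsoidal shells (LV round, RV smaller, adjacent),
    # jittered position/orientation within the torso
    hx <- tx + jit(-0.06, 0.06) * nx
    hy <- ty + jit(-0.06, 0.06) * ny
    hz <- nz / 2 + jit(-0.03, 0.03) * nz
    ang <- jit(0, pi)

    lv_a <- nx * jit(0.095, 0.115)
    lv_b <- ny * jit(0.095, 0.115)
    lv_c <- nz * jit(0.20, 0.26)
    lv <- ellipsoid_field(X, Y, Z, hx, hy, hz, lv_a, lv_b, lv_c, ang)

    # RV displaced along the rotated x-axis
    off <- nx * jit(0.11, 0.14)
    rx <- hx + off * cos(ang)
    ry <- hy + off * sin(ang)
    rv <- ellipsoid_field(X, Y, Z, rx, ry, hz,
                          nx * jit(0.06, 0.075), ny * jit(0.05, 0.065),
                          lv_c * 0.85, ang)

    myo <- (lv <= 1 & lv > 0.55) | (rv <= 1 & rv > 0.55)
    pool_lv <- lv <= 0.55
    pool_rv <- rv <= 0.55
    vol[myo] <- 0.5
    vol[pool_lv] <- 0.9
    vol[pool_rv] <- 0.85

    mask <- (lv <= 1) | (rv <= 1)
    # magnitude-style acquisition noise, as in the brain phantom
    vol <- abs(vol + rnorm(length(vol), 0, 0.01))
    vol <- pmin(vol, 1)
    list(volume = volume3d(vol, spacing),
         mask = heart_mask(mask, spacing))
  })
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return An `mri_volume`.
#' @export
read_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) {
                    stop_invalid("cannot read NIfTI file '%s': %s",
                                 path, conditionMessage(e))
                  })
  d <- dim(img)
  if (length(d) != 3) {
    stop_invalid("file '%s' is %dD; a 3D volume is required", path, length(d))
  }
  volume3d(array(as.double(img), d), spacing = RNifti::pixdim(img))
}

#' Write a 3D volume (or mask) to a NIfTI-1 file
#'
#' Data are stored as float32; spacing is written to the NIfTI header exactly.
#'
#' @param volume An `mri_volume` or `heart_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, c("mri_volume", "heart_mask"))) {
    stop_invalid("write_volume() needs an mri_volume or heart_mask")
  }
  data <- volume$data
  if (is.logical(data)) data <- array(as.double(data), dim(data))
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Extract the central axial slice of a volume
#'
#' The central slice is at 0-based index `floor(depth / 2)`.
#'
#' @param volume An `mri_volume`.
#' @return An `mri_image` (real-valued).
#' @export
central_slice <- function(volume) {
  stopifnot(inherits(volume, "mri_volume"))
  z <- dim(volume$data)[3] %/% 2 + 1L
  image2d(volume$data[, , z], spacing = volume$spacing[1:2])
}

#' Export a 2D image as an 8-bit PNG (visualization only)
#'
#' The image is min-max scaled to 8 bits; PNG exports are never pipeline
#' inputs.
#'
#' @param image An `mri_image` (magnitude taken if complex).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_png_slice <- function(image, path) {
  stopifnot(inherits(image, "mri_image"))
  m <- Mod(image$data)
  rng <- range(m)
  if (rng[2] > rng[1]) m <- (m - rng[1]) / (rng[2] - rng[1]) else m[] <- 0
  # transpose so image rows render as PNG rows
  png::writePNG(t(m)[nrow(t(m)):1, , drop = FALSE], path)
  invisible(path)
}
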