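# Intensity-based feature extraction inside a rectangular region of
# interest: box, line, histogram (global and patch), and Haralick texture
# features, from a frozen, randomly parameterized specification applied
# identically to every image.

#' Construct a rectangular region of interest
#'
#' @param row0,col0 0-based top-left corner.
#' @param height,width Extent in pixels (half-open rectangle).
#' @param image_shape Optional image dimensions for a bounds check.
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(row0, col0, height, width, image_shape = NULL) {
  if (row0 < 0 || col0 < 0 || height < 1 || width < 1 ||
      height * width < 16) {
    stop_invalid("ROI must be inside bounds with area >= 16 pixels")
  }
  if (!is.null(image_shape)) {
    if (row0 + height > image_shape[1] || col0 + width > image_shape[2]) {
      stop_invalid("ROI exceeds image bounds")
    }
  }
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_rect")
}

#' @export
print.roi_rect <- function(x, ...) {
  cat("<roi_rect> origin (", x$row0, ",", x$col0, "), ",
      x$height, " x ", x$width, " px\n", sep = "")
  invisible(x)
}

roi_pixels <- function(image_data, roi) {
  image_data[roi$row0 + seq_len(roi$height), roi$col0 + seq_len(roi$width),
             drop = FALSE]
}

#' Region of interest around the heart (or the full image)
#'
#' With masks: the bounding box of each subject's heart on the central axial
#' slice is computed; the maximum width and height over subjects are each
#' enlarged by `margin` in total (half on each side), and the box is centered
#' on the pooled mask centroid and clipped to the image. Without masks (the
#' head-scan case), the ROI is the full image.
#'
#' @param masks List of `heart_mask` objects, or `NULL`.
#' @param image_shape Image dimensions (rows, cols).
#' @param margin Total relative enlargement per dimension (default 0.10).
#' @return An `roi_rect`.
#' @export
compute_roi <- function(masks, image_shape, margin = 0.10) {
  if (is.null(masks) || length(masks) == 0) {
    return(roi_rect(0, 0, image_shape[1], image_shape[2], image_shape))
  }
  hs <- ws <- rs <- cs <- numeric(length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    stopifnot(inherits(m, "heart_mask"))
    z <- dim(m$data)[3] %/% 2 + 1L
    sl <- m$data[, , z]
    if (!any(sl)) stop_invalid("mask %d is empty on the central slice", i)
    rows <- which(apply(sl, 1, any))
    cols <- which(apply(sl, 2, any))
    hs[i] <- max(rows) - min(rows) + 1
    ws[i] <- max(cols) - min(cols) + 1
    cen <- which(sl, arr.ind = TRUE)
    rs[i] <- mean(cen[, 1])
    cs[i] <- mean(cen[, 2])
  }
  h <- round(max(hs) * (1 + margin))
  w <- round(max(ws) * (1 + margin))
  h <- min(h, image_shape[1])
  w <- min(w, image_shape[2])
  r0 <- round(mean(rs) - 1 - (h - 1) / 2)
  c0 <- round(mean(cs) - 1 - (w - 1) / 2)
  r0 <- max(0, min(r0, image_shape[1] - h))
  c0 <- max(0, min(c0, image_shape[2] - w))
  roi_rect(r0, c0, h, w, image_shape)
}

#' Sample a frozen set of feature specifications
#'
#' Draws the geometry of each feature uniformly subject to containment in the
#' ROI. One spec set serves an entire experiment so that feature columns are
#' comparable across images. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param roi An `roi_rect`.
#' @param counts Named counts per kind:
#'   `c(box =, line =, histogram_global =, histogram_patch =, texture =)`.
#'   Missing names default to 0.
#' @param bin_range Integer range for histogram bin counts (default
#'   `c(8, 64)`).
#' @param edge_range Patch edge-length range in pixels; default
#'   `c(4, floor(min(roi dims) / 2))`.
#' @param max_line_radius Maximum line-profile length in pixels; default
#'   `floor(min(roi dims) / 2)`.
#' @param glcm_levels Gray-level count for texture features (default 64).
#' @return An object of class `feature_spec_set`.
#' @export
sample_feature_specs <- function(seed, roi,
                                 counts = c(box = 200, line = 100,
                                            histogram_global = 25,
                                            histogram_patch = 25,
                                            texture = 1),
                                 bin_range = c(8, 64),
                                 edge_range = NULL,
                                 max_line_radius = NULL,
                                 glcm_levels = 64) {
  stopifnot(inherits(roi, "roi_rect"))
  kinds <- c("box", "line", "histogram_global", "histogram_patch", "texture")
  counts <- unlist(counts)
  full <- stats::setNames(integer(5), kinds)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0) || sum(full) == 0) {
    stop_invalid("counts must be non-negative with at least one kind > 0")
  }
  mind <- min(roi$height, roi$width)
  if (is.null(edge_range)) edge_range <- c(4, max(4, mind %/% 2))
  if (is.null(max_line_radius)) max_line_radius <- max(2, mind %/% 2)
  if (edge_range[1] > roi$height || edge_range[1] > roi$width) {
    stop_invalid("edge_range minimum exceeds ROI extent")
  }
  edge_range[2] <- min(edge_range[2], mind)
  with_seed(derive_seed(seed, 404), {
    specs <- list()
    rint <- function(lo, hi) if (hi <= lo) as.integer(lo) else
      as.integer(floor(runif(1, lo, hi + 1)))
    sample_patch <- function() {
      eh <- rint(edge_range[1], min(edge_range[2], roi$height))
      ew <- rint(edge_range[1], min(edge_range[2], roi$width))
      r0 <- rint(roi$row0, roi$row0 + roi$height - eh)
      c0 <- rint(roi$col0, roi$col0 + roi$width - ew)
      list(row0 = r0, col0 = c0, height = eh, width = ew)
    }
    for (i in seq_len(full["box"])) {
      specs[[length(specs) + 1]] <- c(list(kind = "box"), sample_patch())
    }
    for (i in seq_len(full["line"])) {
      # start uniform in the ROI; length limited by the ROI boundary along
      # the drawn direction (redraw the direction if too little room)
      for (attempt in 1:100) {
        sr <- runif(1, roi$row0, roi$row0 + roi$height - 1)
        sc <- runif(1, roi$col0, roi$col0 + roi$width - 1)
        ang <- runif(1, 0, 2 * pi)
        dr <- sin(ang); dc <- cos(ang)
        tmax <- Inf
        if (abs(dr) > 1e-12) {
          lim <- if (dr > 0) (roi$row0 + roi$height - 1 - sr) / dr
                 else (roi$row0 - sr) / dr
          tmax <- min(tmax, lim)
        }
        if (abs(dc) > 1e-12) {
          lim <- if (dc > 0) (roi$col0 + roi$width - 1 - sc) / dc
                 else (roi$col0 - sc) / dc
          tmax <- min(tmax, lim)
        }
        max_len <- min(floor(tmax) + 1, max_line_radius)
        if (max_len >= 2) {
          len <- rint(2, max_len)
          specs[[length(specs) + 1]] <- list(kind = "line", row = sr, col = sc,
                                             angle = ang, length = len)
          break
        }
      }
    }
    for (i in seq_len(full["histogram_global"])) {
      specs[[length(specs) + 1]] <- list(kind = "histogram_global",
                                         n_bins = rint(bin_range[1], bin_range[2]))
    }
    for (i in seq_len(full["histogram_patch"])) {
      specs[[length(specs) + 1]] <- c(list(kind = "histogram_patch"),
                                      sample_patch(),
                                      list(n_bins = rint(bin_range[1], bin_range[2])))
    }
    for (i in seq_len(full["texture"])) {
      specs[[length(specs) + 1]] <- list(kind = "texture", levels = glcm_levels)
    }
    structure(list(specs = specs, seed = seed, roi = roi),
              class = "feature_spec_set")
  })
}

#' @export
print.feature_spec_set <- function(x, ...) {
  kinds <- vapply(x$specs, `[[`, "", "kind")
  cat("<feature_spec_set> ", length(x$specs), " specs (",
      paste(sprintf("%s: %d", names(table(kinds)), as.integer(table(kinds))),
            collapse = ", "),
      "), ", n_feature_columns(x), " feature columns\n", sep = "")
  invisible(x)
}

feature_width <- function(kind) {
  switch(kind, box = 2L, line = 2L, histogram_global = 6L,
         histogram_patch = 6L, texture = 13L)
}

n_feature_columns <- function(specs) {
  sum(vapply(specs$specs, function(s) feature_width(s$kind), 0L))
}

#' Box features: mean and variance inside a patch
#'
#' @param image An `mri_image` (real-valued).
#' @param spec A box spec from [sample_feature_specs()].
#' @return Named numeric vector `c(mean, variance)` (population variance).
#' @export
box_features <- function(image, spec) {
  stopifnot(spec$kind == "box")
  v <- as.vector(image$data[spec$row0 + seq_len(spec$height),
                            spec$col0 + seq_len(spec$width)])
  m <- mean(v)
  c(mean = m, variance = mean((v - m)^2))
}

bilinear_at <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- pmin(pmax(floor(r), 0), nr - 2)
  c0 <- pmin(pmax(floor(c), 0), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0 + 1, c0 + 1)]
  i10 <- img[cbind(r0 + 2, c0 + 1)]
  i01 <- img[cbind(r0 + 1, c0 + 2)]
  i11 <- img[cbind(r0 + 2, c0 + 2)]
  (i00 * (1 - fr) + i10 * fr) * (1 - fc) + (i01 * (1 - fr) + i11 * fr) * fc
}

#' Line features: standard deviation and range along a profile
#'
#' The profile is sampled at unit-pixel steps from the start point along the
#' line direction, with bilinear interpolation.
#'
#' @param image An `mri_image`.
#' @param spec A line spec from [sample_feature_specs()].
#' @return Named numeric vector `c(std, range)` (population sd,
#'   max - min of the profile).
#' @export
line_features <- function(image, spec) {
  stopifnot(spec$kind == "line")
  t <- seq_len(spec$length) - 1
  r <- spec$row + t * sin(spec$angle)
  c <- spec$col + t * cos(spec$angle)
  if (any(r < 0) || any(r > nrow(image$data) - 1) ||
      any(c < 0) || any(c > ncol(image$data) - 1)) {
    stop_invalid("line profile exits the image")
  }
  p <- bilinear_at(image$data, r, c)
  m <- mean(p)
  c(std = sqrt(mean((p - m)^2)), range = max(p) - min(p))
}

#' Histogram features: six scalars from a binned intensity distribution
#'
#' A histogram with `n_bins` equal bins over `[min, max]` of the values is
#' formed (a degenerate `min == max` input puts all mass in one bin); with
#' bin centers `c_i` and normalized counts `p_i`, the six scalars are the
#' histogram mean, variance, skewness, excess kurtosis, entropy (bits), and
#' energy. Skewness and kurtosis are 0 when the variance is 0.
#'
#' @param values Numeric vector of intensities (length >= 1).
#' @param n_bins Number of bins (>= 2).
#' @return Named numeric vector
#'   `c(mean, variance, skewness, kurtosis, entropy, energy)`.
#' @export
histogram_features <- function(values, n_bins) {
  if (length(values) < 1) stop_invalid("histogram needs at least one value")
  if (!is_count(n_bins, 2)) stop_invalid("n_bins must be an integer >= 2")
  lo <- min(values); hi <- max(values)
  if (hi > lo) {
    bin <- pmin(floor((values - lo) / (hi - lo) * n_bins) + 1, n_bins)
    counts <- tabulate(bin, n_bins)
    centers <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  } else {
    counts <- c(length(values), rep(0, n_bins - 1))
    centers <- rep(lo, n_bins)
  }
  p <- counts / sum(counts)
  m <- sum(p * centers)
  v <- sum(p * (centers - m)^2)
  s <- sqrt(v)
  skew <- if (s > 0) sum(p * (centers - m)^3) / s^3 else 0
  kurt <- if (s > 0) sum(p * (centers - m)^4) / s^4 - 3 else 0
  pp <- p[p > 0]
  c(mean = m, variance = v, skewness = skew, kurtosis = kurt,
    entropy = -sum(pp * log2(pp)), energy = sum(p^2))
}

# ---- Haralick texture features --------------------------------------------

glcm_offsets <- matrix(c(0, 1,   # horizontal
                         1, 0,   # vertical
                         1, 1,   # diagonal
                         1, -1), # anti-diagonal
                       ncol = 2, byrow = TRUE)

quantize_levels <- function(x, levels) {
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    pmin(floor((x - lo) / (hi - lo) * levels) + 1L, levels)
  } else {
    array(1L, dim(x))
  }
}

glcm_matrix <- function(q, levels, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  rs <- r1[r1 + dr >= 1 & r1 + dr <= nr]
  cs <- c1[c1 + dc >= 1 & c1 + dc <= nc]
  a <- q[rs, cs, drop = FALSE]
  b <- q[rs + dr, cs + dc, drop = FALSE]
  P <- matrix(0, levels, levels)
  tab <- table(factor(a, levels = seq_len(levels)),
               factor(b, levels = seq_len(levels)))
  P <- matrix(as.numeric(tab), levels, levels)
  P <- P + t(P)          # symmetric
  P / sum(P)
}

haralick_from_glcm <- function(P) {
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mx <- sum(seq_len(Ng) * px)
  my <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - my)^2 * py))
  # p_{x+y}: k = 2..2Ng ; p_{x-y}: k = 0..Ng-1
  sums <- i + j
  diffs <- abs(i - j)
  pxy_sum <- vapply(2:(2 * Ng), function(k) sum(P[sums == k]), 0)
  pxy_dif <- vapply(0:(Ng - 1), function(k) sum(P[diffs == k]), 0)
  ent2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  asm <- sum(P^2)
  contrast <- sum((0:(Ng - 1))^2 * pxy_dif)
  correlation <- if (sx > 0 && sy > 0) {
    (sum(i * j * P) - mx * my) / (sx * sy)
  } else 0
  variance <- sum((i - mx)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  ks <- 2:(2 * Ng)
  sum_avg <- sum(ks * pxy_sum)
  sum_var <- sum((ks - sum_avg)^2 * pxy_sum)
  sum_ent <- ent2(pxy_sum)
  entropy <- ent2(P)
  kd <- 0:(Ng - 1)
  dif_avg <- sum(kd * pxy_dif)
  dif_var <- sum((kd - dif_avg)^2 * pxy_dif)
  dif_ent <- ent2(pxy_dif)
  # information measures of correlation (entropies in bits throughout)
  pxpy <- outer(px, py)
  pos <- P > 0 & pxpy > 0
  hxy1 <- -sum(P[pos] * log2(pxpy[pos]))
  hxy2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hx <- ent2(px)
  hy <- ent2(py)
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_ent, entropy = entropy,
    difference_variance = dif_var, difference_entropy = dif_ent,
    imc1 = imc1, imc2 = imc2)
}

#' Haralick texture features over an ROI
#'
#' The ROI is quantized to `levels` gray levels by min-max scaling;
#' symmetric normalized gray-level co-occurrence matrices are formed at
#' distance 1 for the four 2D adjacency directions (horizontal, vertical,
#' and both diagonals), and the 13 classical Haralick statistics are
#' computed per direction and averaged element-wise, giving rotation
#' invariance under quarter turns. Entropies use log base 2. A constant ROI
#' returns the degenerate convention (ASM 1, contrast 0, correlation 0,
#' entropies 0).
#'
#' @param image An `mri_image`.
#' @param roi An `roi_rect`.
#' @param levels Gray-level count (default 64).
#' @return Named numeric 13-vector.
#' @export
haralick_features <- function(image, roi, levels = 64) {
  stopifnot(inherits(image, "mri_image"), inherits(roi, "roi_rect"))
  if (roi$height * roi$width < 4) stop_invalid("ROI area must be >= 4")
  px <- roi_pixels(image$data, roi)
  q <- quantize_levels(px, levels)
  acc <- NULL
  for (o in seq_len(nrow(glcm_offsets))) {
    P <- glcm_matrix(q, levels, glcm_offsets[o, 1], glcm_offsets[o, 2])
    f <- haralick_from_glcm(P)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(glcm_offsets)
}

#' Extract the feature matrix for a set of images
#'
#' Each image is min-max normalized to `[0, 1]` over the ROI before
#' extraction, so features do not key on global intensity scale introduced
#' by reconstruction weights. Columns are ordered by spec order with
#' per-spec scalar expansion (box and line give 2 columns, histogram kinds
#' 6, texture 13).
#'
#' @param images List of `mri_image` objects sharing one grid.
#' @param labels Binary labels (0 = clean, 1 = artefact), one per image.
#' @param subject_ids Unique subject identifiers, one per image.
#' @param specs A `feature_spec_set`.
#' @return A `data.frame` of class `feature_matrix` with columns
#'   `subject_id`, `label`, then named feature columns.
#' @export
extract_feature_matrix <- function(images, labels, subject_ids, specs) {
  stopifnot(inherits(specs, "feature_spec_set"))
  n <- length(images)
  if (length(labels) != n || length(subject_ids) != n) {
    stop_invalid("images, labels, and subject_ids must have equal length")
  }
  if (anyDuplicated(subject_ids)) {
    stop_invalid("subject_ids must be unique (one image per subject)")
  }
  if (!all(labels %in% c(0, 1))) stop_invalid("labels must be 0 or 1")
  roi <- specs$roi
  cols <- n_feature_columns(specs)
  X <- matrix(NA_real_, n, cols)
  names_out <- character(cols)
  for (r in seq_len(n)) {
    img <- images[[r]]
    stopifnot(inherits(img, "mri_image"))
    d <- Mod(img$data)
    rpx <- roi_pixels(d, roi)
    lo <- min(rpx); hi <- max(rpx)
    d <- if (hi > lo) (d - lo) / (hi - lo) else d * 0
    norm_img <- image2d(d, img$spacing)
    at <- 1L
    for (si in seq_along(specs$specs)) {
      sp <- specs$specs[[si]]
      v <- switch(sp$kind,
        box = box_features(norm_img, sp),
        line = line_features(norm_img, sp),
        histogram_global = histogram_features(as.vector(roi_pixels(d, roi)),
                                              sp$n_bins),
        histogram_patch = histogram_features(
          as.vector(d[sp$row0 + seq_len(sp$height),
                      sp$col0 + seq_len(sp$width)]), sp$n_bins),
        texture = haralick_features(norm_img, roi, sp$levels))
      w <- length(v)
      X[r, at:(at + w - 1)] <- v
      if (r == 1) {
        names_out[at:(at + w - 1)] <- sprintf("%s%03d_%s", sp$kind, si,
                                              names(v))
      }
      at <- at + w
    }
  }
  stopifnot(all(is.finite(X)))
  out <- data.frame(subject_id = subject_ids, label = as.integer(labels),
                    X, stringsAsFactors = FALSE)
  names(out) <- c("subject_id", "label", names_out)
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Write a feature matrix to CSV
#'
#' @param matrix A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path) {
  utils::write.csv(matrix, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a feature spec set to JSON
#'
#' @param specs A `feature_spec_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_specs <- function(specs, path) {
  jsonlite::write_json(
    list(seed = specs$seed,
         roi = unclass(specs$roi),
         specs = specs$specs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
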