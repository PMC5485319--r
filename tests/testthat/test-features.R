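make_mask_with_box <- function(shape, rows, cols) {
  m <- array(FALSE, shape)
  z <- shape[3] %/% 2 + 1
  m[rows, cols, z] <- TRUE
  heart_mask(m)
}

test_that("compute_roi applies the max-box-plus-margin rule", {
  m <- make_mask_with_box(c(128, 128, 16), 10:109, 20:99)  # 100 x 80 box
  roi <- compute_roi(list(m), c(128, 128), margin = 0.10)
  expect_equal(roi$height, 110)
  expect_equal(roi$width, 88)

  roi_full <- compute_roi(NULL, c(64, 48))
  expect_equal(c(roi_full$row0, roi_full$col0, roi_full$height, roi_full$width),
               c(0, 0, 64, 48))

  # per-dimension maxima over subjects: 60x60 and 100x40 -> 110 x 66
  m1 <- make_mask_with_box(c(160, 160, 16), 50:109, 50:109)
  m2 <- make_mask_with_box(c(160, 160, 16), 30:129, 60:99)
  roi2 <- compute_roi(list(m1, m2), c(160, 160), margin = 0.10)
  expect_equal(roi2$height, 110)
  expect_equal(roi2$width, 66)
})

test_that("feature specs are deterministic, contained, and uniform", {
  roi <- roi_rect(10, 20, 60, 50)
  s1 <- sample_feature_specs(5, roi)
  s2 <- sample_feature_specs(5, roi)
  expect_identical(s1, s2)
  expect_equal(n_feature_columns <- sum(vapply(s1$specs, function(s)
    switch(s$kind, box = 2, line = 2, histogram_global = 6,
           histogram_patch = 6, texture = 13), 0)), 200 * 2 + 100 * 2 +
      25 * 6 + 25 * 6 + 13)

  for (sp in s1$specs) {
    if (sp$kind %in% c("box", "histogram_patch")) {
      expect_gte(sp$row0, roi$row0)
      expect_gte(sp$col0, roi$col0)
      expect_lte(sp$row0 + sp$height, roi$row0 + roi$height)
      expect_lte(sp$col0 + sp$width, roi$col0 + roi$width)
    }
    if (sp$kind == "line") {
      t <- sp$length - 1
      er <- sp$row + t * sin(sp$angle)
      ec <- sp$col + t * cos(sp$angle)
      expect_true(er >= roi$row0 - 1e-9 && er <= roi$row0 + roi$height - 1 + 1e-9)
      expect_true(ec >= roi$col0 - 1e-9 && ec <= roi$col0 + roi$width - 1 + 1e-9)
    }
  }

  # patch centers cover the feasible region uniformly (chi-square on a
  # coarse partition of the row coordinate of the top-left corner)
  roi_big <- roi_rect(0, 0, 80, 80)
  specs <- sample_feature_specs(11, roi_big,
                                counts = c(box = 10000),
                                edge_range = c(4, 4))
  r0s <- vapply(specs$specs, `[[`, 0, "row0")
  expect_true(all(r0s >= 0 & r0s <= 76))
  counts <- tabulate(r0s + 1, 77)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("box features match direct computation", {
  img <- image2d(matrix(2, 16, 16))
  spec <- list(kind = "box", row0 = 2, col0 = 3, height = 4, width = 5)
  expect_equal(unname(box_features(img, spec)), c(2, 0))

  img2 <- image2d(matrix(c(0, 0, 2, 2), 2, 2)[rep(1:2, 8), rep(1:2, 8)])
  spec2 <- list(kind = "box", row0 = 0, col0 = 0, height = 2, width = 2)
  expect_equal(unname(box_features(img2, spec2)), c(1, 1))

  set.seed(8)
  rimg <- matrix(stats::runif(400), 20)
  spec3 <- list(kind = "box", row0 = 3, col0 = 5, height = 7, width = 6)
  got <- box_features(image2d(rimg), spec3)
  vals <- c()
  for (r in (spec3$row0 + 1):(spec3$row0 + spec3$height)) {
    for (c in (spec3$col0 + 1):(spec3$col0 + spec3$width)) {
      vals <- c(vals, rimg[r, c])
    }
  }
  expect_equal(unname(got), c(mean(vals), mean((vals - mean(vals))^2)),
               tolerance = 1e-12)
})

test_that("line features sample the profile with bilinear interpolation", {
  img <- image2d(matrix(5, 16, 16))
  spec <- list(kind = "line", row = 2, col = 3, angle = 0.7, length = 8)
  expect_equal(unname(line_features(img, spec)), c(0, 0))

  # axis-aligned profile over 0,1,2,3
  m <- matrix(0, 16, 16)
  m[3, ] <- rep(0:15)
  spec2 <- list(kind = "line", row = 2, col = 0, angle = 0, length = 4)
  got <- line_features(image2d(m), spec2)
  expect_equal(unname(got), c(sqrt(1.25), 3), tolerance = 1e-12)

  # diagonal profile against a pointwise oracle
  set.seed(2)
  rimg <- matrix(stats::runif(400), 20)
  spec3 <- list(kind = "line", row = 3.2, col = 4.7, angle = pi / 5,
                length = 10)
  got <- line_features(image2d(rimg), spec3)
  prof <- numeric(10)
  for (i in 0:9) {
    r <- 3.2 + i * sin(pi / 5)
    c <- 4.7 + i * cos(pi / 5)
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    prof[i + 1] <- rimg[r0 + 1, c0 + 1] * (1 - fr) * (1 - fc) +
      rimg[r0 + 2, c0 + 1] * fr * (1 - fc) +
      rimg[r0 + 1, c0 + 2] * (1 - fr) * fc +
      rimg[r0 + 2, c0 + 2] * fr * fc
  }
  expect_equal(unname(got),
               c(sqrt(mean((prof - mean(prof))^2)), max(prof) - min(prof)),
               tolerance = 1e-10)
})

test_that("histogram features reproduce closed forms", {
  f <- histogram_features(rep(3.5, 100), 8)
  expect_equal(unname(f[c("variance", "skewness", "kurtosis", "entropy",
                          "energy")]), c(0, 0, 0, 0, 1))
  expect_equal(unname(f["mean"]), 3.5)

  # two equally occupied bins
  f2 <- histogram_features(c(rep(0, 50), rep(1, 50)), 2)
  expect_equal(unname(f2["entropy"]), 1)
  expect_equal(unname(f2["energy"]), 0.5)

  # eight equally occupied bins -> entropy log2(8) = 3 bits
  vals <- rep(seq(0.5, 7.5), each = 10) / 8
  f3 <- histogram_features(vals, 8)
  expect_equal(unname(f3["entropy"]), 3)

  expect_error(histogram_features(numeric(0), 8), "one value")
  expect_error(histogram_features(1:5, 1), "2")
})

test_that("haralick features match a brute-force GLCM enumeration", {
  set.seed(4)
  img <- matrix(stats::runif(16), 4, 4)
  levels <- 4
  roi <- roi_rect(0, 0, 4, 4)
  got <- haralick_features(image2d(rbind(cbind(img, img), cbind(img, img))),
                           roi_rect(0, 0, 4, 4), levels = levels)
  q <- oracle_quantize(img, levels)
  offsets <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  want <- Reduce(`+`, lapply(offsets, function(o) {
    oracle_haralick(oracle_glcm(q, levels, o[1], o[2]))
  })) / 4
  expect_equal(unname(got), want, tolerance = 1e-10)
})

test_that("constant ROI yields the degenerate haralick convention", {
  f <- haralick_features(image2d(matrix(1, 8, 8)), roi_rect(0, 0, 8, 8))
  expect_equal(unname(f["asm"]), 1)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["correlation"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  expect_true(all(is.finite(f)))
})

test_that("rotation invariance holds for averaged haralick and global
           histograms but not for patch features", {
  set.seed(6)
  img <- matrix(stats::runif(64 * 64), 64)
  rot90 <- function(m) t(m)[, nrow(m):1]
  roi <- roi_rect(0, 0, 64, 64)

  h1 <- haralick_features(image2d(img), roi)
  h2 <- haralick_features(image2d(rot90(img)), roi)
  expect_equal(h1, h2, tolerance = 1e-12)

  g1 <- histogram_features(as.vector(img), 16)
  g2 <- histogram_features(as.vector(rot90(img)), 16)
  expect_equal(g1, g2, tolerance = 1e-12)

  # an off-center patch sees different pixels after rotation
  spec <- list(kind = "box", row0 = 2, col0 = 5, height = 8, width = 8)
  b1 <- box_features(image2d(img), spec)
  b2 <- box_features(image2d(rot90(img)), spec)
  expect_false(isTRUE(all.equal(b1, b2, tolerance = 1e-8)))
})

test_that("feature matrix has spec-ordered columns and unique subjects", {
  imgs <- lapply(1:4, function(s) test_slice(s, 32))
  roi <- compute_roi(NULL, c(32, 32))
  specs <- sample_feature_specs(3, roi, counts = c(box = 10),
                                edge_range = c(4, 8))
  fm <- extract_feature_matrix(imgs, c(0, 1, 0, 1), paste0("s", 1:4), specs)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(dim(fm), c(4, 2 + 20))

  fm2 <- extract_feature_matrix(imgs, c(0, 1, 0, 1), paste0("s", 1:4), specs)
  expect_identical(fm, fm2)

  # permuting images permutes rows only
  perm <- c(3, 1, 4, 2)
  fm3 <- extract_feature_matrix(imgs[perm], c(0, 1, 0, 1)[perm],
                                paste0("s", 1:4)[perm], specs)
  expect_equal(unname(as.matrix(fm3[order(perm), -(1:2)])),
               unname(as.matrix(fm[, -(1:2)])))

  expect_error(extract_feature_matrix(imgs, c(0, 1, 0, 1),
                                      c("a", "a", "b", "c"), specs),
               "unique")
})
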