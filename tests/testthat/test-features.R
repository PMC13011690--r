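cube_case <- function(side = 5L, pad = 3L, value = 50, background = -100) {
  d <- as.integer(side + 2L * pad)
  arr <- array(background, dim = c(d, d, d))
  m <- array(FALSE, dim = c(d, d, d))
  idx <- (pad + 1L):(pad + side)
  m[idx, idx, idx] <- TRUE
  arr[m] <- value
  list(volume = image_volume(arr, c(1, 1, 1)), mask = roi_mask(m))
}

test_that("the feature catalog is stable, ordered and family-complete", {
  cat1 <- feature_catalog()
  cat2 <- feature_catalog()
  expect_identical(cat1, cat2)
  expect_identical(unique(cat1$family),
                   c("shape", "firstorder", "GLCM", "GLRLM", "GLSZM",
                     "GLDM", "NGTDM"))
  expect_identical(nrow(cat1), 64L)
  expect_false(any(duplicated(cat1$name)))
  sub <- feature_catalog(c("GLCM", "shape"))
  # catalog order is fixed regardless of the order families are requested in
  expect_identical(unique(sub$family), c("shape", "GLCM"))
  expect_error(feature_catalog("GLXM"), "unknown feature family")
})

test_that("a constant ROI has zero spread and zero texture contrast", {
  cs <- cube_case()
  f <- extract_radiomic_features(cs$volume, cs$mask)
  expect_equal(unname(f["firstorder_variance"]), 0)
  expect_equal(unname(f["firstorder_range"]), 0)
  expect_equal(unname(f["firstorder_entropy"]), 0)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_dissimilarity"]), 0)
  expect_equal(unname(f["ngtdm_contrast"]), 0)
  expect_equal(unname(f["firstorder_mean"]), 50)
  expect_equal(unname(f["firstorder_uniformity"]), 1)
})

test_that("first-order features match hand-computed values on a small ROI", {
  vals <- c(10, 20, 20, 30, 40, 40, 40, 100)
  arr <- array(0, dim = c(2, 2, 2)); arr[] <- vals
  m <- array(TRUE, dim = c(2, 2, 2))
  f <- extract_radiomic_features(image_volume(arr, c(1, 2, 3)), roi_mask(m))
  expect_equal(unname(f["firstorder_mean"]), mean(vals))
  expect_equal(unname(f["firstorder_median"]), median(vals))
  expect_equal(unname(f["firstorder_minimum"]), 10)
  expect_equal(unname(f["firstorder_maximum"]), 100)
  expect_equal(unname(f["firstorder_energy"]), sum(vals^2))
  expect_equal(unname(f["firstorder_total_energy"]), 6 * sum(vals^2))
  expect_equal(unname(f["firstorder_variance"]), mean((vals - mean(vals))^2))
  expect_equal(unname(f["firstorder_rms"]), sqrt(mean(vals^2)))
  expect_equal(unname(f["firstorder_range"]), 90)
  expect_equal(unname(f["shape_voxel_count"]), 8)
  expect_equal(unname(f["shape_volume"]), 8 * 6)
})

test_that("texture features are invariant to a constant intensity shift", {
  set.seed(5)
  arr <- array(round(rnorm(5 * 8 * 8, 50, 60)), dim = c(5, 8, 8))
  m <- array(FALSE, dim = c(5, 8, 8)); m[2:4, 2:7, 2:7] <- TRUE
  v1 <- image_volume(arr, c(1, 1, 1))
  v2 <- image_volume(arr + 100, c(1, 1, 1))
  f1 <- extract_radiomic_features(v1, roi_mask(m))
  f2 <- extract_radiomic_features(v2, roi_mask(m))
  tex <- attr(f1, "families") %in% c("GLCM", "GLRLM", "GLSZM", "GLDM", "NGTDM")
  expect_equal(f1[tex], f2[tex], tolerance = 1e-12)
  # shape is intensity-independent entirely
  expect_equal(f1[attr(f1, "families") == "shape"],
               f2[attr(f2, "families") == "shape"], tolerance = 1e-12)
})

test_that("GLCM matrices match direct pair counting on random small grids", {
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (rep in 1:6) {
    set.seed(100 + rep)
    nr <- sample(3:8, 1L); nc <- sample(3:8, 1L)
    ng <- sample(2:5, 1L)
    sl <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
    lv <- array(NA_integer_, dim = c(1L, nr, nc))
    lv[1, , ] <- sl
    for (off in offsets) {
      P <- nodebag:::glcm_from_offset(lv, ng, off[1L], off[2L])
      expect_equal(P, glcm_bruteforce(sl, ng, off[1L], off[2L]),
                   tolerance = 1e-12)
    }
  }
})

test_that("GLCM contrast separates horizontal from vertical stripes", {
  # alternating rows of two levels: horizontal neighbours agree,
  # vertical neighbours always differ by one level
  sl <- matrix(rep(c(1L, 2L), 8), 4, 4)  # column-major: rows alternate 1,2
  lv <- array(NA_integer_, dim = c(1L, 4L, 4L)); lv[1, , ] <- sl
  P_h <- nodebag:::glcm_from_offset(lv, 2L, 0L, 1L)
  P_v <- nodebag:::glcm_from_offset(lv, 2L, 1L, 0L)
  contrast <- function(P) {
    i <- row(P); j <- col(P); sum((i - j)^2 * P)
  }
  expect_identical(contrast(P_h), 0)
  expect_identical(contrast(P_v), 1)
})

test_that("GLRLM run counts match rle on a hand-built slice", {
  sl <- matrix(c(1L, 1L, 2L,
                 1L, 2L, 2L,
                 3L, 3L, 3L), 3, 3, byrow = TRUE)
  lv <- array(NA_integer_, dim = c(1L, 3L, 3L)); lv[1, , ] <- sl
  P <- nodebag:::glrlm_counts(lv, 3L, "h")  # horizontal runs (within rows)
  # rows: (1,1)(2) ; (1)(2,2) ; (3,3,3)
  want <- matrix(0, 3L, 3L)
  want[1L, 2L] <- 1; want[1L, 1L] <- 1
  want[2L, 2L] <- 1; want[2L, 1L] <- 1
  want[3L, 3L] <- 1
  expect_equal(unname(P[, 1:3]), unname(want))
})

test_that("GLSZM zones follow 8-connectivity within slices", {
  sl <- matrix(c(1L, 1L, 2L,
                 1L, 1L, 2L,
                 2L, 2L, 2L), 3, 3, byrow = TRUE)
  lv <- array(NA_integer_, dim = c(1L, 3L, 3L)); lv[1, , ] <- sl
  Z <- nodebag:::glszm_counts(lv, 2L)
  # level 1: the 2x2 block -> one zone of 4
  expect_equal(Z[1L, 4L], 1)
  expect_equal(sum(Z[1L, ]), 1)
  # level 2: the right column and bottom row connect -> one zone of 5
  expect_equal(Z[2L, 5L], 1)
  expect_equal(sum(Z[2L, ]), 1)
  # diagonal-only contact still merges under 8-connectivity
  sl2 <- matrix(c(1L, 2L,
                  2L, 1L), 2, 2, byrow = TRUE)
  lv2 <- array(NA_integer_, dim = c(1L, 2L, 2L)); lv2[1, , ] <- sl2
  Z2 <- nodebag:::glszm_counts(lv2, 2L)
  expect_equal(Z2[1L, 2L], 1)  # the two 1s touch at a corner: one zone
  expect_equal(Z2[2L, 2L], 1)
})

test_that("surface-derived shape features are accurate on spheres", {
  r_mm <- 10
  ph <- generate_phantom_case(
    grid_shape = c(25L, 25L, 25L), spacing = c(1, 1, 1),
    lesion_spec = list(list(center = c(12, 12, 12), radii = rep(r_mm, 3L),
                            intensity = 60)),
    noise_sd = 0)
  f <- extract_radiomic_features(ph$volume, ph$masks[[1L]],
                                 feature_catalog("shape"))
  true_vol <- (4 / 3) * pi * r_mm^3
  expect_lt(abs(f[["shape_volume"]] / true_vol - 1), 0.05)
  # sphericity of a sphere is 1 by definition; the meshed estimate must be
  # within 5% at this resolution
  expect_lt(abs(f[["shape_sphericity"]] - 1), 0.05)
  expect_lt(abs(f[["shape_max_3d_diameter"]] - 2 * r_mm), 1.5)
  expect_lt(abs(f[["shape_elongation"]] - 1), 0.1)
  expect_lt(abs(f[["shape_flatness"]] - 1), 0.1)
})

test_that("an elongated ellipsoid is flagged by the axis features", {
  ph <- generate_phantom_case(
    grid_shape = c(15L, 40L, 20L), spacing = c(1, 1, 1),
    lesion_spec = list(list(center = c(7, 20, 10), radii = c(4, 16, 4),
                            intensity = 60)),
    noise_sd = 0)
  f <- extract_radiomic_features(ph$volume, ph$masks[[1L]],
                                 feature_catalog("shape"))
  expect_lt(f[["shape_elongation"]], 0.5)   # minor/major axis ratio
  expect_lt(f[["shape_sphericity"]], 0.95)
  expect_gt(f[["shape_major_axis_length"]], 2 * f[["shape_minor_axis_length"]])
})

test_that("feature extraction handles degenerate ROIs without error", {
  arr <- array(-40, dim = c(3, 6, 6))
  m <- array(FALSE, dim = c(3, 6, 6)); m[2, 3, 3] <- TRUE  # single voxel
  f <- extract_radiomic_features(image_volume(arr, c(1, 1, 1)), roi_mask(m))
  expect_true(all(is.finite(f)))
  expect_equal(unname(f["shape_voxel_count"]), 1)
  # single in-plane line of voxels
  m2 <- array(FALSE, dim = c(3, 6, 6)); m2[2, 3, 2:5] <- TRUE
  f2 <- extract_radiomic_features(image_volume(arr, c(1, 1, 1)), roi_mask(m2))
  expect_true(all(is.finite(f2)))
})

test_that("extraction errors on mismatched volume and mask shapes", {
  arr <- array(0, dim = c(3, 6, 6))
  m <- array(TRUE, dim = c(3, 5, 6))
  expect_error(extract_radiomic_features(image_volume(arr, c(1, 1, 1)),
                                         roi_mask(m)),
               "shapes differ")
})

test_that("the stub deep extractor is deterministic and 512-dimensional", {
  cs <- cube_case(side = 7L, pad = 4L, value = 80)
  set.seed(31)
  noise <- array(rnorm(length(cs$volume$intensities), sd = 20),
                 dim = dim(cs$volume$intensities))
  v <- image_volume(cs$volume$intensities + noise, c(1, 1, 1))
  ks <- select_key_slices(cs$mask)
  patch <- extract_patch(v, dilate_roi_2d(cs$mask, 2), ks)
  f1 <- extract_deep_features(patch)
  f2 <- extract_deep_features(patch)
  expect_length(f1, 512L)
  expect_identical(f1, f2)
  expect_identical(names(f1)[1L], "deep001")
  expect_true(all(abs(f1) <= 1))  # tanh output
  # a different patch maps to a different vector
  patch2 <- extract_patch(cs$volume, dilate_roi_2d(cs$mask, 2), ks)
  expect_false(identical(extract_deep_features(patch2), f1))
})

test_that("the extractor contract rejects wrong output lengths", {
  cs <- cube_case()
  patch <- extract_patch(cs$volume, dilate_roi_2d(cs$mask, 2),
                         select_key_slices(cs$mask))
  bad <- structure(list(extract = function(p) numeric(10L), name = "bad",
                        deterministic = TRUE, n_features = 512L),
                   class = "deep_extractor")
  expect_error(extract_deep_features(patch, bad), "contract requires 512")
})
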