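disk_mask <- function(n = 51, r = 20) {
  c0 <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

test_that("morphology features behave on canonical shapes", {
  d <- morphology_features(disk_mask())
  expect_lt(d["radial_cv"], 0.05)
  expect_gte(d["convexity"], 0.98)
  expect_gte(d["circularity"], 0.98)
  expect_lt(d["eccentricity"], 0.2)

  # star-shaped mask is far less convex than a disk
  n <- 101; c0 <- 51
  ang <- function(i, j) atan2(i - c0, j - c0)
  rad <- function(i, j) sqrt((i - c0)^2 + (j - c0)^2)
  star <- outer(1:n, 1:n, function(i, j)
    rad(i, j) <= 20 * (1 + 0.6 * cos(5 * ang(i, j))))
  s <- morphology_features(star)
  expect_lt(s["convexity"], 0.75)
  expect_gt(s["radial_cv"], d["radial_cv"])
  expect_error(morphology_features(matrix(FALSE, 3, 3)), "empty")
})

test_that("counting morphology features are rotation invariant", {
  m <- disk_mask(41, 13)
  m[10:14, 18:30] <- TRUE                     # break the symmetry
  rot <- t(m)[ncol(m):1, ]                    # 90 degree rotation
  a <- morphology_features(m); b <- morphology_features(rot)
  for (f in c("area", "circularity", "convexity")) {
    expect_equal(unname(a[f]), unname(b[f]), tolerance = 1e-9)
  }
  for (f in c("radial_mean", "radial_sd", "radial_max", "radial_cv")) {
    expect_equal(unname(a[f]), unname(b[f]), tolerance = 1e-6)
  }
})

test_that("density features match direct statistics", {
  img <- matrix(7, 20, 20)
  mask <- disk_mask(20, 6)
  u <- density_features(img, mask, band_width = 3)
  expect_equal(unname(u["interior_sd"]), 0)
  expect_equal(unname(u["boundary_contrast"]), 0)

  img2 <- matrix(100, 41, 41)
  d <- disk_mask(41, 10)
  img2[d] <- 200
  v <- density_features(img2, d, band_width = 4)
  expect_equal(unname(v["boundary_contrast"]), 100)

  withr::with_seed(3, {
    img3 <- matrix(stats::rnorm(41 * 41, 50, 5), 41, 41)
    w <- density_features(img3, d, band_width = 4)
    vals <- img3[d]
    m <- mean(vals); s <- sd(vals)
    expect_equal(unname(w["interior_skewness"]),
                 mean((vals - m)^3) / s^3, tolerance = 1e-12)
    expect_equal(unname(w["interior_kurtosis"]),
                 mean((vals - m)^4) / s^4 - 3, tolerance = 1e-12)
  })
})

test_that("GLCM texture statistics match hand-enumerated co-occurrences", {
  const <- texture_features(matrix(5, 10, 10), NULL, levels = 8)
  expect_equal(unname(const["energy"]), 1)
  expect_equal(unname(const["contrast"]), 0)
  expect_equal(unname(const["entropy"]), 0)

  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  tf <- texture_features(cb, NULL, levels = 2, offsets = list(c(0, 1)))
  expect_equal(unname(tf["contrast"]), 1)
  expect_equal(unname(tf["energy"]), 0.5)
  expect_equal(unname(tf["correlation"]), -1)

  withr::with_seed(4, {
    q <- matrix(sample(1:4, 64, replace = TRUE), 8, 8)
    P <- mammocad:::glcm_matrix(q, 4, 1, 1)
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))
  })
})

test_that("wavelet subband energies are conservative and normalised", {
  withr::with_seed(6, {
    img <- matrix(stats::rnorm(64 * 64), 64, 64)
    w <- wavelet_features(img, levels = 2)
    fr <- w[grep("energy_frac", names(w))]
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    sub <- dwt2(img, 2)
    expect_equal(sum(vapply(sub, function(s) sum(s^2), 0)), sum(img^2),
                 tolerance = 1e-6 * sum(img^2))
  })
  wc <- wavelet_features(matrix(3, 32, 32), levels = 2)
  expect_gt(wc["wavelet_LL2_energy_frac"], 0.999)
  expect_error(wavelet_features(matrix(1, 3, 3), levels = 2), "small")
})

test_that("full extraction is deterministic, schema-aligned and documented", {
  spec <- phantom_spec(edge_case_fraction = 0)
  roi <- generate_roi(spec, "malignant", rng_seed = 9)
  seg <- segment_lesion(roi)
  f1 <- extract_all(roi, seg)
  f2 <- extract_all(roi, seg)
  expect_identical(f1$values, f2$values)
  schema <- feature_schema()
  expect_length(f1$values, length(schema$names))
  expect_named(f1$values, schema$names)

  # offset invariance except the documented translation-sensitive list
  roi_shift <- roi; roi_shift$image <- roi$image + 250
  f3 <- extract_all(roi_shift, seg)
  sens <- translation_sensitive_features(schema)
  stable <- setdiff(schema$names, sens)
  expect_equal(f1$values[stable], f3$values[stable], tolerance = 1e-6)
  expect_gt(abs(f3$values["interior_mean"] - f1$values["interior_mean"]), 100)

  # mirror invariance for orientation-agnostic categories
  roi_m <- roi
  roi_m$image <- roi$image[, ncol(roi$image):1]
  roi_m$padded_region <- roi$padded_region[, ncol(roi$image):1]
  seg_m <- seg
  seg_m$final_mask <- seg$final_mask[, ncol(roi$image):1]
  f4 <- extract_all(roi_m, seg_m)
  ortho <- schema$names[schema$categories %in% c("morphology", "density", "texture")]
  expect_equal(f1$values[ortho], f4$values[ortho], tolerance = 1e-6)
})

test_that("malignant phantoms have higher radial variability than benign", {
  spec <- phantom_spec()
  cv_of <- function(label, seeds) vapply(seeds, function(s) {
    roi <- generate_roi(spec, label, rng_seed = s)
    morphology_features(roi$truth_mask)[["radial_cv"]]
  }, 0)
  mal <- cv_of("malignant", 1:60)
  ben <- cv_of("benign", 61:120)
  expect_lt(wilcox.test(mal, ben, alternative = "greater")$p.value, 0.01)
})
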