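test_that("seed intensity is the window maximum", {
  img <- matrix(100, 5, 5)
  expect_equal(seed_intensity(img, c(3, 3), 1), 100)
  img2 <- matrix(50, 5, 5); img2[3, 3] <- 20
  expect_equal(seed_intensity(img2, c(3, 3), 0), 20)
  img3 <- matrix(50, 5, 5); img3[3, 4] <- 200
  expect_equal(seed_intensity(img3, c(3, 3), 1), 200)
  expect_error(seed_intensity(img, c(0, 3), 1), "bounds")
})

test_that("layer region is the seed's connected component with fallback", {
  img <- matrix(50, 21, 21)
  disk <- outer(1:21, 1:21, function(i, j) (i - 11)^2 + (j - 11)^2 <= 36)
  img[disk] <- 200
  expect_equal(layer_region(img, c(11, 11), 100), disk)

  # threshold above the global maximum: singleton fallback
  single <- layer_region(img, c(11, 11), 1e6)
  expect_equal(sum(single), 1)
  expect_true(single[11, 11])

  # two bright blobs: only the seeded one is returned
  img2 <- matrix(0, 30, 30)
  img2[5:10, 5:10] <- 200
  img2[20:25, 20:25] <- 200
  reg <- layer_region(img2, c(7, 7), 100)
  expect_true(all(reg[5:10, 5:10]))
  expect_false(any(reg[20:25, 20:25]))
  expect_equal(reg, bfs_flood_fill(img2 >= 100, c(7, 7), 8))
})

test_that("run-length components agree with BFS flood fill on random images", {
  withr::with_seed(42, {
    for (trial in 1:25) {
      img <- matrix(stats::runif(32 * 32), 32, 32)
      thr <- stats::runif(1, 0.3, 0.7)
      seed <- c(sample(32, 1), sample(32, 1))
      for (conn in c(4, 8)) {
        got <- layer_region(img, seed, thr, connectivity = conn)
        binary <- img >= thr
        if (binary[seed[1], seed[2]]) {
          expect_identical(got, bfs_flood_fill(binary, seed, conn))
        }
      }
    }
  })
})

test_that("boundary contour follows the exterior-4-neighbour rule", {
  sq <- matrix(TRUE, 3, 3)
  b <- boundary_contour(sq)
  expect_equal(nrow(b), 8)
  expect_false(any(b[, 1] == 2 & b[, 2] == 2))

  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_equal(unname(boundary_contour(single)), matrix(c(2, 2), 1, 2))

  plus <- matrix(FALSE, 5, 5)
  plus[3, 2:4] <- TRUE; plus[2:4, 3] <- TRUE
  got <- boundary_contour(plus)
  # brute-force oracle: a mask pixel with any 4-neighbour outside
  px <- which(plus, arr.ind = TRUE)
  oracle <- px[sapply(seq_len(nrow(px)), function(k) {
    r <- px[k, 1]; c <- px[k, 2]
    any(!c(r > 1 && plus[r - 1, c], r < 5 && plus[r + 1, c],
           c > 1 && plus[r, c - 1], c < 5 && plus[r, c + 1]))
  }), , drop = FALSE]
  expect_setequal(paste(got[, 1], got[, 2]), paste(oracle[, 1], oracle[, 2]))
  expect_error(boundary_contour(matrix(FALSE, 2, 2)), "empty")
})

test_that("layer contrast is boundary mean minus interior mean", {
  expect_equal(layer_contrast(matrix(7, 4, 4), matrix(TRUE, 4, 4)), 0)

  img <- matrix(100, 3, 3); img[2, 2] <- 200
  expect_equal(layer_contrast(img, matrix(TRUE, 3, 3)), -100)

  withr::with_seed(5, {
    img <- matrix(stats::rnorm(49), 7, 7)
    mask <- outer(1:7, 1:7, function(i, j) (i - 4)^2 + (j - 4)^2 <= 6)
    b <- boundary_contour(mask)
    bm <- matrix(FALSE, 7, 7); bm[b] <- TRUE
    oracle <- mean(img[bm]) - mean(img[mask & !bm])
    expect_equal(layer_contrast(img, mask), oracle)
  })
})

test_that("circularity is the equal-area-disk overlap fraction", {
  disk <- outer(1:51, 1:51, function(i, j) (i - 26)^2 + (j - 26)^2 <= 400)
  expect_gte(circularity(disk), 0.98)

  line <- matrix(FALSE, 5, 120); line[3, 6:105] <- TRUE
  v_line <- circularity(line)
  # brute-force oracle: count line pixels within the equal-area disk
  px <- which(line, arr.ind = TRUE)
  cen <- colMeans(px)
  r2 <- nrow(px) / pi
  oracle <- sum((px[, 1] - cen[1])^2 + (px[, 2] - cen[2])^2 <= r2) / nrow(px)
  expect_equal(v_line, oracle)
  expect_lt(v_line, 0.3)

  withr::with_seed(8, {
    for (i in 1:10) {
      m <- matrix(stats::runif(100) > 0.5, 10, 10)
      if (!sum(m)) next
      v <- circularity(m)
      expect_gt(v, 0); expect_lte(v, 1)
    }
  })
})

test_that("termination rules fire in the documented order", {
  p <- seg_params()
  expect_equal(check_termination(100, 350, 0.9, 0.9, p), "stop_size")
  expect_equal(check_termination(100, 150, 0.8, 0.3, p), "stop_circularity")
  expect_equal(check_termination(100, 150, 0.8, 0.7, p), "continue")
  # size check takes precedence when both would fire
  expect_equal(check_termination(100, 500, 0.8, 0.1, p), "stop_size")
})

test_that("segmentation recovers noise-free phantom lesions", {
  spec <- sharp_spec()
  for (s in 1:4) {
    roi <- generate_roi(spec, if (s %% 2) "benign" else "malignant",
                        rng_seed = s)
    seg <- segment_lesion(roi)
    expect_gte(dice_overlap(seg$final_mask, roi$truth_mask), 0.85)
    expect_true(seg$final_mask[roi$seed_point[1], roi$seed_point[2]])
    expect_identical(seg$final_mask, seg$layers[[seg$final_layer_index]]$mask)
  }
})

test_that("an exploding second layer returns the small first layer", {
  # small bright core with an internal gradient, surrounded by a large
  # slightly-dimmer field it would leak into at the next threshold
  img <- matrix(0, 40, 40)
  img[10:30, 10:30] <- 870
  img[19:23, 19:23] <- 910
  img[20:22, 20:22] <- 980
  img[21, 21] <- 1000
  roi <- list(image = img, seed_point = c(21, 21))
  seg <- segment_lesion(roi, seg_params(min_check_area = 1L))
  expect_equal(seg$termination_reason, "size_growth")
  expect_lte(sum(seg$final_mask), 25)
  expect_true(seg$final_mask[21, 21])
})

test_that("growth never crosses into a disjoint structure", {
  img <- matrix(1000, 60, 60)
  d1 <- outer(1:60, 1:60, function(i, j) (i - 20)^2 + (j - 20)^2 <= 64)
  d2 <- outer(1:60, 1:60, function(i, j) (i - 45)^2 + (j - 45)^2 <= 64)
  img[d1] <- 1600; img[d2] <- 1600
  roi <- list(image = img, seed_point = c(20, 20))
  seg <- segment_lesion(roi)
  expect_false(any(seg$final_mask & d2))
  expect_true(all(!seg$final_mask | d1))   # mask stays within the seeded disk
})

test_that("thresholds are non-increasing and layers nested for bright lesions", {
  roi <- generate_roi(phantom_spec(edge_case_fraction = 0), "benign",
                      rng_seed = 21)
  seg <- segment_lesion(roi)
  s <- summary(seg)
  acc <- seq_len(seg$final_layer_index)
  expect_true(all(diff(s$Tj[acc]) <= 1e-9))
  for (j in acc[-1]) {
    expect_true(all(seg$layers[[j]]$mask[seg$layers[[j - 1]]$mask]))
  }
  # final mask is one connected component
  comp <- bfs_flood_fill(seg$final_mask, seg$seed_point, 8)
  expect_identical(comp, seg$final_mask)
})

test_that("segmentation is mirror-symmetric", {
  roi <- generate_roi(phantom_spec(edge_case_fraction = 0), "malignant",
                      rng_seed = 33)
  seg <- segment_lesion(roi)
  flipped <- roi
  flipped$image <- roi$image[, ncol(roi$image):1]
  flipped$padded_region <- roi$padded_region[, ncol(roi$image):1]
  flipped$seed_point <- c(roi$seed_point[1],
                          ncol(roi$image) + 1L - roi$seed_point[2])
  seg_f <- segment_lesion(flipped)
  expect_identical(seg_f$final_mask[, ncol(roi$image):1], seg$final_mask)
})

test_that("padded pixels are excluded from growth", {
  spec_edge <- phantom_spec(edge_case_fraction = 1)
  roi <- generate_roi(spec_edge, "benign", rng_seed = 12)
  seg <- segment_lesion(roi)
  expect_false(any(seg$final_mask & roi$padded_region))
})
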