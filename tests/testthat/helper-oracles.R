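# Shared fixtures and independent oracles.

# Queue-based breadth-first flood fill: the independent oracle for
# connected-component extraction.
bfs_flood_fill <- function(binary, seed_point, connectivity = 8) {
  n <- nrow(binary); m <- ncol(binary)
  visited <- matrix(FALSE, n, m)
  if (!binary[seed_point[1], seed_point[2]]) return(visited)
  offs <- if (connectivity == 8) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  queue <- matrix(seed_point, 1, 2)
  visited[seed_point[1], seed_point[2]] <- TRUE
  while (nrow(queue) > 0) {
    p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (k in seq_len(nrow(offs))) {
      r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
      if (r >= 1 && r <= n && c >= 1 && c <= m &&
          binary[r, c] && !visited[r, c]) {
        visited[r, c] <- TRUE
        queue <- rbind(queue, c(r, c))
      }
    }
  }
  visited
}

# Noise-free sharp-margin phantom spec used for segmentation oracles.
sharp_spec <- function(...) {
  phantom_spec(background_noise_sd = 0,
               margin_blur_sigma_range = c(0.3, 0.3),
               edge_case_fraction = 0, ...)
}

# Contrast-coded, trivially separable phantom set for the surrogate
# backbone (malignant bright, benign faint).
separable_rois <- function(n_per_class = 30, seed = 5) {
  hi <- phantom_spec(lesion_contrast_range = c(800, 1000))
  lo <- phantom_spec(lesion_contrast_range = c(120, 200))
  rois <- c(generate_dataset(hi, n_per_class, 0, rng_seed = seed),
            generate_dataset(lo, 0, n_per_class, rng_seed = seed + 1,
                             id_prefix = "ben"))
  class(rois) <- "lesion_roi_set"
  rois
}

# Synthetic informative feature table (no imaging) for classifier tests.
gaussian_feature_df <- function(n = 400, p = 20, shift = 1.5, seed = 1) {
  withr::with_seed(seed, {
    labs <- rep(c("malignant", "benign"), length.out = n)
    x <- matrix(stats::rnorm(n * p), n, p)
    x[labs == "malignant", 1:3] <- x[labs == "malignant", 1:3] + shift
    df <- data.frame(sample_id = sprintf("s%04d", seq_len(n)), label = labs,
                     x, stringsAsFactors = FALSE)
    df
  })
}

random_score_table <- function(n = 40, seed = 1, model_id = "m") {
  withr::with_seed(seed, {
    labs <- sample(rep(c("malignant", "benign"), length.out = n))
    score_table(sprintf("s%03d", seq_len(n)), model_id,
                rep_len(1:4, n), labs, stats::runif(n))
  })
}

# Shared heavyweight end-to-end run, computed once per test session.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_model_i_run <- function() {
  if (is.null(.acceptance_cache$model_i)) {
    spec <- phantom_spec()
    rois <- generate_dataset(spec, 200, 200, rng_seed = 20260928L)
    segs <- lapply(rois, segment_lesion)
    feats <- suppressWarnings(extract_features_dataset(rois, segs = segs))
    folds <- make_folds(roi_labels(rois), k = 10, rng_seed = 77,
                        sample_ids = roi_ids(rois))
    s1 <- suppressMessages(
      suppressWarnings(cross_validated_scores(feats, folds = folds)))
    .acceptance_cache$model_i <- list(rois = rois, segs = segs,
                                      feats = feats, folds = folds, s1 = s1)
  }
  .acceptance_cache$model_i
}
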