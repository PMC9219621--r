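# Synthetic mammogram-like lesion phantoms.
#
# Each phantom is a bright soft-tissue-mass-like blob on a correlated-noise
# background.  The lesion radial profile is a gently drooping dome (4%
# centre-to-edge droop) with a raised-cosine shoulder falling from 96% of
# the core contrast to zero over 12% of the lesion radius; the shoulder is
# then diffused by a Gaussian margin blur.  Benign lesions are smooth
# ellipses; malignant lesions add low-order harmonic boundary perturbation
# and thin radial spicules of decaying contrast.  Lesions are BRIGHTER
# than the background (processed-FFDM convention, fixed package-wide).

DOME_DROOP <- 0.04       # relative contrast droop at the lesion edge
SHOULDER_FRAC <- 0.12    # raised-cosine falloff width, fraction of radius
SPICULE_PEAK <- 0.75     # spicule base contrast, fraction of core contrast

#' Specification of the phantom generator
#'
#' Defaults describe the study conditions used throughout the package:
#' 150x150 16-bit patches at an implied 0.35 mm pixel scale, background
#' level 1000 with correlated noise (sd 40, correlation scale 3 px --
#' a contrast-to-noise ratio of roughly 7-20, consistent with mass
#' lesions on pixel-averaged FFDM),
#' lesion radii 12-30 px, core contrasts 300-800, margin blur 0.5-2.5 px,
#' 4-10 spicules and 25% harmonic radius perturbation for malignant
#' lesions, and 10% of lesions abutting a zero-padded patch border.
#'
#' @param patch_size patch side in pixels
#' @param background_mean background intensity level
#' @param background_noise_sd standard deviation of the background texture
#' @param background_correlation_sigma Gaussian low-pass scale of the
#'   background texture, pixels
#' @param lesion_radius_range range (min, max) of lesion radii, pixels
#' @param lesion_contrast_range range of lesion core contrast (lesion core
#'   minus background mean)
#' @param margin_blur_sigma_range range of the Gaussian margin blur sigma,
#'   pixels (small = solid margin, large = diffuse margin)
#' @param n_spicules_range range of spicule counts (malignant only)
#' @param radius_perturbation_amp RMS amplitude of the harmonic boundary
#'   perturbation, fraction of radius (malignant only)
#' @param edge_case_fraction fraction of lesions placed against a
#'   zero-padded patch border
#' @param bit_depth raster bit depth
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(patch_size = 150L,
                         background_mean = 1000,
                         background_noise_sd = 40,
                         background_correlation_sigma = 3,
                         lesion_radius_range = c(12, 30),
                         lesion_contrast_range = c(300, 800),
                         margin_blur_sigma_range = c(0.5, 2.5),
                         n_spicules_range = c(4L, 10L),
                         radius_perturbation_amp = 0.25,
                         edge_case_fraction = 0.1,
                         bit_depth = 16L) {
  spec <- structure(list(
    patch_size = as.integer(patch_size),
    background_mean = background_mean,
    background_noise_sd = background_noise_sd,
    background_correlation_sigma = background_correlation_sigma,
    lesion_radius_range = as.numeric(lesion_radius_range),
    lesion_contrast_range = as.numeric(lesion_contrast_range),
    margin_blur_sigma_range = as.numeric(margin_blur_sigma_range),
    n_spicules_range = as.integer(n_spicules_range),
    radius_perturbation_amp = radius_perturbation_amp,
    edge_case_fraction = edge_case_fraction,
    bit_depth = as.integer(bit_depth)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' @param spec a `phantom_spec`
#' @return the spec, invisibly; errors name the offending field
#' @export
validate_phantom_spec <- function(spec) {
  rng2 <- function(x) length(x) == 2 && !any(is.na(x)) && x[1] <= x[2]
  if (length(spec$patch_size) != 1 || is.na(spec$patch_size) || spec$patch_size <= 0)
    stop_field("patch_size", "must be a positive integer")
  if (spec$background_noise_sd < 0)
    stop_field("background_noise_sd", "must be >= 0")
  if (spec$background_correlation_sigma < 0)
    stop_field("background_correlation_sigma", "must be >= 0")
  if (!rng2(spec$lesion_radius_range) || spec$lesion_radius_range[1] <= 0)
    stop_field("lesion_radius_range", "must be a positive (min, max) pair")
  if (!rng2(spec$lesion_contrast_range) || spec$lesion_contrast_range[1] <= 0)
    stop_field("lesion_contrast_range",
               "must be a positive (min, max) pair: lesions are brighter than background")
  if (!rng2(spec$margin_blur_sigma_range) || spec$margin_blur_sigma_range[1] < 0)
    stop_field("margin_blur_sigma_range", "must be a non-negative (min, max) pair")
  if (!rng2(spec$n_spicules_range) || spec$n_spicules_range[1] < 0)
    stop_field("n_spicules_range", "must be a non-negative (min, max) pair")
  if (spec$radius_perturbation_amp < 0)
    stop_field("radius_perturbation_amp", "must be >= 0")
  if (spec$edge_case_fraction < 0 || spec$edge_case_fraction > 1)
    stop_field("edge_case_fraction", "must be in [0, 1]")
  if (spec$bit_depth < 8)
    stop_field("bit_depth", "must be >= 8 bits")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Phantom specification\n")
  cat(sprintf("  patch %dx%d px, %d-bit; background %g +/- %g (corr. sigma %g px)\n",
              x$patch_size, x$patch_size, x$bit_depth, x$background_mean,
              x$background_noise_sd, x$background_correlation_sigma))
  cat(sprintf("  lesion radius %g-%g px, contrast %g-%g, margin blur %g-%g px\n",
              x$lesion_radius_range[1], x$lesion_radius_range[2],
              x$lesion_contrast_range[1], x$lesion_contrast_range[2],
              x$margin_blur_sigma_range[1], x$margin_blur_sigma_range[2]))
  cat(sprintf("  malignant: %d-%d spicules, boundary perturbation %g; edge cases %g%%\n",
              x$n_spicules_range[1], x$n_spicules_range[2],
              x$radius_perturbation_amp, 100 * x$edge_case_fraction))
  invisible(x)
}

# Angle-dependent lesion radius: ellipse, optionally harmonically perturbed.
lesion_radius_fun <- function(r0, axis_ratio, orientation, amp) {
  harm <- NULL
  if (amp > 0) {
    k <- 3:7
    ak <- stats::rnorm(length(k)); bk <- stats::rnorm(length(k))
    nrm <- sqrt(sum(ak^2 + bk^2) / 2)
    if (nrm > 0) { ak <- ak / nrm; bk <- bk / nrm }
    harm <- list(k = k, ak = ak, bk = bk)
  }
  function(theta) {
    th <- theta - orientation
    r <- r0 * axis_ratio / sqrt((axis_ratio * cos(th))^2 + sin(th)^2)
    if (!is.null(harm)) {
      g <- rep(0, length(theta))
      for (i in seq_along(harm$k)) {
        g <- g + harm$ak[i] * cos(harm$k[i] * theta) +
          harm$bk[i] * sin(harm$k[i] * theta)
      }
      r <- r * pmax(0.3, 1 + amp * g)
    }
    r
  }
}

#' Generate one synthetic lesion ROI
#'
#' Deterministic given `(spec, label, rng_seed)`.  The truth mask is the
#' set of pixels where the blurred, noiseless lesion profile exceeds half
#' the core contrast.
#'
#' @param spec a [phantom_spec()]
#' @param label `"malignant"` or `"benign"`
#' @param rng_seed integer seed for this sample
#' @param sample_id optional identifier (default derived from seed)
#' @return an object of class `lesion_roi` with fields `image`,
#'   `seed_point` (row, col), `label`, `truth_mask`, `padded_region`,
#'   `sample_id`, `bit_depth`, plus generator metadata (`core_contrast`,
#'   `radius`, `margin_blur_sigma`)
#' @export
generate_roi <- function(spec, label = c("malignant", "benign"),
                         rng_seed = 1L, sample_id = NULL) {
  validate_phantom_spec(spec)
  label <- match.arg(label)
  n <- spec$patch_size
  with_seed(rng_seed, {
    r0 <- stats::runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
    contrast <- stats::runif(1, spec$lesion_contrast_range[1],
                             spec$lesion_contrast_range[2])
    blur <- stats::runif(1, spec$margin_blur_sigma_range[1],
                         spec$margin_blur_sigma_range[2])
    axis_ratio <- stats::runif(1, 0.75, 1.0)
    orientation <- stats::runif(1, 0, pi)
    amp <- if (label == "malignant") spec$radius_perturbation_amp else 0
    rfun <- lesion_radius_fun(r0, axis_ratio, orientation, amp)

    edge_case <- stats::runif(1) < spec$edge_case_fraction
    pad_side <- pad_width <- NULL
    support <- 1.25 * r0 * (1 + 1.5 * amp) + 3 * blur
    if (edge_case) {
      pad_side <- sample(c("top", "bottom", "left", "right"), 1)
      pad_width <- round(stats::runif(1, 5, max(6, min(40, n / 2 - r0 - 5))))
      d_edge <- pad_width + stats::runif(1, 0.35, 1.0) * r0
      centre <- c(stats::runif(1, min(support, n / 2 - 1) + 1,
                               n - min(support, n / 2 - 1)),
                  stats::runif(1, min(support, n / 2 - 1) + 1,
                               n - min(support, n / 2 - 1)))
      centre <- switch(pad_side,
        top = c(d_edge, centre[2]),
        bottom = c(n + 1 - d_edge, centre[2]),
        left = c(centre[1], d_edge),
        right = c(centre[1], n + 1 - d_edge))
    } else {
      m <- min(support + 3, n / 2 - 1)
      centre <- c(stats::runif(1, m + 1, n - m), stats::runif(1, m + 1, n - m))
    }

    # noiseless lesion field on the patch grid
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    dy <- rows - centre[1]; dx <- cols - centre[2]
    r <- sqrt(dy^2 + dx^2)
    theta <- atan2(dy, dx)
    rb <- matrix(rfun(as.vector(theta)), n, n)
    u <- r / rb
    lesion <- matrix(0, n, n)
    dome <- u <= 1
    lesion[dome] <- contrast * (1 - DOME_DROOP * u[dome]^2)
    shoulder <- u > 1 & u <= 1 + SHOULDER_FRAC
    lesion[shoulder] <- contrast * (1 - DOME_DROOP) * 0.5 *
      (1 + cos(pi * (u[shoulder] - 1) / SHOULDER_FRAC))

    if (label == "malignant") {
      n_spic <- sample(seq(spec$n_spicules_range[1], spec$n_spicules_range[2]), 1)
      if (n_spic > 0) {
        phis <- stats::runif(n_spic, -pi, pi)
        lens <- stats::runif(n_spic, 0.4, 0.9) * r0
        sig_th <- 1.2 / r0
        spic <- matrix(0, n, n)
        for (i in seq_len(n_spic)) {
          dth <- (theta - phis[i] + pi) %% (2 * pi) - pi
          base <- 0.85 * rb
          along <- (r - base) / lens[i]
          ridge <- SPICULE_PEAK * contrast *
            exp(-dth^2 / (2 * sig_th^2)) * pmax(0, 1 - pmax(along, 0))
          ridge[r < 0.5 * rb] <- 0
          spic <- pmax(spic, ridge)
        }
        lesion <- pmax(lesion, spic)
      }
    }

    lesion <- gaussian_blur(lesion, blur)
    truth <- lesion > contrast / 2

    noise <- matrix(stats::rnorm(n * n), n, n)
    if (spec$background_correlation_sigma > 0) {
      noise <- gaussian_blur(noise, spec$background_correlation_sigma)
    }
    s <- stats::sd(as.vector(noise))
    if (s > 0) noise <- noise / s * spec$background_noise_sd
    image <- spec$background_mean + noise + lesion

    padded <- matrix(FALSE, n, n)
    if (edge_case) {
      w <- pad_width
      idx <- switch(pad_side,
        top = seq_len(w), bottom = (n - w + 1):n,
        left = seq_len(w), right = (n - w + 1):n)
      if (pad_side %in% c("top", "bottom")) padded[idx, ] <- TRUE else padded[, idx] <- TRUE
      truth[padded] <- FALSE
    }

    image <- pmin(pmax(round(image), 0), 2^spec$bit_depth - 1)
    image[padded] <- 0

    seed_point <- pmin(pmax(round(centre), 1L), n)
    # keep the marked centre inside the truth mask (raster/pad safety)
    if (!truth[seed_point[1], seed_point[2]]) {
      cand <- which(truth, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        d2 <- (cand[, 1] - centre[1])^2 + (cand[, 2] - centre[2])^2
        seed_point <- as.integer(cand[which.min(d2), ])
      }
    }

    structure(list(
      image = image,
      seed_point = as.integer(seed_point),
      label = label,
      truth_mask = truth,
      padded_region = padded,
      sample_id = if (is.null(sample_id))
        sprintf("roi-%08d", as.integer(rng_seed) %% 99999999L) else sample_id,
      bit_depth = spec$bit_depth,
      core_contrast = contrast,
      radius = r0,
      margin_blur_sigma = blur
    ), class = "lesion_roi")
  })
}

#' @export
print.lesion_roi <- function(x, ...) {
  cat(sprintf("Lesion ROI '%s': %dx%d px, %s, seed (%d, %d)\n",
              x$sample_id, nrow(x$image), ncol(x$image), x$label,
              x$seed_point[1], x$seed_point[2]))
  cat(sprintf("  core contrast %.0f, radius %.1f px, margin blur %.2f px, %d padded px\n",
              x$core_contrast, x$radius, x$margin_blur_sigma, sum(x$padded_region)))
  invisible(x)
}

#' Generate a labelled phantom dataset
#'
#' Per-sample seeds are derived reproducibly from `rng_seed`, so the i-th
#' sample is identical whatever the requested counts of the other class.
#'
#' @param spec a [phantom_spec()]
#' @param n_malignant,n_benign class counts
#' @param rng_seed integer master seed
#' @param id_prefix prefix for sample identifiers
#' @return a list of [generate_roi()] objects (class `lesion_roi_set`)
#' @export
generate_dataset <- function(spec, n_malignant, n_benign, rng_seed = 1L,
                             id_prefix = "roi") {
  stopifnot(n_malignant >= 0, n_benign >= 0)
  validate_phantom_spec(spec)
  labels <- c(rep("malignant", n_malignant), rep("benign", n_benign))
  rois <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    rois[[i]] <- generate_roi(
      spec, labels[i], rng_seed = derive_seed(rng_seed, i),
      sample_id = sprintf("%s-%s%04d", id_prefix,
                          ifelse(labels[i] == "malignant", "M", "B"),
                          if (labels[i] == "malignant") i else i - n_malignant))
  }
  structure(rois, class = "lesion_roi_set")
}

#' @export
print.lesion_roi_set <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("Phantom ROI set: %d samples (%d malignant, %d benign)\n",
              length(x), sum(labs == "malignant"), sum(labs == "benign")))
  invisible(x)
}

roi_labels <- function(rois) vapply(rois, `[[`, "", "label")
roi_ids <- function(rois) vapply(rois, `[[`, "", "sample_id")

#' Write a phantom dataset to disk
#'
#' Images as 16-bit grayscale TIFF, truth masks as 8-bit PNG (0/255), plus
#' a `manifest.csv` (sample_id, path, mask_path, seed_row, seed_col,
#' label).  Coordinates are (row, col), 1-based, origin top-left.
#'
#' @param rois a `lesion_roi_set` or list of `lesion_roi`
#' @param dir output directory (created if needed)
#' @return path of the manifest, invisibly
#' @export
write_roi_dataset <- function(rois, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(rois, function(roi) {
    img_path <- file.path(dir, paste0(roi$sample_id, ".tif"))
    scale <- 2^roi$bit_depth - 1
    tiff::writeTIFF(roi$image / scale, img_path, bits.per.sample = 16L,
                    compression = "none")
    mask_path <- NA_character_
    if (!is.null(roi$truth_mask)) {
      mask_path <- file.path(dir, paste0(roi$sample_id, "_mask.png"))
      png::writePNG(roi$truth_mask * 1.0, mask_path)
    }
    data.frame(sample_id = roi$sample_id, path = img_path,
               mask_path = mask_path, seed_row = roi$seed_point[1],
               seed_col = roi$seed_point[2], label = roi$label,
               bit_depth = roi$bit_depth, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Read a phantom dataset written by [write_roi_dataset()]
#'
#' @param manifest path to the manifest CSV
#' @return a `lesion_roi_set`
#' @export
read_roi_dataset <- function(manifest) {
  mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  rois <- lapply(seq_len(nrow(mf)), function(i) {
    bit_depth <- if ("bit_depth" %in% names(mf)) mf$bit_depth[i] else 16L
    img <- tiff::readTIFF(mf$path[i]) * (2^bit_depth - 1)
    mask <- NULL
    if (!is.na(mf$mask_path[i]) && nzchar(mf$mask_path[i])) {
      mask <- png::readPNG(mf$mask_path[i]) > 0.5
    }
    padded <- img == 0
    structure(list(
      image = round(img), seed_point = c(mf$seed_row[i], mf$seed_col[i]),
      label = mf$label[i], truth_mask = mask,
      padded_region = padded & outer_border_band(padded),
      sample_id = mf$sample_id[i], bit_depth = bit_depth,
      core_contrast = NA_real_, radius = NA_real_,
      margin_blur_sigma = NA_real_), class = "lesion_roi")
  })
  structure(rois, class = "lesion_roi_set")
}

# Zero-pad bands are flush with the patch border: keep only zero pixels
# connected to the border through zero rows/columns.
outer_border_band <- function(zero) {
  n <- nrow(zero); m <- ncol(zero)
  band <- matrix(FALSE, n, m)
  full_rows <- which(apply(zero, 1, all))
  full_cols <- which(apply(zero, 2, all))
  for (i in full_rows) if (i == 1 || all(seq_len(i) %in% full_rows)) band[i, ] <- TRUE
  for (i in rev(full_rows)) if (i == n || all(i:n %in% full_rows)) band[i, ] <- TRUE
  for (j in full_cols) if (j == 1 || all(seq_len(j) %in% full_cols)) band[, j] <- TRUE
  for (j in rev(full_cols)) if (j == m || all(j:m %in% full_cols)) band[, j] <- TRUE
  band
}
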