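# Handcrafted radiomics battery: lesion morphology, density heterogeneity
# and boundary contrast, grey-level co-occurrence texture, and wavelet
# subband statistics.  The battery is fixed and versioned through a
# feature schema so downstream tables are always aligned.

GLCM_OFFSETS <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))

#' Default radiomics configuration
#'
#' @param band_width outer band width for boundary contrast, pixels
#' @param glcm_levels grey levels for co-occurrence quantisation
#' @param glcm_offsets list of (dr, dc) offsets, averaged over
#' @param glcm_distances pixel distances at which the offset set is applied
#' @param wavelet_levels wavelet decomposition levels
#' @param texture_on_bbox compute texture on the mask bounding box
#'   (otherwise the whole ROI)
#' @param wavelet_on_roi compute wavelet features on the whole ROI
#'   (otherwise the mask bounding box)
#' @return a named list
#' @export
radiomics_config <- function(band_width = 5L, glcm_levels = 32L,
                             glcm_offsets = GLCM_OFFSETS,
                             glcm_distances = c(1L, 2L),
                             wavelet_levels = 2L,
                             texture_on_bbox = TRUE,
                             wavelet_on_roi = TRUE) {
  list(band_width = as.integer(band_width),
       glcm_levels = as.integer(glcm_levels),
       glcm_offsets = glcm_offsets,
       glcm_distances = as.integer(glcm_distances),
       wavelet_levels = as.integer(wavelet_levels),
       texture_on_bbox = isTRUE(texture_on_bbox),
       wavelet_on_roi = isTRUE(wavelet_on_roi))
}

#' Radiomics feature schema
#'
#' Fixed, ordered feature names with their category (`morphology`,
#' `density`, `texture`, `wavelet`).
#'
#' @param config a [radiomics_config()]
#' @return an object of class `feature_schema` with `names`,
#'   `categories` and `version`
#' @export
feature_schema <- function(config = radiomics_config()) {
  morph <- c("area", "perimeter", "circularity", "compactness",
             "eccentricity", "extent", "convexity", "radial_mean",
             "radial_sd", "radial_max", "radial_cv", "radial_roughness")
  dens <- c("interior_mean", "interior_sd", "interior_skewness",
            "interior_kurtosis", "interior_entropy", "interior_mad",
            "interior_p10", "interior_p90", "interior_p90_p10",
            "boundary_contrast", "boundary_contrast_norm")
  tex_stats <- c("energy", "contrast", "correlation", "homogeneity",
                 "entropy", "dissimilarity", "cluster_shade")
  tex <- as.vector(t(outer(paste0("glcm_d", config$glcm_distances),
                           tex_stats, paste, sep = "_")))
  bands <- c(as.vector(t(outer(c("LH", "HL", "HH"),
                               seq_len(config$wavelet_levels), paste0))),
             paste0("LL", config$wavelet_levels))
  wav <- c(paste0("wavelet_", bands, "_energy_frac"),
           paste0("wavelet_", bands, "_entropy"))
  names_all <- c(morph, dens, tex, wav)
  categories <- c(rep("morphology", length(morph)),
                  rep("density", length(dens)),
                  rep("texture", length(tex)),
                  rep("wavelet", length(wav)))
  names(categories) <- names_all
  structure(list(names = names_all, categories = categories,
                 version = "1.0"), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("Radiomics feature schema v%s: %d features\n", x$version,
              length(x$names)))
  print(table(factor(x$categories,
                     c("morphology", "density", "texture", "wavelet"))))
  invisible(x)
}

#' Features whose value shifts when a constant is added to the image
#'
#' All other features in the schema are invariant to intensity offsets.
#' Wavelet features appear here because the approximation subband absorbs
#' the image mean.
#'
#' @param schema a [feature_schema()]
#' @return character vector of feature names
#' @export
translation_sensitive_features <- function(schema = feature_schema()) {
  c("interior_mean", "interior_p10", "interior_p90",
    schema$names[schema$categories == "wavelet"])
}

#' Morphology features of a lesion mask
#'
#' @param mask logical matrix (nonempty, connected)
#' @return named numeric vector: area, perimeter (boundary pixel count),
#'   circularity, compactness (4*pi*A/P^2), best-fit-ellipse
#'   eccentricity, bounding-box extent, convexity (area / convex hull
#'   area), and centroid-to-boundary radial statistics (mean, sd, max,
#'   coefficient of variation, roughness)
#' @export
morphology_features <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  if (!nrow(px)) stop("empty mask")
  area <- nrow(px)
  bnd <- boundary_contour(mask)
  perim <- nrow(bnd)
  cen <- colMeans(px)

  # second-moment ellipse
  if (area > 1) {
    cv <- stats::cov(px)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ecc <- if (ev[1] > 0) sqrt(max(0, 1 - ev[2] / ev[1])) else 0
  } else ecc <- 0

  bbox_area <- (diff(range(px[, 1])) + 1) * (diff(range(px[, 2])) + 1)

  # convexity as a pixel-count ratio against the rasterised convex hull,
  # so a convex raster shape scores ~1 despite half-pixel boundary effects
  convexity <- area / hull_pixel_count(px, dim(mask))

  rad <- sqrt((bnd[, 1] - cen[1])^2 + (bnd[, 2] - cen[2])^2)
  ang <- atan2(bnd[, 1] - cen[1], bnd[, 2] - cen[2])
  rad_by_ang <- rad[order(ang)]
  roughness <- if (length(rad) > 1) stats::sd(diff(rad_by_ang)) else 0
  rmean <- mean(rad)

  c(area = area,
    perimeter = perim,
    circularity = circularity(mask),
    compactness = if (perim > 0) 4 * pi * area / perim^2 else 0,
    eccentricity = ecc,
    extent = area / bbox_area,
    convexity = convexity,
    radial_mean = rmean,
    radial_sd = if (length(rad) > 1) stats::sd(rad) else 0,
    radial_max = max(rad),
    radial_cv = if (rmean > 0 && length(rad) > 1) stats::sd(rad) / rmean else 0,
    radial_roughness = roughness)
}

# Number of pixel centres inside (or on) the convex hull of the mask's
# pixel centres, restricted to the image grid.
hull_pixel_count <- function(px, dims) {
  hull <- grDevices::chull(px)
  hp <- px[hull, , drop = FALSE]
  nv <- nrow(hp)
  if (nv < 3) return(nrow(px))          # degenerate hull: point or segment
  rr <- min(px[, 1]):max(px[, 1])
  cc <- min(px[, 2]):max(px[, 2])
  gr <- rep(rr, length(cc))
  gc <- rep(cc, each = length(rr))
  inside_pos <- rep(TRUE, length(gr))
  inside_neg <- rep(TRUE, length(gr))
  eps <- 1e-9
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cr <- (hp[j, 1] - hp[i, 1]) * (gc - hp[i, 2]) -
      (hp[j, 2] - hp[i, 2]) * (gr - hp[i, 1])
    inside_pos <- inside_pos & cr >= -eps
    inside_neg <- inside_neg & cr <= eps
  }
  max(sum(inside_pos | inside_neg), nrow(px))
}

# Morphological outer band of a mask: pixels outside the mask within
# `width` chebyshev-dilations (8-neighbourhood), padded pixels excluded.
outer_band <- function(mask, width, padded = NULL) {
  dil <- mask
  for (i in seq_len(width)) dil <- dilate8(dil)
  band <- dil & !mask
  if (!is.null(padded)) band <- band & !padded
  band
}

dilate8 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  v <- m
  v[-1, ] <- v[-1, ] | m[-n, ]
  v[-n, ] <- v[-n, ] | m[-1, ]
  out <- v
  out[, -1] <- out[, -1] | v[, -k]
  out[, -k] <- out[, -k] | v[, -1]
  out
}

#' Density and boundary-contrast features
#'
#' Intensity statistics over the mask plus the contrast between the mask
#' interior and a morphological outer band.
#'
#' @param image numeric matrix
#' @param mask logical matrix (nonempty)
#' @param band_width outer band width, pixels
#' @param padded optional logical matrix of zero-padded pixels to exclude
#'   from the outer band
#' @return named numeric vector
#' @export
density_features <- function(image, mask, band_width = 5L, padded = NULL) {
  if (!sum(mask)) stop("empty mask")
  vals <- image[mask]
  m <- mean(vals); s <- stats::sd(vals); if (is.na(s)) s <- 0
  cm <- vals - m
  skew <- if (s > 0) mean(cm^3) / s^3 else 0
  kurt <- if (s > 0) mean(cm^4) / s^4 - 3 else 0
  h <- if (diff(range(vals)) > 0) {
    tabulate(cut(vals, breaks = 32, labels = FALSE), 32)
  } else length(vals)
  band <- outer_band(mask, band_width, padded)
  if (sum(band) > 0) {
    contrast <- m - mean(image[band])
  } else {
    warning("outer band empty (padded or outside image); boundary contrast set to 0")
    contrast <- 0
  }
  q <- stats::quantile(vals, c(0.1, 0.9), names = FALSE, type = 7)
  c(interior_mean = m,
    interior_sd = s,
    interior_skewness = skew,
    interior_kurtosis = kurt,
    interior_entropy = entropy_bits(h / sum(h)),
    interior_mad = stats::mad(vals),
    interior_p10 = q[1],
    interior_p90 = q[2],
    interior_p90_p10 = q[2] - q[1],
    boundary_contrast = contrast,
    boundary_contrast_norm = if (s > 0) contrast / s else 0)
}

# Symmetric normalised grey-level co-occurrence matrix.
glcm_matrix <- function(q, levels, dr, dc) {
  n <- nrow(q); m <- ncol(q)
  rs <- if (dr >= 0) seq_len(n - dr) else seq(1 - dr, n)
  cs <- if (dc >= 0) seq_len(m - dc) else seq(1 - dc, m)
  a <- as.vector(q[rs, cs, drop = FALSE])
  b <- as.vector(q[rs + dr, cs + dc, drop = FALSE])
  tab <- table(factor(a, levels = seq_len(levels)),
               factor(b, levels = seq_len(levels)))
  P <- unclass(tab + t(tab))
  P / sum(P)
}

glcm_stats <- function(P) {
  levels <- nrow(P)
  i <- matrix(seq_len(levels), levels, levels)
  j <- t(i)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (sd_i > 0 && sd_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j) else 0
  c(energy = sum(P^2),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    homogeneity = sum(P / (1 + (i - j)^2)),
    entropy = entropy_bits(as.vector(P)),
    dissimilarity = sum(abs(i - j) * P),
    cluster_shade = sum(((i - mu_i) + (j - mu_j))^3 * P))
}

#' Grey-level co-occurrence texture features
#'
#' Quantises the region to `levels` grey levels, builds symmetric
#' normalised co-occurrence matrices for each offset and averages the
#' Haralick-style statistics over offsets.
#'
#' @param image numeric matrix
#' @param mask logical matrix; texture is computed over the mask bounding
#'   box (`NULL` uses the whole image)
#' @param levels number of grey levels (>= 2)
#' @param offsets list of (dr, dc) offsets
#' @param distance pixel distance multiplying each offset
#' @return named numeric vector averaged over offsets
#' @export
texture_features <- function(image, mask = NULL, levels = 32L,
                             offsets = GLCM_OFFSETS, distance = 1L) {
  stopifnot(levels >= 2)
  region <- image
  if (!is.null(mask)) {
    if (!sum(mask)) stop("empty mask")
    px <- which(mask, arr.ind = TRUE)
    region <- image[min(px[, 1]):max(px[, 1]), min(px[, 2]):max(px[, 2]),
                    drop = FALSE]
  }
  rng <- range(region)
  q <- if (rng[2] > rng[1]) {
    pmin(floor((region - rng[1]) / (rng[2] - rng[1]) * levels) + 1L, levels)
  } else matrix(1L, nrow(region), ncol(region))
  acc <- NULL
  used <- 0L
  for (off in offsets) {
    dr <- off[1] * distance; dc <- off[2] * distance
    if (abs(dr) >= nrow(q) || abs(dc) >= ncol(q)) next
    st <- glcm_stats(glcm_matrix(q, levels, dr, dc))
    acc <- if (is.null(acc)) st else acc + st
    used <- used + 1L
  }
  if (used == 0L) {
    # region smaller than every offset: degenerate single-cell co-occurrence
    acc <- c(energy = 1, contrast = 0, correlation = 0, homogeneity = 1,
             entropy = 0, dissimilarity = 0, cluster_shade = 0)
    used <- 1L
  }
  acc / used
}

#' Wavelet subband features
#'
#' Per-subband energy fraction (sum of squared coefficients over the
#' total) and coefficient entropy (base-2 entropy of the per-subband
#' normalised squared coefficients).
#'
#' @param image numeric matrix, both sides `>= 2^levels`
#' @param levels decomposition levels
#' @return named numeric vector
#' @export
wavelet_features <- function(image, levels = 2L) {
  sub <- dwt2(image, levels)
  energies <- vapply(sub, function(s) sum(s^2), 0)
  total <- sum(energies)
  fracs <- if (total > 0) energies / total else
    stats::setNames(c(rep(0, length(sub) - 1), 1), names(sub))
  ents <- vapply(sub, function(s) {
    e <- as.vector(s)^2
    if (sum(e) <= 0) return(0)
    entropy_bits(e / sum(e))
  }, 0)
  # fixed report order: details first, approximation last
  ord <- c(as.vector(t(outer(c("LH", "HL", "HH"), seq_len(levels), paste0))),
           paste0("LL", levels))
  out <- c(stats::setNames(fracs[ord], paste0("wavelet_", ord, "_energy_frac")),
           stats::setNames(ents[ord], paste0("wavelet_", ord, "_entropy")))
  out
}

#' Extract the full radiomics battery for one ROI
#'
#' Concatenates the four category extractors in schema order.  Non-finite
#' values are replaced by 0 (with a warning).
#'
#' @param roi a `lesion_roi`
#' @param seg a `seg_result` for the ROI (its `final_mask` is used)
#' @param config a [radiomics_config()]
#' @param schema a [feature_schema()]; must match the config
#' @return an object of class `feature_vector`: named numeric `values`,
#'   `sample_id`, `schema_version`
#' @export
extract_all <- function(roi, seg, config = radiomics_config(),
                        schema = feature_schema(config)) {
  mask <- seg$final_mask
  if (!sum(mask)) stop("empty final mask")
  tex_img <- roi$image
  vals <- c(
    morphology_features(mask),
    density_features(roi$image, mask, config$band_width, roi$padded_region),
    unlist(lapply(config$glcm_distances, function(d) {
      st <- texture_features(roi$image, if (config$texture_on_bbox) mask else NULL,
                             config$glcm_levels, config$glcm_offsets, d)
      stats::setNames(st, paste0("glcm_d", d, "_", names(st)))
    })),
    wavelet_features(if (config$wavelet_on_roi) roi$image else
      crop_to_mask(roi$image, mask), config$wavelet_levels)
  )
  if (!identical(names(vals), schema$names))
    stop("feature schema mismatch: extractor output does not align with schema")
  bad <- !is.finite(vals)
  if (any(bad)) {
    warning(sprintf("non-finite feature values set to 0: %s",
                    paste(names(vals)[bad], collapse = ", ")))
    vals[bad] <- 0
  }
  structure(list(sample_id = roi$sample_id, values = vals,
                 schema_version = schema$version), class = "feature_vector")
}

crop_to_mask <- function(image, mask) {
  px <- which(mask, arr.ind = TRUE)
  image[min(px[, 1]):max(px[, 1]), min(px[, 2]):max(px[, 2]), drop = FALSE]
}

#' Segment and extract features for a whole ROI set
#'
#' @param rois a `lesion_roi_set`
#' @param seg_parameters a [seg_params()]
#' @param config a [radiomics_config()]
#' @param segs optional precomputed list of `seg_result`s
#' @return data frame: sample_id, label, then schema-ordered feature
#'   columns; the schema is attached as attribute `"schema"`, the
#'   segmentations as `"segmentations"`
#' @export
extract_features_dataset <- function(rois, seg_parameters = seg_params(),
                                     config = radiomics_config(),
                                     segs = NULL) {
  schema <- feature_schema(config)
  if (is.null(segs)) segs <- lapply(rois, segment_lesion, params = seg_parameters)
  rows <- lapply(seq_along(rois), function(i) {
    fv <- extract_all(rois[[i]], segs[[i]], config, schema)
    fv$values
  })
  df <- as.data.frame(do.call(rbind, rows))
  df <- cbind(data.frame(sample_id = roi_ids(rois), label = roi_labels(rois),
                         stringsAsFactors = FALSE), df)
  attr(df, "schema") <- schema
  attr(df, "segmentations") <- segs
  df
}

#' Write a feature table (CSV plus JSON schema sidecar)
#' @param features data frame from [extract_features_dataset()]
#' @param path CSV path; the schema goes to `<path>.schema.json`
#' @return `path`, invisibly
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  schema <- attr(features, "schema")
  if (!is.null(schema)) {
    jsonlite::write_json(
      list(version = schema$version, names = schema$names,
           categories = as.list(schema$categories)),
      paste0(path, ".schema.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
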