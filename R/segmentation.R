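# Adaptive multi-layer topographic region growing.
#
# A seed-initialised threshold is relaxed layer by layer like a descending
# contour level.  Each layer is the connected component of super-threshold
# pixels containing (or nearest to) the seed; growth stops when the layer
# area explodes or the layer circularity collapses, and the previous layer
# is returned as the lesion.
#
# Lesions are bright.  The first threshold applies the alpha margin on an
# inverted attenuation-like scale measured from a reference intensity
# (default: seed intensity plus the seed-median gap), which is equivalent
# to placing the first bright-scale threshold an alpha-fraction of the
# seed-to-reference gap below the seed intensity.  Because the
# layer contrast (boundary minus interior) is negative for bright lesions,
# the threshold update then lowers the threshold each layer, producing
# outward topographic growth.  See the methods vignette for the full
# rationale of this convention.

#' Parameters of the topographic region-growing segmenter
#'
#' @param alpha first-layer threshold margin (dimensionless)
#' @param beta contrast-to-threshold update coefficient (dimensionless)
#' @param size_growth_limit stop when the relative layer-area increase
#'   exceeds this limit
#' @param circularity_reduction_limit stop when the relative circularity
#'   reduction exceeds this limit
#' @param connectivity pixel connectivity, 4 or 8
#' @param max_layers maximum number of topographic layers
#' @param seed_window half-width (pixels) of the window used to robustify
#'   the seed intensity
#' @param min_check_area minimum previous-layer area (pixels) before the
#'   two ratio termination tests are applied; relative area and
#'   circularity changes are statistically meaningless on few-pixel
#'   regions during the bootstrap layers
#' @param intensity_origin reference intensity of the inverted working
#'   scale; `NULL` (default) anchors it at the robust seed intensity:
#'   `i_seed + (i_seed - median(I))` over non-padded pixels, so the
#'   first-layer margin spans a tenth of the seed-to-background gap
#' @return an object of class `seg_params`
#' @export
seg_params <- function(alpha = 0.1, beta = 0.5, size_growth_limit = 2.0,
                       circularity_reduction_limit = 0.5, connectivity = 8,
                       max_layers = 20L, seed_window = 3L,
                       min_check_area = 25L, intensity_origin = NULL) {
  if (alpha <= 0) stop_field("alpha", "must be > 0")
  if (beta <= 0) stop_field("beta", "must be > 0")
  if (size_growth_limit <= 0) stop_field("size_growth_limit", "must be > 0")
  if (circularity_reduction_limit <= 0)
    stop_field("circularity_reduction_limit", "must be > 0")
  if (!connectivity %in% c(4, 8)) stop_field("connectivity", "must be 4 or 8")
  if (max_layers < 1) stop_field("max_layers", "must be >= 1")
  if (seed_window < 0) stop_field("seed_window", "must be >= 0")
  structure(list(alpha = alpha, beta = beta,
                 size_growth_limit = size_growth_limit,
                 circularity_reduction_limit = circularity_reduction_limit,
                 connectivity = connectivity, max_layers = as.integer(max_layers),
                 seed_window = as.integer(seed_window),
                 min_check_area = as.integer(min_check_area),
                 intensity_origin = intensity_origin),
            class = "seg_params")
}

#' Robust seed intensity
#'
#' Maximum intensity in the `(2*window+1)^2` neighbourhood of the seed,
#' clipped to the image; `window = 0` returns the seed pixel exactly.
#'
#' @param image numeric matrix
#' @param seed_point (row, col)
#' @param window half-width in pixels
#' @return intensity value
#' @export
seed_intensity <- function(image, seed_point, window = 3L) {
  r <- seed_point[1]; c <- seed_point[2]
  if (r < 1 || r > nrow(image) || c < 1 || c > ncol(image))
    stop("seed_point out of image bounds")
  rr <- max(1, r - window):min(nrow(image), r + window)
  cc <- max(1, c - window):min(ncol(image), c + window)
  max(image[rr, cc])
}

#' First topographic threshold
#'
#' `T1 = Iseed + alpha * Iseed` with `alpha = 0.1` by default.
#'
#' @param i_seed seed intensity (attenuation scale)
#' @param alpha margin coefficient
#' @return threshold intensity
#' @export
first_threshold <- function(i_seed, alpha = 0.1) {
  stopifnot(i_seed >= 0)
  i_seed * (1 + alpha)
}

#' Next topographic threshold
#'
#' `Tj = T(j-1) + beta * C(j-1)` with `beta = 0.5` by default.  The layer
#' contrast is signed: for bright lesions on the native scale it is
#' negative, so successive thresholds decrease.
#'
#' @param t_prev previous threshold
#' @param c_prev previous layer contrast (signed)
#' @param beta update coefficient
#' @return threshold intensity
#' @export
next_threshold <- function(t_prev, c_prev, beta = 0.5) {
  t_prev + beta * c_prev
}

#' Topographic layer region
#'
#' The connected component of super-threshold pixels (`intensity >=
#' threshold`) containing the seed.  If the seed itself fails the
#' threshold, the component nearest to the seed among those intersecting
#' the seed's window neighbourhood is returned; if none exists, the
#' singleton seed pixel.
#'
#' @param image numeric matrix (padded pixels may be `-Inf`)
#' @param seed_point (row, col)
#' @param threshold intensity threshold
#' @param connectivity 4 or 8
#' @param seed_window half-width of the fallback search window
#' @return logical matrix
#' @export
layer_region <- function(image, seed_point, threshold, connectivity = 8,
                         seed_window = 3L) {
  r <- seed_point[1]; c <- seed_point[2]
  if (r < 1 || r > nrow(image) || c < 1 || c > ncol(image))
    stop("seed_point out of image bounds")
  binary <- !is.na(image) & image >= threshold
  if (binary[r, c]) return(connected_component(binary, seed_point, connectivity))
  runs <- mask_runs(binary)
  if (!length(runs$col)) return(singleton_mask(dim(image), seed_point))
  w <- seed_window
  near <- which(runs$col >= c - w & runs$col <= c + w &
                runs$sr <= r + w & runs$er >= r - w)
  if (!length(near)) return(singleton_mask(dim(image), seed_point))
  roots <- label_runs(runs, connectivity)
  rr <- pmin(pmax(r, runs$sr[near]), runs$er[near])
  d2 <- (rr - r)^2 + (runs$col[near] - c)^2
  root <- roots[near[which.min(d2)]]
  runs_to_mask(runs, which(roots == root), nrow(image), ncol(image))
}

singleton_mask <- function(dims, point) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[point[1], point[2]] <- TRUE
  m
}

#' Inner boundary contour of a mask
#'
#' Mask pixels having at least one 4-neighbour outside the mask
#' (out-of-image neighbours count as outside).
#'
#' @param mask logical matrix
#' @return two-column (row, col) matrix of boundary pixel coordinates
#' @export
boundary_contour <- function(mask) {
  which(boundary_mask(mask), arr.ind = TRUE)
}

# Logical-matrix form of the inner 4-boundary.
boundary_mask <- function(mask) {
  if (!sum(mask)) stop("empty mask")
  n <- nrow(mask); m <- ncol(mask)
  up <- rbind(FALSE, mask[-n, , drop = FALSE])
  down <- rbind(mask[-1, , drop = FALSE], FALSE)
  left <- cbind(FALSE, mask[, -m, drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], FALSE)
  mask & !(up & down & left & right)
}

#' Layer contrast
#'
#' Mean intensity over the inner boundary contour minus mean intensity
#' over the interior (mask minus boundary).  Defined as 0 when the mask
#' has no interior.  For a bright lesion whose rim is darker than its
#' core this is negative.
#'
#' @param image numeric matrix
#' @param mask logical matrix
#' @return signed intensity difference
#' @export
layer_contrast <- function(image, mask) {
  if (!sum(mask)) stop("empty mask")
  b <- boundary_mask(mask)
  interior <- mask & !b
  if (!sum(interior)) return(0)
  mean(image[b]) - mean(image[interior])
}

#' Circularity of a mask
#'
#' Fraction of mask pixels falling inside the equal-area disk centred at
#' the mask centroid; 1 for a perfect centred disk (up to pixelation),
#' small for elongated shapes.
#'
#' @param mask logical matrix
#' @return value in (0, 1]
#' @export
circularity <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  if (!nrow(px)) stop("empty mask")
  area <- nrow(px)
  cen <- colMeans(px)
  r2 <- area / pi
  inside <- (px[, 1] - cen[1])^2 + (px[, 2] - cen[2])^2 <= r2
  max(sum(inside) / area, 1 / area)
}

#' Growth-termination test
#'
#' Size check first: stop if the relative area increase exceeds the size
#' growth limit; otherwise stop if the relative circularity reduction
#' exceeds its limit; otherwise continue.
#'
#' @param s_prev,s_j areas of the previous and current layer
#' @param v_prev,v_j circularities of the previous and current layer
#' @param params a [seg_params()]
#' @return one of `"continue"`, `"stop_size"`, `"stop_circularity"`
#' @export
check_termination <- function(s_prev, s_j, v_prev, v_j, params = seg_params()) {
  stopifnot(s_prev >= 1, v_prev > 0)
  if ((s_j - s_prev) / s_prev > params$size_growth_limit) return("stop_size")
  if (abs(v_prev - v_j) / v_prev > params$circularity_reduction_limit)
    return("stop_circularity")
  "continue"
}

#' Segment a lesion by multi-layer topographic region growing
#'
#' Iterates topographic layers from the seed until a termination rule
#' fires: area explosion or circularity collapse return the previous
#' layer; an unchanged layer stops with `no_growth`; otherwise the layer
#' cap `max_layers` applies.  Zero-padded pixels are excluded from
#' growth.
#'
#' @param roi a `lesion_roi` (or any list with `image`, `seed_point`,
#'   optional `padded_region`)
#' @param params a [seg_params()]
#' @return an object of class `seg_result` with `layers` (each holding
#'   `index`, `threshold`, `mask`, `area`, `circularity`, `contrast`,
#'   `boundary`), `final_mask`, `final_layer_index`,
#'   `termination_reason`, `seed_point`, `i_seed`, `intensity_origin`
#' @export
segment_lesion <- function(roi, params = seg_params()) {
  image <- roi$image
  seed <- roi$seed_point
  work <- image
  if (!is.null(roi$padded_region) && any(roi$padded_region)) {
    work[roi$padded_region] <- -Inf
  }
  finite <- work[is.finite(work)]
  i_seed <- seed_intensity(work, seed, params$seed_window)
  if (!is.finite(i_seed)) i_seed <- max(image[seed[1], seed[2]], 0)
  origin <- params$intensity_origin
  if (is.null(origin)) {
    origin <- i_seed + max(i_seed - stats::median(finite), 0)
  }
  # alpha margin on the inverted attenuation scale, mapped back to the
  # native bright scale: T1 = i_seed - alpha * (origin - i_seed)
  t_j <- origin - first_threshold(max(origin - i_seed, 0), params$alpha)

  layers <- vector("list", params$max_layers)
  reason <- NULL; final_idx <- NULL
  for (j in seq_len(params$max_layers)) {
    mask <- layer_region(work, seed, t_j, params$connectivity,
                         params$seed_window)
    layer <- list(index = j, threshold = t_j, mask = mask,
                  area = sum(mask), circularity = circularity(mask),
                  contrast = layer_contrast(work, mask),
                  boundary = boundary_contour(mask))
    layers[[j]] <- layer
    if (j >= 2) {
      prev <- layers[[j - 1]]
      if (identical(mask, prev$mask)) {
        reason <- "no_growth"; final_idx <- j
        break
      }
      verdict <- if (prev$area >= params$min_check_area) {
        check_termination(prev$area, layer$area,
                          prev$circularity, layer$circularity, params)
      } else "continue"
      if (verdict == "stop_size") {
        reason <- "size_growth"; final_idx <- j - 1
        break
      }
      if (verdict == "stop_circularity") {
        reason <- "circularity_reduction"; final_idx <- j - 1
        break
      }
    }
    if (j == params$max_layers) {
      reason <- "max_layers"; final_idx <- j
      break
    }
    t_j <- next_threshold(t_j, layer$contrast, params$beta)
  }
  layers <- layers[!vapply(layers, is.null, logical(1))]
  structure(list(layers = layers,
                 final_mask = layers[[final_idx]]$mask,
                 final_layer_index = final_idx,
                 termination_reason = reason,
                 seed_point = seed,
                 i_seed = i_seed,
                 intensity_origin = origin),
            class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat(sprintf("Topographic segmentation: %d layer(s), final layer %d (%s)\n",
              length(x$layers), x$final_layer_index, x$termination_reason))
  cat(sprintf("  seed (%d, %d), seed intensity %.1f, final area %d px, circularity %.3f\n",
              x$seed_point[1], x$seed_point[2], x$i_seed,
              x$layers[[x$final_layer_index]]$area,
              x$layers[[x$final_layer_index]]$circularity))
  invisible(x)
}

#' Per-layer summary of a segmentation
#'
#' @param object a `seg_result`
#' @param ... unused
#' @return data frame with columns j, Tj, Sj, Vj, Cj, terminated
#' @export
summary.seg_result <- function(object, ...) {
  data.frame(
    j = vapply(object$layers, `[[`, 0L, "index"),
    Tj = vapply(object$layers, `[[`, 0, "threshold"),
    Sj = vapply(object$layers, `[[`, 0L, "area"),
    Vj = vapply(object$layers, `[[`, 0, "circularity"),
    Cj = vapply(object$layers, `[[`, 0, "contrast"),
    terminated = seq_along(object$layers) == object$final_layer_index
  )
}
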