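# Connected components of binary masks via column run-length encoding and
# union-find.  This is the primitive behind layer-by-layer region growing;
# the test suite checks it against a brute-force breadth-first flood fill.

# Decompose a logical matrix into vertical runs (column-major order).
mask_runs <- function(mask) {
  n <- nrow(mask)
  v <- rbind(mask, FALSE)            # sentinel row stops cross-column runs
  r <- rle(as.vector(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  s <- starts[keep]; e <- ends[keep]
  col <- (s - 1L) %/% (n + 1L) + 1L
  list(col = as.integer(col),
       sr = as.integer(s - (col - 1L) * (n + 1L)),
       er = as.integer(e - (col - 1L) * (n + 1L)))
}

# Union-find labelling of runs; returns the root id of each run.
label_runs <- function(runs, connectivity = 8) {
  k <- length(runs$col)
  parent <- seq_len(k)
  if (k < 2) return(parent)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  tol <- if (connectivity == 8) 1L else 0L
  # runs come out of rle() sorted by column, then start row
  first_of_col <- match(unique(runs$col), runs$col)
  col_index <- split(seq_len(k), runs$col)
  cols <- as.integer(names(col_index))
  for (ci in seq_along(cols)[-1]) {
    if (cols[ci] - cols[ci - 1] != 1L) next
    a <- col_index[[ci - 1]]; b <- col_index[[ci]]
    ia <- 1L; ib <- 1L
    while (ia <= length(a) && ib <= length(b)) {
      ra <- a[ia]; rb <- b[ib]
      if (runs$sr[ra] <= runs$er[rb] + tol && runs$sr[rb] <= runs$er[ra] + tol) {
        fa <- find(ra); fb <- find(rb)
        if (fa != fb) parent[fb] <- fa
      }
      if (runs$er[ra] <= runs$er[rb]) ia <- ia + 1L else ib <- ib + 1L
    }
  }
  vapply(seq_len(k), find, integer(1))
}

runs_to_mask <- function(runs, pick, nrow, ncol) {
  out <- matrix(FALSE, nrow, ncol)
  for (i in pick) out[runs$sr[i]:runs$er[i], runs$col[i]] <- TRUE
  out
}

#' Connected component of a binary mask containing a pixel
#'
#' @param mask logical matrix
#' @param point (row, col) of a pixel inside the mask
#' @param connectivity 4 or 8
#' @return logical matrix of the component
#' @keywords internal
connected_component <- function(mask, point, connectivity = 8) {
  stopifnot(isTRUE(mask[point[1], point[2]]))
  runs <- mask_runs(mask)
  roots <- label_runs(runs, connectivity)
  at <- which(runs$col == point[2] & runs$sr <= point[1] & runs$er >= point[1])
  runs_to_mask(runs, which(roots == roots[at[1]]), nrow(mask), ncol(mask))
}
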