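# Score-level fusion of the two CAD branches (Model-III.1 .. III.4):
# a stacked 2-feature SVM, the weighted average, and the pointwise
# minimum and maximum of the branch scores.

#' Weighted-average score fusion (Model-III.2)
#'
#' `S = w1 * s1 + (1 - w1) * s2`; `w1 = 0.5` gives the average score.
#'
#' @param s1,s2 branch scores in [0, 1]
#' @param w1 weight of the first branch, in [0, 1]
#' @return fused scores
#' @export
fuse_weighted <- function(s1, s2, w1 = 0.5) {
  if (any(s1 < 0 | s1 > 1) || any(s2 < 0 | s2 > 1))
    stop("scores must be in [0, 1]")
  if (any(w1 < 0 | w1 > 1)) stop("w1 must be in [0, 1]")
  w1 * s1 + (1 - w1) * s2
}

#' Minimum score fusion (Model-III.3)
#' @rdname fuse_weighted
#' @export
fuse_min <- function(s1, s2) {
  if (any(s1 < 0 | s1 > 1) || any(s2 < 0 | s2 > 1))
    stop("scores must be in [0, 1]")
  pmin(s1, s2)
}

#' Maximum score fusion (Model-III.4)
#' @rdname fuse_weighted
#' @export
fuse_max <- function(s1, s2) {
  if (any(s1 < 0 | s1 > 1) || any(s2 < 0 | s2 > 1))
    stop("scores must be in [0, 1]")
  pmax(s1, s2)
}

# Align two score tables on their common samples; errors on label or
# fold disagreement.
align_scores <- function(scores1, scores2) {
  common <- intersect(scores1$sample_id, scores2$sample_id)
  if (!length(common)) stop("score tables share no sample ids")
  a <- scores1[match(common, scores1$sample_id), ]
  b <- scores2[match(common, scores2$sample_id), ]
  if (!identical(a$true_label, b$true_label))
    stop("true labels disagree between score tables")
  if (!identical(a$fold, b$fold))
    stop("fold assignments disagree between score tables")
  list(ids = common, s1 = a$score, s2 = b$score,
       label = a$true_label, fold = a$fold)
}

#' Stacked-SVM score fusion (Model-III.1)
#'
#' The two branch scores are used as a 2-feature input to another
#' calibrated polynomial-kernel SVM, trained and tested under the SAME
#' fold assignment that produced the branch scores, so no test score
#' leaks into fusion training.
#'
#' @param scores1,scores2 [score_table()]s of the two branches (same
#'   samples, same folds)
#' @param kernel_degree,regularisation passed to [fit_svm()]
#' @param model_id output model identifier
#' @return a [score_table()]
#' @export
fuse_svm <- function(scores1, scores2, kernel_degree = 3L,
                     regularisation = 1.0, model_id = "Model-III.1") {
  al <- align_scores(scores1, scores2)
  x <- cbind(s1 = al$s1, s2 = al$s2)
  k <- max(al$fold)
  out <- vector("list", k)
  for (f in sort(unique(al$fold))) {
    tr <- al$fold != f
    te <- !tr
    if (length(unique(al$label[tr])) < 2)
      stop(sprintf("fold %d: fusion training data contains a single class", f))
    svm <- fit_svm(x[tr, , drop = FALSE], al$label[tr], kernel_degree,
                   regularisation)
    sc <- predict(svm, x[te, , drop = FALSE])
    out[[f]] <- score_table(al$ids[te], model_id, f, al$label[te],
                            pmin(pmax(sc, 0), 1))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  class(res) <- c("score_table", "data.frame")
  res
}

#' Build all four fusion models from two branch score tables
#'
#' @param scores1,scores2 [score_table()]s of Model-I and Model-II
#' @param w1 weight of the first branch for the weighted fusion
#' @param kernel_degree,regularisation stacked-SVM settings
#' @return named list of four [score_table()]s: `Model-III.1` (stacked
#'   SVM), `Model-III.2` (weighted average), `Model-III.3` (minimum),
#'   `Model-III.4` (maximum)
#' @export
fuse_all <- function(scores1, scores2, w1 = 0.5, kernel_degree = 3L,
                     regularisation = 1.0) {
  al <- align_scores(scores1, scores2)
  simple <- function(vals, id) {
    score_table(al$ids, id, al$fold, al$label, vals)
  }
  list(
    "Model-III.1" = fuse_svm(scores1, scores2, kernel_degree, regularisation),
    "Model-III.2" = simple(fuse_weighted(al$s1, al$s2, w1), "Model-III.2"),
    "Model-III.3" = simple(fuse_min(al$s1, al$s2), "Model-III.3"),
    "Model-III.4" = simple(fuse_max(al$s1, al$s2), "Model-III.4")
  )
}
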