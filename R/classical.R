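# Model-I: standardisation + PCA at a 95% explained-variance target +
# polynomial-kernel SVM with sigmoid score calibration, refitted
# independently inside every cross-validation fold so no test-fold
# information enters any fitting step.

#' Score table constructor
#'
#' The common currency of all classifier branches: one row per
#' (sample_id, model_id) with the fold, the true label and a malignancy
#' likelihood score in [0, 1].
#'
#' @param sample_id,model_id,fold,true_label,score column vectors
#' @return a data frame of class `score_table`
#' @export
score_table <- function(sample_id, model_id, fold, true_label, score) {
  stopifnot(all(score >= 0 & score <= 1),
            all(true_label %in% c("malignant", "benign")))
  df <- data.frame(sample_id = as.character(sample_id),
                   model_id = as.character(model_id),
                   fold = as.integer(fold),
                   true_label = as.character(true_label),
                   score = as.numeric(score),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("sample_id", "model_id")]))
    stop("duplicate (sample_id, model_id) rows in score table")
  class(df) <- c("score_table", "data.frame")
  df
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("Score table: %d samples, model(s) %s\n", nrow(x),
              paste(unique(x$model_id), collapse = ", ")))
  NextMethod()
}

#' Cross-validation fold assignment
#'
#' Deterministic given `rng_seed`.  Stratified assignment deals each
#' class round-robin into the k folds after shuffling, so per-class fold
#' sizes differ by at most one.
#'
#' @param labels per-sample class labels ("malignant"/"benign")
#' @param k number of folds
#' @param rng_seed integer seed
#' @param stratified stratify by class
#' @param sample_ids optional sample identifiers (default names of
#'   `labels` or 1..n)
#' @return an object of class `fold_assignment`: `fold` (integer vector
#'   aligned with `sample_ids`), `sample_id`, `k`, `rng_seed`,
#'   `stratified`
#' @export
make_folds <- function(labels, k = 10L, rng_seed = 1L, stratified = TRUE,
                       sample_ids = NULL) {
  n <- length(labels)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the number of samples")
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(names(labels))) names(labels) else
      as.character(seq_len(n))
  }
  fold <- integer(n)
  with_seed(rng_seed, {
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      idx <- sample.int(n)
      fold[idx] <- rep_len(seq_len(k), n)
    }
  })
  structure(list(fold = fold, sample_id = as.character(sample_ids),
                 k = as.integer(k), rng_seed = as.integer(rng_seed),
                 stratified = isTRUE(stratified)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("%d-fold assignment over %d samples (%s)\n", x$k,
              length(x$fold), if (x$stratified) "stratified" else "random"))
  invisible(x)
}

#' Fit a PCA feature-reduction model
#'
#' Features are z-scored with training statistics (zero-variance features
#' are dropped), then the minimal number of leading principal components
#' whose cumulative explained variance reaches `variance_target` is
#' retained.
#'
#' @param train_features numeric matrix (samples x features)
#' @param variance_target cumulative explained-variance fraction
#' @return an object of class `pca_model`
#' @export
fit_pca <- function(train_features, variance_target = 0.95) {
  x <- as.matrix(train_features)
  if (nrow(x) < 2) stop("need at least 2 training samples")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    message(sprintf("dropping %d zero-variance feature(s): %s",
                    sum(!keep),
                    paste(utils::head(colnames(x)[!keep], 5), collapse = ", ")))
  }
  if (!any(keep)) stop("all features have zero variance")
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  rank_keep <- pc$sdev > 1e-12
  rotation <- pc$rotation[, rank_keep, drop = FALSE]
  sdev <- pc$sdev[rank_keep]
  # canonical component signs (largest-magnitude loading positive), so the
  # decomposition is reproducible across algebraically equivalent inputs
  for (j in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) rotation[, j] <- -rotation[, j]
  }
  ratios <- sdev^2 / sum(pc$sdev^2)
  n_ret <- which(cumsum(ratios) >= variance_target - 1e-12)[1]
  if (is.na(n_ret)) n_ret <- length(ratios)
  structure(list(feature_means = mu, feature_scales = sdv, keep = keep,
                 components = rotation,
                 component_sdev = sdev,
                 explained_variance_ratios = ratios,
                 n_retained = as.integer(n_ret),
                 variance_target = variance_target),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d/%d components retained (cumulative variance %.3f >= %g)\n",
              x$n_retained, length(x$explained_variance_ratios),
              sum(x$explained_variance_ratios[seq_len(x$n_retained)]),
              x$variance_target))
  invisible(x)
}

#' Project samples onto retained principal components
#'
#' Component scores are whitened (divided by the training-set component
#' standard deviation), which makes the projection invariant to
#' duplicated feature columns.
#'
#' @param object a `pca_model`
#' @param newdata numeric matrix (samples x original features)
#' @param n_components override the number of components (default
#'   `n_retained`)
#' @param whiten divide scores by training component standard deviations
#' @param ... unused
#' @return matrix of component scores
#' @export
predict.pca_model <- function(object, newdata, n_components = NULL,
                              whiten = TRUE, ...) {
  x <- as.matrix(newdata)[, object$keep, drop = FALSE]
  z <- sweep(sweep(x, 2, object$feature_means[object$keep]), 2,
             object$feature_scales[object$keep], "/")
  k <- if (is.null(n_components)) object$n_retained else n_components
  sc <- z %*% object$components[, seq_len(k), drop = FALSE]
  if (whiten) sc <- sweep(sc, 2, object$component_sdev[seq_len(k)], "/")
  sc
}

#' Fit a calibrated polynomial-kernel SVM scorer
#'
#' The SVM margin is mapped to a malignancy likelihood in [0, 1] by a
#' monotone logistic calibration fitted on the training margins.  The
#' kernel is inhomogeneous (`coef0 = 1`) so a degree-2 kernel separates
#' XOR-type configurations.
#'
#' @param train_components numeric matrix (samples x components)
#' @param labels training labels ("malignant"/"benign")
#' @param kernel_degree polynomial degree
#' @param regularisation SVM cost parameter
#' @return an object of class `svm_scorer`; use [predict.svm_scorer()]
#'   for scores
#' @export
fit_svm <- function(train_components, labels, kernel_degree = 3L,
                    regularisation = 1.0) {
  x <- as.matrix(train_components)
  y <- factor(labels, levels = c("benign", "malignant"))
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  fit <- e1071::svm(x, y, kernel = "polynomial", degree = kernel_degree,
                    coef0 = 1, cost = regularisation, scale = FALSE)
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  if (mean(dv[y == "malignant"]) < mean(dv[y == "benign"])) dv_sign <- -1
  else dv_sign <- 1
  dv <- dv * dv_sign
  cal <- suppressWarnings(
    stats::glm(I(y == "malignant") ~ dv, family = stats::binomial()))
  coefs <- stats::coef(cal)
  if (any(!is.finite(coefs)) || coefs[2] <= 0) {
    # degenerate calibration (e.g. perfectly separable margins)
    coefs <- c(0, max(coefs[2], 1, na.rm = TRUE))
  }
  structure(list(svm = fit, dv_sign = dv_sign,
                 calibration = unname(coefs)), class = "svm_scorer")
}

#' Malignancy scores from a calibrated SVM
#'
#' @param object an `svm_scorer`
#' @param newdata numeric matrix
#' @param ... unused
#' @return numeric scores in [0, 1]
#' @export
predict.svm_scorer <- function(object, newdata, ...) {
  dv <- attr(stats::predict(object$svm, as.matrix(newdata),
                            decision.values = TRUE),
             "decision.values")[, 1] * object$dv_sign
  stats::plogis(object$calibration[1] + object$calibration[2] * dv)
}

#' Cross-validated Model-I scores
#'
#' For each fold, standardisation, PCA and the calibrated SVM are fitted
#' on the nine training folds only; scores are emitted for the held-out
#' fold.  Per-fold PCA dimensionality is recorded in the `"pca_info"`
#' attribute.
#'
#' @param features data frame with `sample_id`, `label` and feature
#'   columns (as from [extract_features_dataset()]), or a numeric matrix
#' @param labels labels, required when `features` is a matrix
#' @param folds a [make_folds()] assignment
#' @param model_config list: `variance_target` (0.95), `kernel_degree`
#'   (3), `regularisation` (1), `model_id` ("Model-I")
#' @return a [score_table()]
#' @export
cross_validated_scores <- function(features, labels = NULL, folds,
                                   model_config = list()) {
  cfg <- utils::modifyList(list(variance_target = 0.95, kernel_degree = 3L,
                                regularisation = 1.0, model_id = "Model-I"),
                           model_config)
  if (is.data.frame(features) && all(c("sample_id", "label") %in% names(features))) {
    ids <- features$sample_id
    labels <- features$label
    x <- as.matrix(features[setdiff(names(features), c("sample_id", "label"))])
  } else {
    x <- as.matrix(features)
    ids <- folds$sample_id
    if (is.null(labels)) stop("labels required when features is a matrix")
  }
  stopifnot(nrow(x) == length(folds$fold), length(labels) == nrow(x))
  out <- vector("list", folds$k)
  pca_info <- data.frame(fold = seq_len(folds$k), n_retained = NA_integer_,
                         cum_variance = NA_real_)
  for (f in seq_len(folds$k)) {
    tr <- folds$fold != f
    te <- !tr
    if (length(unique(labels[tr])) < 2)
      stop(sprintf("fold %d: training data contains a single class", f))
    pca <- fit_pca(x[tr, , drop = FALSE], cfg$variance_target)
    comp_tr <- predict(pca, x[tr, , drop = FALSE])
    svm <- fit_svm(comp_tr, labels[tr], cfg$kernel_degree, cfg$regularisation)
    sc <- predict(svm, predict(pca, x[te, , drop = FALSE]))
    pca_info$n_retained[f] <- pca$n_retained
    pca_info$cum_variance[f] <-
      sum(pca$explained_variance_ratios[seq_len(pca$n_retained)])
    out[[f]] <- score_table(ids[te], cfg$model_id, f, labels[te],
                            pmin(pmax(sc, 0), 1))
  }
  res <- do.call(rbind, out)
  class(res) <- c("score_table", "data.frame")
  attr(res, "pca_info") <- pca_info
  res
}

#' Write / read a score table CSV
#' @param scores a `score_table`
#' @param path CSV path
#' @return `path` (write) or a `score_table` (read)
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  score_table(df$sample_id, df$model_id, df$fold, df$true_label, df$score)
}
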