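# ROC and accuracy evaluation: empirical (Mann-Whitney) AUC with
# DeLong-style standard error, a re-implemented binormal
# ordinal-likelihood maximum-likelihood ROC fit (the model family behind
# legacy ROC-fitting programs), paired DeLong AUC comparison, and
# thresholded overall accuracy with per-fold spread.

roc_obj <- function(scores) {
  if (length(unique(scores$true_label)) < 2)
    stop("both classes must be present")
  pROC::roc(response = factor(scores$true_label,
                              levels = c("benign", "malignant")),
            predictor = scores$score, levels = c("benign", "malignant"),
            direction = "<", quiet = TRUE)
}

#' Empirical ROC analysis
#'
#' AUC equals the Mann-Whitney probability that a malignant score exceeds
#' a benign one (ties counted half); the standard error is the DeLong
#' paired-components estimator.
#'
#' @param scores a [score_table()]
#' @return an object of class `roc_result`: `auc`, `auc_std`, `method`,
#'   `curve` (data frame of fpr, tpr)
#' @export
empirical_auc <- function(scores) {
  r <- roc_obj(scores)
  cc <- pROC::coords(r, "all", ret = c("specificity", "sensitivity"),
                     transpose = FALSE)
  curve <- data.frame(fpr = 1 - cc$specificity, tpr = cc$sensitivity)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  curve <- rbind(data.frame(fpr = 0, tpr = 0), curve,
                 data.frame(fpr = 1, tpr = 1))
  curve <- unique(curve)
  structure(list(auc = as.numeric(pROC::auc(r)),
                 auc_std = suppressWarnings(sqrt(pROC::var(r))),
                 method = "empirical",
                 binormal_a = NULL, binormal_b = NULL,
                 curve = curve, convergence_warning = FALSE),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s): AUC = %.4f +/- %.4f%s\n", x$method, x$auc,
              x$auc_std,
              if (isTRUE(x$convergence_warning)) "  [convergence warning]" else ""))
  if (!is.null(x$binormal_a))
    cat(sprintf("  binormal parameters: a = %.4f, b = %.4f\n",
                x$binormal_a, x$binormal_b))
  invisible(x)
}

#' Binormal maximum-likelihood ROC fit
#'
#' Scores are binned into `n_bins` ordered categories (equal-quantile
#' bins over the pooled scores) and the binormal model -- benign latent
#' N(0,1), malignant latent N(a/b, 1/b) so that `TPR =
#' Phi(a + b * qnorm(FPR))` -- is fitted by maximising the
#' ordinal-category likelihood over (a, b, category cutpoints).
#' `AUC = Phi(a / sqrt(1 + b^2))`; its standard error comes from the
#' inverse observed information via the delta method.
#'
#' @param scores a [score_table()]
#' @param n_bins number of ordinal score categories
#' @return an object of class `roc_result` with `binormal_a`,
#'   `binormal_b` and a smooth fitted `curve`; degenerate inputs
#'   (perfect separation) report AUC 1.0 with `convergence_warning`
#' @export
binormal_fit <- function(scores, n_bins = 10L) {
  lab <- scores$true_label
  if (length(unique(lab)) < 2) stop("both classes must be present")
  s <- scores$score
  if (max(s[lab == "benign"]) < min(s[lab == "malignant"])) {
    warning("perfect separation: binormal fit is degenerate")
    return(structure(list(auc = 1.0, auc_std = NA_real_,
                          method = "binormal_mle",
                          binormal_a = Inf, binormal_b = 1,
                          curve = data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1)),
                          convergence_warning = TRUE), class = "roc_result"))
  }
  breaks <- unique(stats::quantile(s, probs = seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE))
  cat_idx <- cut(s, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  K <- max(cat_idx)
  if (K < 2) stop("scores collapse into a single ordinal category")
  n0 <- tabulate(cat_idx[lab == "benign"], K)
  n1 <- tabulate(cat_idx[lab == "malignant"], K)

  # initial values: cutpoints from benign cumulative rates, a from the
  # empirical AUC, b = 1
  cum0 <- pmin(pmax(cumsum(n0)[-K] / sum(n0), 0.01), 0.99)
  c0 <- stats::qnorm(cum0)
  c0 <- cummax(c0 + seq_along(c0) * 1e-6)
  auc_emp <- auc_mann_whitney(s, lab)
  a0 <- stats::qnorm(pmin(pmax(auc_emp, 0.02), 0.98)) * sqrt(2)
  theta0 <- c(a0, 0, c0[1], log(pmax(diff(c0), 1e-3)))

  unpack <- function(theta) {
    a <- theta[1]; b <- exp(theta[2])
    cuts <- cumsum(c(theta[3], exp(theta[4:length(theta)])))
    list(a = a, b = b, cuts = cuts)
  }
  nll <- function(theta) {
    p <- unpack(theta)
    e0 <- c(stats::pnorm(p$cuts), 1)
    p0 <- diff(c(0, e0))
    e1 <- c(stats::pnorm(p$b * p$cuts - p$a), 1)
    p1 <- diff(c(0, e1))
    -sum(n0 * log(pmax(p0, 1e-300))) - sum(n1 * log(pmax(p1, 1e-300)))
  }
  fit <- stats::optim(theta0, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  p <- unpack(fit$par)
  auc <- stats::pnorm(p$a / sqrt(1 + p$b^2))
  conv_warn <- fit$convergence != 0 || abs(p$a) > 10

  auc_std <- NA_real_
  cov2 <- try(solve(fit$hessian)[1:2, 1:2], silent = TRUE)
  if (!inherits(cov2, "try-error") && all(is.finite(cov2))) {
    u <- p$a / sqrt(1 + p$b^2)
    # gradient wrt (a, log b)
    da <- stats::dnorm(u) / sqrt(1 + p$b^2)
    dlb <- stats::dnorm(u) * (-p$a * p$b^2 / (1 + p$b^2)^1.5)
    g <- c(da, dlb)
    v <- as.numeric(t(g) %*% cov2 %*% g)
    if (is.finite(v) && v >= 0) auc_std <- sqrt(v)
  }
  fpr <- seq(0.001, 0.999, length.out = 199)
  curve <- data.frame(fpr = c(0, fpr, 1),
                      tpr = c(0, stats::pnorm(p$a + p$b * stats::qnorm(fpr)), 1))
  structure(list(auc = as.numeric(auc), auc_std = auc_std,
                 method = "binormal_mle",
                 binormal_a = p$a, binormal_b = p$b,
                 curve = curve, convergence_warning = conv_warn),
            class = "roc_result")
}

# Mann-Whitney AUC of raw scores (ties counted half) via rank sums.
auc_mann_whitney <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == "malignant"); n0 <- sum(label == "benign")
  (sum(r[label == "malignant"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired DeLong comparison of two AUCs
#'
#' Two-sided p-value for the difference between the AUCs of two score
#' tables over the same samples, using the paired pairwise-component
#' covariance.
#'
#' @param scores_a,scores_b [score_table()]s over identical samples
#' @return two-sided p-value
#' @export
compare_auc <- function(scores_a, scores_b) {
  if (!setequal(scores_a$sample_id, scores_b$sample_id))
    stop("score tables must cover the same samples")
  b <- scores_b[match(scores_a$sample_id, scores_b$sample_id), ]
  if (!identical(scores_a$true_label, b$true_label))
    stop("true labels disagree between score tables")
  if (isTRUE(all.equal(scores_a$score, b$score))) return(1.0)
  ra <- roc_obj(scores_a); rb <- roc_obj(b)
  tst <- suppressWarnings(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE))
  pv <- as.numeric(tst$p.value)
  if (!is.finite(pv)) pv <- 1.0
  pv
}

#' Overall accuracy at an operating threshold
#'
#' A sample is called malignant when `score > threshold` (a score exactly
#' at the threshold is called benign).  `ACC = (TM + TB) / N` where TM
#' and TB count correctly classified malignant and benign samples.
#'
#' @param scores a [score_table()]
#' @param threshold operating threshold
#' @return an object of class `accuracy_result`: `acc`, `threshold`,
#'   `tm`, `tb`, `n`
#' @export
accuracy_at_threshold <- function(scores, threshold = 0.5) {
  if (!nrow(scores)) stop("empty score table")
  pred_mal <- scores$score > threshold
  tm <- sum(pred_mal & scores$true_label == "malignant")
  tb <- sum(!pred_mal & scores$true_label == "benign")
  structure(list(acc = (tm + tb) / nrow(scores), threshold = threshold,
                 tm = tm, tb = tb, n = nrow(scores)),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("ACC = %.4f at threshold %g (TM = %d, TB = %d, N = %d)\n",
              x$acc, x$threshold, x$tm, x$tb, x$n))
  invisible(x)
}

#' Per-fold accuracy
#'
#' @param scores a [score_table()] with populated folds
#' @param threshold operating threshold
#' @return data frame (fold, acc, tm, tb, n) with attributes `acc_mean`
#'   and `acc_sd`
#' @export
per_fold_accuracy <- function(scores, threshold = 0.5) {
  folds <- sort(unique(scores$fold))
  rows <- lapply(folds, function(f) {
    a <- accuracy_at_threshold(scores[scores$fold == f, ], threshold)
    data.frame(fold = f, acc = a$acc, tm = a$tm, tb = a$tb, n = a$n)
  })
  df <- do.call(rbind, rows)
  attr(df, "acc_mean") <- mean(df$acc)
  attr(df, "acc_sd") <- stats::sd(df$acc)
  df
}

#' Summary report over several models
#'
#' One row per score table: empirical and binormal AUC with standard
#' errors, overall accuracy with across-fold spread; pairwise DeLong
#' p-values in the `"auc_p_values"` attribute.
#'
#' @param score_tables named list of [score_table()]s over aligned
#'   samples
#' @param threshold accuracy operating threshold
#' @param n_bins binormal fit bins
#' @return a data frame of class `cad_report`
#' @export
summarize_models <- function(score_tables, threshold = 0.5, n_bins = 10L) {
  if (is.null(names(score_tables)))
    names(score_tables) <- vapply(score_tables,
                                  function(s) s$model_id[1], "")
  rows <- lapply(names(score_tables), function(nm) {
    st <- score_tables[[nm]]
    emp <- empirical_auc(st)
    bn <- suppressWarnings(binormal_fit(st, n_bins))
    pf <- per_fold_accuracy(st, threshold)
    data.frame(model = nm,
               auc = emp$auc, auc_std = emp$auc_std,
               auc_binormal = bn$auc, auc_binormal_std = bn$auc_std,
               acc = accuracy_at_threshold(st, threshold)$acc,
               acc_fold_mean = attr(pf, "acc_mean"),
               acc_fold_sd = attr(pf, "acc_sd"),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  k <- length(score_tables)
  pmat <- matrix(NA_real_, k, k,
                 dimnames = list(names(score_tables), names(score_tables)))
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      pv <- try(compare_auc(score_tables[[i]], score_tables[[j]]),
                silent = TRUE)
      if (!inherits(pv, "try-error")) pmat[i, j] <- pmat[j, i] <- pv
    }
  }
  attr(report, "auc_p_values") <- pmat
  class(report) <- c("cad_report", "data.frame")
  report
}

#' @export
print.cad_report <- function(x, ...) {
  cat("CAD model comparison\n")
  df <- as.data.frame(x)
  df$`AUC +/- STD` <- sprintf("%.3f +/- %.3f", df$auc, df$auc_std)
  df$`ACC (%) +/- STD` <- sprintf("%.2f +/- %.2f", 100 * df$acc,
                                  100 * df$acc_fold_sd)
  print(df[c("model", "AUC +/- STD", "ACC (%) +/- STD")], row.names = FALSE)
  invisible(x)
}

#' Write a model-comparison report as CSV and markdown
#'
#' @param report a `cad_report`
#' @param path base path; writes `<path>.csv` and `<path>.md`
#' @return base path, invisibly
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), paste0(path, ".csv"),
                   row.names = FALSE)
  md <- c("| Model | AUC +/- STD | Binormal AUC +/- STD | ACC (%) +/- STD |",
          "|---|---|---|---|",
          sprintf("| %s | %.3f +/- %.3f | %.3f +/- %.3f | %.2f +/- %.2f |",
                  report$model, report$auc, report$auc_std,
                  report$auc_binormal, report$auc_binormal_std,
                  100 * report$acc, 100 * report$acc_fold_sd))
  writeLines(md, paste0(path, ".md"))
  invisible(path)
}
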