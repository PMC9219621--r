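test_that("fold assignment is a stratified deterministic partition", {
  labs <- rep(c("malignant", "benign"), 10)
  f <- make_folds(labs, k = 10, rng_seed = 1)
  per_fold <- table(f$fold, labs)
  expect_true(all(per_fold == 1))
  expect_setequal(f$fold, 1:10)

  f2 <- make_folds(labs, k = 10, rng_seed = 1)
  expect_identical(f$fold, f2$fold)
  f3 <- make_folds(labs, k = 10, rng_seed = 2)
  expect_false(identical(f$fold, f3$fold))
  expect_error(make_folds(labs, k = 30, rng_seed = 1), "exceed")

  # unstratified is still an exact partition
  f4 <- make_folds(labs, k = 7, rng_seed = 3, stratified = FALSE)
  expect_equal(sort(unique(f4$fold)), 1:7)
  expect_length(f4$fold, 20)
})

test_that("PCA retains the minimal component set for the variance target", {
  withr::with_seed(11, {
    basis <- qr.Q(qr(matrix(rnorm(8 * 3), 8, 3)))
    x <- matrix(rnorm(200 * 3), 200, 3) %*% t(basis) +
      matrix(rnorm(200 * 8, sd = 1e-8), 200, 8)
    p <- fit_pca(x, 0.95)
    expect_lte(p$n_retained, 3)

    iso <- matrix(rnorm(10000 * 10), ncol = 10)
    expect_equal(fit_pca(iso, 0.95)$n_retained, 10L)

    # orthonormality and reconstruction through all components
    g <- matrix(rnorm(60 * 6), 60, 6)
    pg <- fit_pca(g)
    expect_equal(crossprod(pg$components), diag(ncol(pg$components)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    z <- predict(pg, g, n_components = ncol(pg$components), whiten = FALSE)
    zs <- sweep(sweep(g, 2, pg$feature_means), 2, pg$feature_scales, "/")
    expect_equal(z %*% t(pg$components), zs, tolerance = 1e-8,
                 ignore_attr = TRUE)
  })
})

test_that("zero-variance features are dropped with a message", {
  withr::with_seed(2, {
    x <- cbind(matrix(rnorm(40), 20, 2), 5)
    colnames(x) <- c("a", "b", "konst")
    expect_message(p <- fit_pca(x), "zero-variance")
    expect_false(p$keep["konst"])
  })
})

test_that("polynomial SVM separates XOR and calibrates scores to [0,1]", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c("benign", "benign", "malignant", "malignant")
  sv <- fit_svm(x, y, kernel_degree = 2, regularisation = 10)
  sc <- predict(sv, x)
  expect_true(all((sc > 0.5) == (y == "malignant")))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(fit_svm(x, rep("benign", 4)), "both classes")

  withr::with_seed(7, {
    tr <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 8), 50, 2))
    te <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 8), 50, 2))
    labs <- rep(c("benign", "malignant"), each = 50)
    sv2 <- fit_svm(tr, labs)
    acc <- mean((predict(sv2, te) > 0.5) == (labs == "malignant"))
    expect_equal(acc, 1.0)
  })
})

test_that("cross-validated scores cover every sample exactly once", {
  df <- gaussian_feature_df(n = 120, shift = 2, seed = 5)
  folds <- make_folds(df$label, k = 10, rng_seed = 9, sample_ids = df$sample_id)
  st <- cross_validated_scores(df, folds = folds)
  expect_setequal(st$sample_id, df$sample_id)
  expect_equal(nrow(st), 120)
  expect_true(all(st$score >= 0 & st$score <= 1))
  # fold column matches the assignment
  expect_equal(st$fold, folds$fold[match(st$sample_id, folds$sample_id)])
  # informative features produce a high AUC
  expect_gt(empirical_auc(st)$auc, 0.85)
  # per-fold PCA always satisfies the variance criterion
  info <- attr(st, "pca_info")
  expect_true(all(info$cum_variance >= 0.95))
})

test_that("label permutation collapses performance to chance", {
  df <- gaussian_feature_df(n = 400, seed = 6)
  withr::with_seed(8, df$label <- sample(df$label))
  folds <- make_folds(df$label, k = 10, rng_seed = 10,
                      sample_ids = df$sample_id)
  st <- cross_validated_scores(df, folds = folds)
  auc <- empirical_auc(st)$auc
  expect_gt(auc, 0.42); expect_lt(auc, 0.58)
})

test_that("duplicating every feature column leaves CV scores unchanged", {
  df <- gaussian_feature_df(n = 80, p = 10, seed = 4)
  folds <- make_folds(df$label, k = 5, rng_seed = 2, sample_ids = df$sample_id)
  x <- df[setdiff(names(df), c("sample_id", "label"))]
  dup <- cbind(df[c("sample_id", "label")], x, stats::setNames(x, paste0(names(x), "_dup")))
  s1 <- cross_validated_scores(df, folds = folds)
  s2 <- cross_validated_scores(dup, folds = folds)
  expect_equal(s1$score, s2$score, tolerance = 1e-6)
})

test_that("a training fold with one class is rejected", {
  df <- gaussian_feature_df(n = 12, seed = 3)
  df$label <- c(rep("malignant", 11), "benign")
  folds <- make_folds(df$label, k = 6, rng_seed = 1, sample_ids = df$sample_id)
  expect_error(cross_validated_scores(df, folds = folds), "single class")
})

test_that("score tables round-trip through CSV", {
  st <- random_score_table(20, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_table(st, path)
  back <- read_score_table(path)
  expect_equal(back$score, st$score)
  expect_equal(back$sample_id, st$sample_id)
  expect_error(score_table("a", "m", 1, "benign", 1.4), "score")
})
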