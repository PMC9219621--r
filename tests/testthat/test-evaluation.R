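pairwise_auc_oracle <- function(score, label) {
  mal <- score[label == "malignant"]; ben <- score[label == "benign"]
  mean(outer(mal, ben, ">") + 0.5 * outer(mal, ben, "=="))
}

test_that("empirical AUC equals the Mann-Whitney pairwise probability", {
  st <- score_table(1:4, "m", 1, c("malignant", "malignant", "benign", "benign"),
                    c(0.9, 0.8, 0.2, 0.1))
  expect_equal(empirical_auc(st)$auc, 1.0)

  withr::with_seed(21, {
    for (i in 1:30) {
      n <- sample(10:50, 1)
      labs <- c("malignant", "benign",
                sample(c("malignant", "benign"), n - 2, replace = TRUE))
      sc <- round(runif(n), 2)           # coarse grid forces ties
      st <- score_table(seq_len(n), "m", 1, labs, sc)
      expect_equal(empirical_auc(st)$auc, pairwise_auc_oracle(sc, labs),
                   tolerance = 1e-12)
    }
  })
  expect_error(empirical_auc(score_table(1:3, "m", 1,
                                         rep("benign", 3), c(.1, .2, .3))),
               "both classes")
})

test_that("AUC is invariant under strictly increasing transforms and null-centred", {
  withr::with_seed(22, {
    labs <- sample(rep(c("malignant", "benign"), 500))
    sc <- runif(1000)
    st <- score_table(1:1000, "m", 1, labs, sc)
    a <- empirical_auc(st)$auc
    expect_gt(a, 0.45); expect_lt(a, 0.55)
    st2 <- st; st2$score <- plogis(5 * qlogis(pmin(pmax(sc, 1e-9), 1 - 1e-9)))
    expect_equal(empirical_auc(st2)$auc, a)
  })
  # curve endpoints and monotonicity
  st <- random_score_table(50, seed = 7)
  cv <- empirical_auc(st)$curve
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0)); expect_true(all(diff(cv$tpr) >= 0))
})

test_that("binormal fit recovers identical and degenerate configurations", {
  withr::with_seed(23, {
    sc <- plogis(rnorm(4000))
    labs <- rep(c("malignant", "benign"), 2000)
    st <- score_table(1:4000, "m", 1, labs, sc)
    fit <- binormal_fit(st)
    expect_lt(abs(fit$auc - 0.5), 0.02)
    expect_true(all(diff(fit$curve$tpr) >= -1e-12))
    expect_true(all(fit$curve$tpr >= 0 & fit$curve$tpr <= 1))
  })
  sep <- score_table(1:20, "m", 1, rep(c("malignant", "benign"), each = 10),
                     c(runif(10, 0.8, 1), runif(10, 0, 0.2)))
  expect_warning(fit <- binormal_fit(sep), "separation")
  expect_equal(fit$auc, 1.0)
  expect_true(fit$convergence_warning)
})

test_that("paired DeLong comparison behaves at the extremes", {
  a <- random_score_table(100, seed = 9)
  expect_equal(compare_auc(a, a), 1.0)

  withr::with_seed(24, {
    labs <- rep(c("malignant", "benign"), each = 200)
    perfect <- score_table(1:400, "A", 1, labs,
                           ifelse(labs == "malignant", runif(400, .8, 1),
                                  runif(400, 0, .2)))
    noise <- score_table(1:400, "B", 1, labs, runif(400))
    expect_lt(compare_auc(perfect, noise), 0.001)
    for (i in 1:5) {
      x <- score_table(1:60, "A", 1, rep(c("malignant", "benign"), 30),
                       runif(60))
      y <- score_table(1:60, "B", 1, rep(c("malignant", "benign"), 30),
                       runif(60))
      p <- compare_auc(x, y)
      expect_gte(p, 0); expect_lte(p, 1)
    }
  })
  b <- random_score_table(50, seed = 10)
  b$sample_id <- paste0("x", b$sample_id)
  expect_error(compare_auc(a, b), "same samples")
})

test_that("threshold accuracy counts the confusion matrix exactly", {
  st <- score_table(1:2, "m", 1, c("malignant", "benign"), c(0.9, 0.1))
  expect_equal(accuracy_at_threshold(st)$acc, 1.0)

  labs <- c(rep("malignant", 5), rep("benign", 5))
  sc <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1, 0.2, 0.3, 0.4, 0.9)  # TM=3, TB=4
  st2 <- score_table(1:10, "m", 1, labs, sc)
  r <- accuracy_at_threshold(st2)
  expect_equal(r$tm, 3); expect_equal(r$tb, 4); expect_equal(r$acc, 0.7)

  # a malignant sample exactly at the threshold is called benign
  st3 <- score_table(1:2, "m", 1, c("malignant", "benign"), c(0.5, 0.5))
  r3 <- accuracy_at_threshold(st3, 0.5)
  expect_equal(r3$tm, 0); expect_equal(r3$tb, 1); expect_equal(r3$acc, 0.5)

  withr::with_seed(25, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      labs <- sample(c("malignant", "benign"), n, replace = TRUE)
      sc <- runif(n)
      st <- score_table(seq_len(n), "m", 1, labs, sc)
      oracle <- mean(ifelse(sc > 0.5, "malignant", "benign") == labs)
      expect_equal(accuracy_at_threshold(st)$acc, oracle)
    }
  })
})

test_that("per-fold accuracies aggregate consistently", {
  labs <- rep(c("malignant", "benign"), 20)
  sc <- rep(c(0.9, 0.1), 20)
  st <- score_table(1:40, "m", rep(1:4, each = 10), labs, sc)
  pf <- per_fold_accuracy(st)
  expect_equal(attr(pf, "acc_sd"), 0)
  expect_equal(attr(pf, "acc_mean"), accuracy_at_threshold(st)$acc)

  withr::with_seed(26, {
    n <- 400
    labs <- sample(rep(c("malignant", "benign"), n / 2))
    st <- score_table(1:n, "m", rep(1:10, each = n / 10), labs, runif(n))
    pf <- per_fold_accuracy(st)
    expect_equal(attr(pf, "acc_mean"), accuracy_at_threshold(st)$acc,
                 tolerance = 1e-12)      # equal fold sizes: weighted = pooled
    binom_sd <- sqrt(0.25 / (n / 10))
    expect_true(all(abs(pf$acc - 0.5) <= 3 * binom_sd + 1e-9))
  })
})

test_that("the model summary report preserves quality ordering", {
  withr::with_seed(27, {
    labs <- rep(c("malignant", "benign"), each = 150)
    make_model <- function(d, id) {
      score_table(1:300, id, rep_len(1:5, 300), labs,
                  plogis(rnorm(300, ifelse(labs == "malignant", d, 0))))
    }
    tables <- list(weak = make_model(0.3, "weak"),
                   mid = make_model(1.2, "mid"),
                   strong = make_model(3, "strong"))
    rep <- suppressWarnings(summarize_models(tables))
    expect_equal(nrow(rep), 3)
    expect_true(rep$auc["weak" == rep$model] < rep$auc[rep$model == "mid"])
    expect_true(rep$auc[rep$model == "mid"] < rep$auc[rep$model == "strong"])
    expect_equal(rep$auc[rep$model == "mid"],
                 empirical_auc(tables$mid)$auc)
    pv <- attr(rep, "auc_p_values")
    expect_lt(pv["weak", "strong"], 0.01)

    one <- suppressWarnings(summarize_models(tables["mid"]))
    expect_equal(nrow(one), 1)
  })
})
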