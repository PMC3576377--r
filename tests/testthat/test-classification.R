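test_that("stratified folds balance both total and per-class sizes", {
  y <- rep(c("pd", "control"), c(50, 42))
  f <- stratified_folds(y, k = 10, seed = 4)
  sizes <- table(f)
  expect_true(all(sizes %in% 9:10))
  per_class <- table(f, y)
  expect_true(all(per_class[, "pd"] == 5))
  expect_true(all(per_class[, "control"] %in% 4:5))
  ## 20/20 with k = 10: exactly 2 + 2 per fold
  f2 <- stratified_folds(rep(c("pd", "control"), each = 20), k = 10, seed = 1)
  expect_true(all(table(f2, rep(c("pd", "control"), each = 20)) == 2))
  ## deterministic in the seed
  expect_identical(f, stratified_folds(y, k = 10, seed = 4))
  expect_false(identical(f, stratified_folds(y, k = 10, seed = 5)))
  expect_error(stratified_folds(rep(c("pd", "control"), c(5, 50)), k = 10),
               "fewer than k")
})

test_that("report metrics reproduce the worked validation confusion", {
  m <- classification_metrics(c(tp = 32, fn = 10, tn = 33, fp = 6))
  expect_equal(m$rounded$sensitivity, 76L)
  expect_equal(m$rounded$specificity, 85L)
  expect_equal(m$rounded$ppv, 84L)
  expect_equal(m$balanced_rate, (100 * 32 / 42 + 100 * 33 / 39) / 2)
  ## symmetric degenerate counts
  m50 <- classification_metrics(c(tp = 5, fn = 5, tn = 7, fp = 7))
  expect_equal(m50$sensitivity, 50)
  expect_equal(m50$specificity, 50)
  expect_equal(m50$balanced_rate, 50)
  expect_equal(classification_metrics(c(tp = 3, fn = 1, tn = 5, fp = 0))$ppv, 100)
  ## metrics depend on counts only: doubling every count changes nothing
  c1 <- c(tp = 13, fn = 4, tn = 11, fp = 6)
  expect_equal(classification_metrics(c1)[1:4],
               classification_metrics(2 * c1)[1:4])
  ## label swap maps sensitivity <-> specificity
  swapped <- c(tp = c1[["tn"]], fn = c1[["fp"]], tn = c1[["tp"]], fp = c1[["fn"]])
  ms <- classification_metrics(swapped)
  m1 <- classification_metrics(c1)
  expect_equal(ms$sensitivity, m1$specificity)
  expect_equal(ms$specificity, m1$sensitivity)
  ## balanced rate = 100 - mean class error
  expect_equal(m1$balanced_rate,
               100 - (100 * 4 / 17 + 100 * 6 / 17) / 2)
  expect_error(classification_metrics(c(tp = 0, fn = 0, tn = 5, fp = 1)),
               "both classes")
})

test_that("all four classifier kinds separate a 1-D separable problem", {
  X <- matrix(c(rnorm(20, -3, 0.3), rnorm(20, 3, 0.3)), ncol = 1)
  y <- rep(c("control", "pd"), each = 20)
  for (kind in c("lda", "adaboost", "svm_linear", "svm_rbf")) {
    spec <- classifier_spec(kind, cost = 10)
    model <- train_classifier(spec, X, y)
    expect_equal(mean(predict(model, X) == y), 1.0, info = kind)
  }
})

test_that("the stump booster agrees with an exhaustive hand-rolled booster", {
  ## XOR layout: no single stump beats chance, so one boosting round
  ## cannot exceed 75 % training accuracy
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c("pd", "pd", "control", "control")
  m1 <- train_classifier(classifier_spec("adaboost", iterations = 1), X, y)
  expect_lte(mean(predict(m1, X) == y), 0.75)
  ## staircase problems need several stumps; compare the full boosted
  ## prediction against the independent oracle on random small datasets
  set.seed(77)
  for (i in 1:10) {
    n <- 30
    Xr <- matrix(rnorm(n * 3), n, 3)
    yr <- ifelse(Xr[, 1] + 0.8 * sign(Xr[, 2]) + rnorm(n, sd = 0.3) > 0,
                 "pd", "control")
    if (length(unique(yr)) < 2) next
    yy <- ifelse(yr == sort(unique(yr))[2], 1, -1)
    for (iters in c(1, 3, 10)) {
      model <- train_classifier(classifier_spec("adaboost", iterations = iters),
                                Xr, yr)
      got <- ifelse(predict(model, Xr) == sort(unique(yr))[2], 1, -1)
      want <- oracle_adaboost_predict(Xr, yy, iters)
      expect_equal(got, want, info = sprintf("iters=%d rep=%d", iters, i))
    }
  }
})

test_that("LDA approaches the closed-form Bayes error on Gaussian classes", {
  set.seed(2001)
  n <- 2000
  delta <- 1.5                      # Mahalanobis distance between means
  X <- matrix(rnorm(2 * n), ncol = 2)
  y <- rep(c("control", "pd"), each = n / 2)
  X[y == "pd", 1] <- X[y == "pd", 1] + delta
  model <- train_classifier(classifier_spec("lda"), X, y)
  ## error on an independent draw from the same population
  X2 <- matrix(rnorm(2 * n), ncol = 2)
  X2[y == "pd", 1] <- X2[y == "pd", 1] + delta
  err <- mean(predict(model, X2) != y)
  bayes <- pnorm(-delta / 2)
  expect_lt(abs(err - bayes), 0.03)
})

test_that("LDA survives singular covariance via shrinkage", {
  X <- cbind(rep(c(0, 1), each = 10), rep(c(0, 1), each = 10))  # rank 1
  y <- rep(c("control", "pd"), each = 10)
  model <- train_classifier(classifier_spec("lda"), X, y)
  expect_equal(mean(predict(model, X) == y), 1.0)
})

test_that("cross-validation is reproducible and honest", {
  set.seed(60)
  n <- 200
  X <- matrix(rnorm(n * 20), n, 20)
  y_null <- sample(rep(c("pd", "control"), each = n / 2))
  ## permuted-label null stays near chance
  r0 <- cross_validate(X, y_null, classifier_spec("lda"), k = 10, seed = 17)
  expect_gte(r0$metrics$balanced_rate, 40)
  expect_lte(r0$metrics$balanced_rate, 60)
  ## perfectly separable features reach 100 %
  Xs <- X
  y <- rep(c("pd", "control"), each = n / 2)
  Xs[, 1] <- ifelse(y == "pd", 5, -5) + rnorm(n, sd = 0.1)
  rs <- cross_validate(Xs, y, classifier_spec("lda"), k = 10, seed = 17)
  expect_equal(rs$metrics$balanced_rate, 100)
  ## bit-reproducible under a fixed seed
  r1 <- cross_validate(Xs, y, classifier_spec("lda"), k = 10, seed = 17)
  expect_identical(rs$fold_counts, r1$fold_counts)
  ## pooled counts equal the fold sums and cover everyone once
  expect_equal(unname(rs$pooled), unname(colSums(as.matrix(rs$fold_counts))))
  expect_equal(sum(rs$pooled), n)
})

test_that("per-fold selection and imputation run inside cross-validation", {
  d <- planted_noise_data(seed = 11, n = 60, p_noise = 29)
  X <- d$X
  X[sample(length(X), 50)] <- NA     # scattered missing values
  r <- cross_validate(X, d$y, classifier_spec("lda"),
                      selection = list(ig_prefilter = 15, patience = 2,
                                       max_k = 5),
                      k = 5, seed = 2)
  expect_equal(r$metrics$balanced_rate, 100)
  expect_length(r$selected, 5)
  ## the planted column is chosen in every fold
  expect_true(all(vapply(r$selected, function(s) 17 %in% s, logical(1))))
  ## fixed-subset evaluation short-circuits selection
  rf <- cross_validate(X, d$y, classifier_spec("lda"),
                       selection = list(fixed_subset = 17), k = 5, seed = 2)
  expect_equal(rf$metrics$balanced_rate, 100)
})
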