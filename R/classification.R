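#' Classifier specification
#'
#' @param kind One of `"lda"` (pooled-covariance linear discriminant with
#'   diagonal shrinkage), `"adaboost"` (discrete AdaBoost.M1 over depth-1
#'   threshold stumps), `"svm_linear"` or `"svm_rbf"`.
#' @param iterations AdaBoost boosting rounds.
#' @param cost SVM cost grid; a single value disables the inner grid
#'   search.
#' @param gamma RBF kernel width grid; `NULL` means `1/ncol(X)` scaled by
#'   `c(0.5, 1, 2)` at training time.
#' @param standardize Z-score columns using training statistics; defaults
#'   to `TRUE` except for AdaBoost, whose stump thresholds are
#'   scale-equivariant.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("lda", "adaboost", "svm_linear", "svm_rbf"),
                            iterations = 10,
                            cost = c(1, 5, 10, 15, 20, 25, 30),
                            gamma = NULL, standardize = NULL) {
  kind <- match.arg(kind)
  stopifnot(iterations >= 1, length(cost) >= 1, all(cost > 0),
            is.null(gamma) || all(gamma > 0))
  if (is.null(standardize)) standardize <- kind != "adaboost"
  structure(list(kind = kind, iterations = iterations, cost = cost,
                 gamma = gamma, standardize = standardize),
            class = "classifier_spec")
}

#' Stratified fold assignment
#'
#' Splits samples into `k` folds such that fold sizes differ by at most
#' one and each class's per-fold counts differ by at most one (classes are
#' dealt evenly, remainders going to the currently smallest folds).
#' Deterministic given `seed`.
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, one per sample.
#' @export
stratified_folds <- function(y, k = 10, seed = 1) {
  y <- as.character(y)
  tab <- table(y)
  if (min(tab) < k) {
    stop(sprintf("smallest class has %d members, fewer than k = %d folds",
                 min(tab), k))
  }
  folds <- integer(length(y))
  sizes <- integer(k)
  set.seed(seed)
  for (cl in names(sort(tab, decreasing = TRUE))) {
    idx <- sample(which(y == cl))
    n_c <- length(idx)
    base <- n_c %/% k
    rem <- n_c %% k
    cnt <- rep(base, k)
    if (rem > 0) {
      extra <- order(sizes, seq_len(k))[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    fold_ids <- rep(seq_len(k), times = cnt)
    folds[idx] <- fold_ids
    sizes <- sizes + cnt
  }
  folds
}

standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(X, st) {
  sweep(sweep(X, 2, st$center, "-"), 2, st$scale, "/")
}

## ---- LDA: pooled covariance with diagonal shrinkage ------------------------

fit_lda <- function(X, y, eps = 1e-4) {
  classes <- sort(unique(y))
  mus <- lapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  n <- nrow(X)
  p <- ncol(X)
  S <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    Xi <- X[y == classes[i], , drop = FALSE]
    Xi <- sweep(Xi, 2, mus[[i]], "-")
    S <- S + crossprod(Xi)
  }
  S <- S / max(1, n - length(classes))
  shrink <- eps * max(mean(diag(S)), .Machine$double.eps)
  S <- S + diag(shrink, p)
  Sinv <- solve(S)
  priors <- as.numeric(table(factor(y, classes)) / n)
  list(classes = classes, mus = mus, Sinv = Sinv, priors = priors)
}

predict_lda <- function(fit, X) {
  scores <- sapply(seq_along(fit$classes), function(i) {
    mu <- fit$mus[[i]]
    as.numeric(X %*% (fit$Sinv %*% mu)) -
      0.5 * as.numeric(t(mu) %*% fit$Sinv %*% mu) + log(fit$priors[i])
  })
  scores <- matrix(scores, nrow = nrow(X))
  fit$classes[max.col(scores, ties.method = "first")]
}

## ---- discrete AdaBoost.M1 over depth-1 threshold stumps --------------------

## best weighted stump: h(x) = polarity * sign(x_j - t), candidates at
## midpoints between distinct consecutive sorted values (plus all-one-side)
fit_stump <- function(X, yy, w) {
  best <- list(err = Inf, j = 1L, t = -Inf, pol = 1)
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xs <- X[ord, j]
    sw <- w[ord] * yy[ord]
    ## err(t) for rule "+1 if x > t": sum w over (y=+1, x<=t) + (y=-1, x>t)
    w_pos_left <- cumsum(pmax(sw, 0))
    w_neg_left <- cumsum(pmax(-sw, 0))
    w_neg_tot <- sum(pmax(-sw, 0))
    cut_ok <- c(xs[-length(xs)] < xs[-1], TRUE)   # valid split points
    err_pos <- w_pos_left + (w_neg_tot - w_neg_left)
    thr_all <- c(-Inf, xs)
    err_pos <- c(w_neg_tot, err_pos)             # t = -Inf: everything "+1"
    cut_ok <- c(TRUE, cut_ok)
    err_neg <- sum(w) - err_pos                  # flipped polarity
    for (pol in c(1, -1)) {
      ## errors rounded so that the first candidate in (feature, polarity,
      ## threshold) order deterministically wins floating-point ties
      e <- round(if (pol == 1) err_pos else err_neg, 10)
      e[!cut_ok] <- Inf
      i <- which.min(e)
      if (e[i] < best$err) {
        best <- list(err = e[i], j = j, t = thr_all[i], pol = pol)
      }
    }
  }
  best
}

stump_predict <- function(st, X) {
  st$pol * ifelse(X[, st$j] > st$t, 1, -1)
}

fit_adaboost <- function(X, y, iterations = 10) {
  classes <- sort(unique(y))
  yy <- ifelse(y == classes[2], 1, -1)
  n <- length(yy)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (t in seq_len(iterations)) {
    st <- fit_stump(X, yy, w)
    h <- stump_predict(st, X)
    err <- round(sum(w[h != yy]), 10)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- st
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * h)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(classes = classes, stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(fit, X) {
  score <- rep(0, nrow(X))
  for (i in seq_along(fit$stumps)) {
    score <- score + fit$alphas[i] * stump_predict(fit$stumps[[i]], X)
  }
  fit$classes[ifelse(score >= 0, 2, 1)]
}

## ---- SVM (e1071) with optional inner grid search ---------------------------

fit_svm <- function(X, y, spec, seed = 1) {
  kernel <- if (spec$kind == "svm_linear") "linear" else "radial"
  gammas <- if (kernel == "linear") NA
            else if (!is.null(spec$gamma)) spec$gamma
            else c(0.5, 1, 2) / ncol(X)
  grid <- expand.grid(cost = spec$cost, gamma = gammas)
  if (nrow(grid) > 1 && min(table(y)) >= 5) {
    folds <- stratified_folds(y, k = 5, seed = seed)
    pos <- sort(unique(y))[1]
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      counts <- c(tp = 0, fn = 0, tn = 0, fp = 0)
      for (f in 1:5) {
        tr <- folds != f
        m <- svm_fit_one(X[tr, , drop = FALSE], y[tr], kernel,
                         grid$cost[g], grid$gamma[g])
        pred <- as.character(stats::predict(m, X[!tr, , drop = FALSE]))
        counts <- counts + confusion_counts(y[!tr], pred, pos)
      }
      (counts["tp"] / (counts["tp"] + counts["fn"]) +
       counts["tn"] / (counts["tn"] + counts["fp"])) / 2
    }, numeric(1))
    g <- which.max(round(acc, 10))
  } else {
    g <- 1L
  }
  svm_fit_one(X, y, kernel, grid$cost[g], grid$gamma[g])
}

svm_fit_one <- function(X, y, kernel, cost, gamma) {
  args <- list(x = X, y = factor(y), kernel = kernel, cost = cost,
               scale = FALSE)
  if (!is.na(gamma)) args$gamma <- gamma
  do.call(e1071::svm, args)
}

#' Train a classifier
#'
#' Standardization (when enabled in the spec) is fitted on the training
#' data and stored with the model, so held-out samples are transformed
#' with training statistics only. LDA uses the pooled within-class
#' covariance with a diagonal shrinkage of `1e-4` times the mean diagonal
#' (degenerate covariances are thereby regularized, never fatal).
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric feature matrix (finite).
#' @param y Binary labels.
#' @param seed Seed for the SVM hyperparameter grid search.
#' @return A `gait_classifier` model with a [predict][predict.gait_classifier]
#'   method.
#' @export
train_classifier <- function(spec, X, y, seed = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) != 2) stop("both classes must be present")
  if (!all(is.finite(X))) stop("X must be finite (impute first)")
  st <- NULL
  if (spec$standardize) {
    st <- standardizer(X)
    X <- apply_standardizer(X, st)
  }
  fit <- switch(spec$kind,
    lda = fit_lda(X, y),
    adaboost = fit_adaboost(X, y, spec$iterations),
    svm_linear = ,
    svm_rbf = fit_svm(X, y, spec, seed))
  structure(list(spec = spec, fit = fit, standardizer = st),
            class = "gait_classifier")
}

#' @rdname train_classifier
#' @param object A `gait_classifier`.
#' @param newdata Feature matrix to predict.
#' @param ... Unused.
#' @export
predict.gait_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$standardizer)) {
    X <- apply_standardizer(X, object$standardizer)
  }
  switch(object$spec$kind,
    lda = predict_lda(object$fit, X),
    adaboost = predict_adaboost(object$fit, X),
    as.character(stats::predict(object$fit, X)))
}

#' Confusion counts with a designated positive class
#'
#' @param truth,pred Label vectors; the positive class is `positive`
#'   (patients, by convention).
#' @return Named integer vector `tp, fn, tn, fp`.
#' @export
confusion_counts <- function(truth, pred, positive = "pd") {
  truth <- as.character(truth)
  pred <- as.character(pred)
  c(tp = sum(truth == positive & pred == positive),
    fn = sum(truth == positive & pred != positive),
    tn = sum(truth != positive & pred != positive),
    fp = sum(truth != positive & pred == positive))
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Report metrics from confusion counts
#'
#' Sensitivity `100 tp/(tp+fn)`, specificity `100 tn/(tn+fp)`, positive
#' predictive value `100 tp/(tp+fp)` (`NA`-flagged when no positive
#' prediction exists) and the balanced classification rate, defined as the
#' mean of sensitivity and specificity. Values are percentages; `rounded`
#' holds the integer report values (half away from zero).
#'
#' @param counts Named vector with `tp`, `fn`, `tn`, `fp` (e.g. from
#'   [confusion_counts()]).
#' @return List with `sensitivity`, `specificity`, `ppv`, `balanced_rate`
#'   (numeric percentages) and `rounded` (integer versions).
#' @examples
#' classification_metrics(c(tp = 32, fn = 10, tn = 33, fp = 6))$rounded
#' @export
classification_metrics <- function(counts) {
  tp <- counts[["tp"]]; fn <- counts[["fn"]]
  tn <- counts[["tn"]]; fp <- counts[["fp"]]
  if (tp + fn == 0 || tn + fp == 0) {
    stop("both classes must be represented in the counts")
  }
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  ppv <- if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
  bal <- (sens + spec) / 2
  out <- list(sensitivity = sens, specificity = spec, ppv = ppv,
              balanced_rate = bal)
  out$rounded <- lapply(out, function(v) {
    if (is.na(v)) NA_integer_ else as.integer(round_half_up(v))
  })
  out
}

## training-portion median imputation; all-NA columns fall back to 0
impute_median <- function(X_train, X_apply = X_train) {
  med <- apply(X_train, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X_apply))) {
    nas <- is.na(X_apply[, j])
    if (any(nas)) X_apply[nas, j] <- med[j]
  }
  X_apply
}

#' Stratified k-fold cross-validation of the selection + classification
#' pipeline
#'
#' For each fold, missing values are imputed with training-fold medians,
#' feature selection (when configured) is re-run on the training portion
#' only, the classifier is trained on the remaining folds and evaluated on
#' the held-out fold. Confusion counts are pooled over folds and the
#' report metrics are computed from the pooled counts.
#'
#' @param X Feature matrix (may contain `NA`).
#' @param y Binary labels.
#' @param spec A [classifier_spec()].
#' @param selection `NULL` (use all features), a list of arguments for
#'   [sequential_forward_selection()] (e.g.
#'   `list(ig_prefilter = 50, patience = 3, max_k = 25)`), or
#'   `list(fixed_subset = idx)` to evaluate a fixed feature subset.
#' @param k Number of folds.
#' @param seed Integer seed; fold assignment and all inner seeds derive
#'   from it.
#' @param positive Positive-class label.
#' @return A `cv_report`: `fold_counts` (per-fold confusion data frame),
#'   `pooled` counts, `metrics` (from [classification_metrics()]),
#'   `selected` (per-fold selected column indices), plus `k` and `seed`.
#' @export
cross_validate <- function(X, y, spec = classifier_spec("lda"),
                           selection = NULL, k = 10, seed = 1,
                           positive = "pd") {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) != 2) stop("both classes must be present")
  if (!positive %in% y) positive <- sort(unique(y))[1]
  folds <- stratified_folds(y, k = k, seed = seed)
  fold_counts <- matrix(0L, nrow = k, ncol = 4,
                        dimnames = list(NULL, c("tp", "fn", "tn", "fp")))
  selected <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fold_seed <- (seed + 1000003 * f) %% 2147483647L + 1L
    Xtr <- impute_median(X[tr, , drop = FALSE])
    Xte <- impute_median(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
    cols <- seq_len(ncol(X))
    if (!is.null(selection)) {
      if (!is.null(selection$fixed_subset)) {
        cols <- selection$fixed_subset
      } else {
        args <- c(list(X = Xtr, y = y[tr], spec = spec, seed = fold_seed,
                       positive = positive), selection)
        cols <- do.call(sequential_forward_selection, args)$selected
        if (!length(cols)) cols <- seq_len(ncol(X))
      }
    }
    selected[[f]] <- cols
    model <- train_classifier(spec, Xtr[, cols, drop = FALSE], y[tr],
                              seed = fold_seed)
    pred <- predict(model, Xte[, cols, drop = FALSE])
    fold_counts[f, ] <- confusion_counts(y[!tr], pred, positive)
  }
  pooled <- colSums(fold_counts)
  structure(list(fold_counts = as.data.frame(fold_counts),
                 pooled = pooled,
                 metrics = classification_metrics(pooled),
                 selected = selected, k = k, seed = seed,
                 classifier = spec$kind, positive = positive),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<cv_report> %d-fold CV, %s classifier\n",
                     "  pooled counts: tp=%d fn=%d tn=%d fp=%d\n",
                     "  balanced rate %.1f%%, sensitivity %.1f%%, ",
                     "specificity %.1f%%, PPV %.1f%%\n"),
              x$k, x$classifier,
              x$pooled[["tp"]], x$pooled[["fn"]],
              x$pooled[["tn"]], x$pooled[["fp"]],
              m$balanced_rate, m$sensitivity, m$specificity, m$ppv))
  invisible(x)
}
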