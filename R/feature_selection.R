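shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a feature for a binary label
#'
#' The feature is discretized into `n_bins` equal-frequency bins (tied
#' quantiles merged) and the mutual information between bin membership and
#' the class label is returned in bits: `H(Y) - sum_b p(b) H(Y | b)`.
#' Equal-frequency binning makes the score invariant under strictly
#' monotone transforms of the feature.
#'
#' @param x Numeric feature column (finite).
#' @param y Binary labels (factor, character or logical), both classes
#'   present.
#' @param n_bins Number of quantile bins.
#' @return Information gain in bits, in `[0, H(Y)]`.
#' @export
information_gain <- function(x, y, n_bins = 10) {
  y <- as.factor(as.character(y))
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (nlevels(y) != 2) stop("labels must contain exactly two classes")
  if (!all(is.finite(x))) stop("feature column must be finite (impute first)")
  hy <- shannon_entropy(table(y) / length(y))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(qs) < 2) return(0)   # constant feature: one bin, no information
  bins <- cut(x, breaks = qs, include.lowest = TRUE)
  h_cond <- 0
  for (b in levels(bins)) {
    sel <- bins == b
    nb <- sum(sel)
    if (nb == 0) next
    h_cond <- h_cond + (nb / length(x)) *
      shannon_entropy(table(y[sel]) / nb)
  }
  max(0, hy - h_cond)
}

#' Rank all feature columns by information gain
#'
#' @param X Numeric feature matrix (finite).
#' @inheritParams information_gain
#' @return Data frame with `index`, `feature` (column name) and `ig`,
#'   sorted by decreasing gain (ties: lower column index first).
#' @export
ig_rank <- function(X, y, n_bins = 10) {
  ig <- vapply(seq_len(ncol(X)), function(j) information_gain(X[, j], y, n_bins),
               numeric(1))
  ord <- order(-ig, seq_along(ig))
  data.frame(index = ord,
             feature = if (is.null(colnames(X))) as.character(ord)
                       else colnames(X)[ord],
             ig = ig[ord], row.names = NULL, stringsAsFactors = FALSE)
}

## balanced accuracy of `spec` on (X, y) under precomputed stratified folds
inner_cv_balanced_acc <- function(X, y, spec, folds, positive) {
  counts <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- train_classifier(spec, X[tr, , drop = FALSE], y[tr])
    pred <- predict(model, X[!tr, , drop = FALSE])
    counts <- counts + confusion_counts(y[!tr], pred, positive)
  }
  sens <- counts["tp"] / (counts["tp"] + counts["fn"])
  spc <- counts["tn"] / (counts["tn"] + counts["fp"])
  unname((sens + spc) / 2)
}

#' Sequential forward selection with information-gain pre-filter
#'
#' Candidates are restricted to the `ig_prefilter` features with highest
#' information gain; starting from the empty set, the candidate that
#' maximizes inner stratified cross-validated balanced accuracy is added
#' greedily (ties broken by higher information gain, then lower column
#' index). The search stops after `patience` consecutive additions without
#' improvement or at `max_k` features, and the best-accuracy prefix of the
#' greedy path is returned.
#'
#' @param X Numeric feature matrix, finite (impute missing values first).
#' @param y Binary labels.
#' @param spec A [classifier_spec()] used as the wrapper criterion.
#' @param inner_cv_folds Folds for the inner stratified CV.
#' @param ig_prefilter Number of top-gain candidates retained.
#' @param patience Consecutive non-improving additions tolerated.
#' @param max_k Maximum subset size explored.
#' @param seed Integer seed controlling the inner folds.
#' @param n_bins Bins for [information_gain()].
#' @param positive Positive-class label for balanced accuracy.
#' @return An `sfs_result` list: `ranked` (the IG ranking), `selected`
#'   (column indices of the best prefix), `trace` (inner-CV balanced
#'   accuracy after each retained addition), `path`/`path_trace` (the full
#'   greedy path before truncation).
#' @export
sequential_forward_selection <- function(X, y, spec = classifier_spec("lda"),
                                         inner_cv_folds = 5,
                                         ig_prefilter = 50, patience = 3,
                                         max_k = 25, seed = 1, n_bins = 10,
                                         positive = "pd") {
  X <- as.matrix(X)
  y <- as.character(y)
  if (!all(is.finite(X))) stop("X must be finite after imputation")
  if (length(unique(y)) != 2) stop("labels must contain exactly two classes")
  if (!positive %in% y) positive <- sort(unique(y))[1]
  if (min(table(y)) < inner_cv_folds) {
    stop("fewer samples than inner folds in one class")
  }
  ranked <- ig_rank(X, y, n_bins)
  cand <- ranked$index[seq_len(min(ig_prefilter, nrow(ranked)))]
  ig_of <- numeric(ncol(X))
  ig_of[ranked$index] <- ranked$ig
  folds <- stratified_folds(y, k = inner_cv_folds, seed = seed)

  selected <- integer(0)
  trace <- numeric(0)
  best_acc <- -Inf
  best_len <- 0
  stale <- 0
  while (length(selected) < max_k && length(cand) > 0) {
    accs <- vapply(cand, function(j) {
      inner_cv_balanced_acc(X[, c(selected, j), drop = FALSE], y, spec,
                            folds, positive)
    }, numeric(1))
    r <- round(accs, 10)
    top <- which(r == max(r))
    if (length(top) > 1) {
      top <- top[order(-ig_of[cand[top]], cand[top])]
    }
    pick <- top[1]
    selected <- c(selected, cand[pick])
    trace <- c(trace, accs[pick])
    cand <- cand[-pick]
    if (accs[pick] > best_acc + 1e-12) {
      best_acc <- accs[pick]
      best_len <- length(selected)
      stale <- 0
    } else {
      stale <- stale + 1
      if (stale >= patience) break
    }
  }
  structure(list(ranked = ranked,
                 selected = selected[seq_len(best_len)],
                 trace = trace[seq_len(best_len)],
                 path = selected, path_trace = trace,
                 best_accuracy = best_acc),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("<sfs_result> %d features selected (path length %d), inner-CV balanced accuracy %.3f\n",
              length(x$selected), length(x$path), x$best_accuracy))
  invisible(x)
}

#' Write a selection report as JSON
#'
#' @param sel An `sfs_result`.
#' @param path Output path.
#' @export
write_selection_report <- function(sel, path) {
  jsonlite::write_json(
    list(ranked = sel$ranked, selected = sel$selected, trace = sel$trace),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(NULL)
}
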