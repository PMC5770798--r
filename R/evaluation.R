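#' Binary confusion counts
#'
#' @param y_true,y_pred Vectors of class labels of equal length.
#' @param positive The label counted as positive.
#' @return Object of class `confusion_counts`: list with `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true (", length(y_true), ") and y_pred (", length(y_pred),
         ") differ in length")
  }
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

## Internal: a ratio that is NA (flagged undefined) on a zero denominator
## rather than 0, so undefined folds never drag averages toward zero.
safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Threshold metrics from confusion counts
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy
#' (tp+tn)/total, precision tp/(tp+fp), and Matthews correlation
#' coefficient
#' (tp*tn - fp*fn) / sqrt((tp+fn)(tp+fp)(tn+fn)(tn+fp)).
#' Any metric with a zero denominator is returned as `NA` (flagged
#' undefined), never silently as 0.
#'
#' @param cc A [confusion()] result.
#' @return Named numeric vector with elements `sensitivity`, `specificity`,
#'   `accuracy`, `precision`, `mcc`.
#' @export
metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fn, tn + fp)))
  c(sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    accuracy    = safe_ratio(tp + tn, tp + tn + fp + fn),
    precision   = safe_ratio(tp, tp + fp),
    mcc         = if (mcc_den == 0) NA_real_
                  else (tp * tn - fp * fn) / mcc_den)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over every distinct score (ties grouped),
#' returning (FPR, TPR) points from (0,0) to (1,1).
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param y_true Labels.
#' @param positive Positive label.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, y_true, positive) {
  is_pos <- y_true == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- is_pos[ord]
  cum_tp <- cumsum(p); cum_fp <- cumsum(!p)
  last <- which(diff(s) != 0)          # last index of each tie group
  keep <- c(last, length(s))
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, cum_fp[keep] / n_neg),
             tpr = c(0, cum_tp[keep] / n_pos))
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the threshold sweep; algebraically equal to the
#' probability that a random positive outscores a random negative, ties
#' counted one half (the Mann-Whitney statistic).
#'
#' @param points A [roc_points()] data.frame, or omit and give
#'   `scores`/`y_true`/`positive` directly.
#' @inheritParams roc_points
#' @return AUC in [0, 1].
#' @export
auc_roc <- function(points = NULL, scores = NULL, y_true = NULL,
                    positive = NULL) {
  if (is.null(points)) points <- roc_points(scores, y_true, positive)
  sum(diff(points$fpr) * (head(points$tpr, -1L) + points$tpr[-1L]) / 2)
}

#' Precision-recall curve points
#'
#' @inheritParams roc_points
#' @return data.frame with columns `threshold`, `recall`, `precision`.
#' @export
pr_points <- function(scores, y_true, positive) {
  is_pos <- y_true == positive
  n_pos <- sum(is_pos)
  if (n_pos == 0L) stop("PR curve requires at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- is_pos[ord]
  cum_tp <- cumsum(p)
  keep <- c(which(diff(s) != 0), length(s))
  data.frame(threshold = s[keep],
             recall = cum_tp[keep] / n_pos,
             precision = cum_tp[keep] / keep)
}

#' Area under the precision-recall curve (average precision)
#'
#' The step-wise average-precision rule: sum over threshold steps of
#' (recall_i - recall_{i-1}) * precision_i. Trapezoidal interpolation is
#' deliberately not used, as linear interpolation in PR space is biased.
#'
#' @inheritParams auc_roc
#' @return AUC-PR in [0, 1].
#' @export
auc_pr <- function(points = NULL, scores = NULL, y_true = NULL,
                   positive = NULL) {
  if (is.null(points)) points <- pr_points(scores, y_true, positive)
  sum(diff(c(0, points$recall)) * points$precision)
}

#' Cross-validation plan
#'
#' @param scheme `"kfold"` or `"loocv"`.
#' @param k Number of folds (kfold only; ignored for loocv).
#' @param stratified Balance classes across folds to within one instance
#'   (kfold only).
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `cv_plan`.
#' @export
cv_plan <- function(scheme = c("kfold", "loocv"), k = 5L,
                    stratified = TRUE, seed = 1L) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, k = as.integer(k),
                 stratified = stratified, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Fold assignment for a cross-validation plan
#'
#' Returns an integer fold index per instance. Stratified k-fold assigns
#' each class's instances round-robin over a randomly rotated fold order,
#' so per-fold class counts differ from exact proportionality by at most 1.
#' LOOCV assigns each instance its own fold.
#'
#' @param y Label vector.
#' @param plan A [cv_plan()].
#' @return Integer vector of fold indices in 1..k (or 1..n for loocv).
#' @export
cv_folds <- function(y, plan) {
  n <- length(y)
  if (plan$scheme == "loocv") return(seq_len(n))
  k <- plan$k
  set.seed(plan$seed)
  folds <- integer(n)
  if (plan$stratified) {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(sample(k), length(idx))
    }
  } else {
    folds <- rep_len(sample(k), n)[sample(n)]
  }
  folds
}

#' A binary SVM evaluation pipeline
#'
#' Packages the fit/score pair used by [cross_validate()]: fits an SVM with
#' the given kernel on the training split (optionally after selecting
#' features on the training split only) and scores the test split with the
#' decision value for the positive class.
#'
#' @param kernel A [kernel_spec()].
#' @param positive Positive class label.
#' @param selection Optional list(technique=, k=) applied within each
#'   training fold.
#' @return Object of class `eval_pipeline` with `fit(X, y, seed)` and
#'   `score(fit, X)` functions; `score` returns list(class, score).
#' @export
svm_pipeline <- function(kernel = kernel_spec("radial"), positive = "HSP",
                         selection = NULL) {
  fit_fun <- function(X, y, seed) {
    feats <- colnames(X)
    if (!is.null(selection)) {
      rk <- rank_features(X, y == positive, technique = selection$technique,
                          seed = seed)
      feats <- select_top_k(rk, selection$k)$selected
      X <- X[, feats, drop = FALSE]
    }
    model <- fit_svm(X, y, kernel = kernel, seed = seed,
                     probability = FALSE)
    list(model = model, features = feats)
  }
  score_fun <- function(fit, X) {
    pr <- predict_classifier(fit$model, X[, fit$features, drop = FALSE],
                             decision_values = TRUE)
    score <- decision_for(pr$decision, positive)
    list(class = as.character(pr$class), score = score)
  }
  structure(list(fit = fit_fun, score = score_fun, positive = positive,
                 kernel = kernel, selection = selection),
            class = "eval_pipeline")
}

#' Cross-validate a binary pipeline
#'
#' Trains on k-1 folds, tests on the held-out fold, each instance tested
#' exactly once. Per-fold metrics are averaged (mean of fold metrics, not
#' pooled counts). AUCs are computed per fold from the pipeline's scores and
#' averaged likewise; folds whose test split lacks a class contribute `NA`
#' AUCs.
#'
#' @param X Numeric feature matrix with column names.
#' @param y Binary label vector.
#' @param pipeline An [svm_pipeline()] (or compatible fit/score pair).
#' @param plan A [cv_plan()].
#' @return List with `folds` (per-fold metric data.frame), `mean` (named
#'   vector), `assignments` (fold index per instance) and `predictions`
#'   (data.frame: index, fold, truth, call, score).
#' @export
cross_validate <- function(X, y, pipeline, plan = cv_plan()) {
  folds <- cv_folds(y, plan)
  fold_ids <- sort(unique(folds))
  positive <- pipeline$positive
  per_fold <- vector("list", length(fold_ids))
  preds <- data.frame(index = seq_along(y), fold = folds,
                      truth = as.character(y), call = NA_character_,
                      score = NA_real_)
  for (f in seq_along(fold_ids)) {
    test <- folds == fold_ids[f]
    if (length(unique(y[!test])) < 2L) {
      stop("fold ", fold_ids[f], ": a class is absent from the training",
           " split")
    }
    fit <- pipeline$fit(X[!test, , drop = FALSE], y[!test],
                        seed = plan$seed + f)
    sc <- pipeline$score(fit, X[test, , drop = FALSE])
    preds$call[test] <- sc$class
    preds$score[test] <- sc$score
    m <- metrics(confusion(y[test], sc$class, positive))
    both <- length(unique(y[test])) == 2L
    per_fold[[f]] <- c(m,
      auc_roc = if (both) auc_roc(scores = sc$score, y_true = y[test],
                                  positive = positive) else NA_real_,
      auc_pr = if (any(y[test] == positive))
                 auc_pr(scores = sc$score, y_true = y[test],
                        positive = positive) else NA_real_)
  }
  fold_df <- as.data.frame(do.call(rbind, per_fold))
  fold_df$fold <- fold_ids
  list(folds = fold_df,
       mean = colMeans(fold_df[setdiff(names(fold_df), "fold")],
                       na.rm = TRUE),
       assignments = folds,
       predictions = preds)
}

#' Balanced resampling plan
#'
#' @param n_samples Number of balanced samples to draw (the evaluation
#'   protocol for imbalanced positive/negative pools; 100 by default).
#' @param draw Per-class draw size; `NULL` means the size of the smaller
#'   pool.
#' @param seed Integer seed.
#' @param cv The [cv_plan()] applied to each sample.
#' @return Object of class `resampling_plan`.
#' @export
resampling_plan <- function(n_samples = 100L, draw = NULL, seed = 1L,
                            cv = cv_plan()) {
  structure(list(n_samples = as.integer(n_samples), draw = draw,
                 seed = as.integer(seed), cv = cv),
            class = "resampling_plan")
}

#' Evaluate over repeated balanced samples
#'
#' Draws `n_samples` equal-sized positive/negative samples (each without
#' replacement within itself) from the two pools, cross-validates each, and
#' reports the mean and standard error of every metric over the samples.
#'
#' @param pos,neg Feature matrices for the positive and negative pools.
#' @param pipeline An [svm_pipeline()].
#' @param plan A [resampling_plan()].
#' @param pos_label,neg_label Labels assigned to the two pools.
#' @return List with `samples` (per-sample mean-metric data.frame), `mean`
#'   and `se` (named vectors; `se` is 0 when `n_samples` is 1).
#' @export
balanced_resample_eval <- function(pos, neg, pipeline,
                                   plan = resampling_plan(),
                                   pos_label = "HSP",
                                   neg_label = "non-HSP") {
  draw <- if (is.null(plan$draw)) min(nrow(pos), nrow(neg)) else plan$draw
  if (draw > nrow(pos) || draw > nrow(neg)) {
    stop("draw size ", draw, " exceeds a pool (", nrow(pos), " positives, ",
         nrow(neg), " negatives)")
  }
  set.seed(plan$seed)
  sample_seeds <- sample.int(.Machine$integer.max, plan$n_samples)
  rows <- vector("list", plan$n_samples)
  for (s in seq_len(plan$n_samples)) {
    set.seed(sample_seeds[s])
    pi <- sample(nrow(pos), draw)
    ni <- sample(nrow(neg), draw)
    X <- rbind(pos[pi, , drop = FALSE], neg[ni, , drop = FALSE])
    y <- c(rep(pos_label, draw), rep(neg_label, draw))
    cv <- plan$cv
    cv$seed <- sample_seeds[s] %% 1000000L
    rows[[s]] <- cross_validate(X, y, pipeline, cv)$mean
  }
  samples <- as.data.frame(do.call(rbind, rows))
  se <- if (plan$n_samples == 1L) {
    stats::setNames(rep(0, ncol(samples)), names(samples))
  } else {
    vapply(samples, function(v) stats::sd(v, na.rm = TRUE) /
             sqrt(sum(!is.na(v))), numeric(1L))
  }
  list(samples = samples,
       mean = colMeans(samples, na.rm = TRUE),
       se = se,
       n_samples = plan$n_samples, draw = draw, seed = plan$seed)
}

#' One-vs-rest family evaluation
#'
#' For each family, a binary cross-validation with that family positive and
#' the union of the others negative; plus class-size-weighted averages of
#' the per-family metrics.
#'
#' @param X Feature matrix.
#' @param y Family labels (at least two families present).
#' @param kernel A [kernel_spec()] used for every binary problem.
#' @param plan A [cv_plan()].
#' @param selection Optional per-fold selection, as in [svm_pipeline()].
#' @return List with `per_family` (data.frame, one row per family) and
#'   `weighted` (named vector of class-size-weighted means).
#' @export
one_vs_rest_family_eval <- function(X, y, kernel = kernel_spec("radial"),
                                    plan = cv_plan(), selection = NULL) {
  fams <- sort(unique(as.character(y)))
  if (length(fams) < 2L) stop("need at least two families")
  rows <- vector("list", length(fams))
  for (i in seq_along(fams)) {
    fam <- fams[i]
    yb <- ifelse(y == fam, fam, "rest")
    pipe <- svm_pipeline(kernel = kernel, positive = fam,
                         selection = selection)
    rows[[i]] <- cross_validate(X, yb, pipe, plan)$mean
  }
  per_family <- as.data.frame(do.call(rbind, rows))
  per_family <- cbind(family = fams,
                      n = as.integer(table(factor(y, levels = fams))),
                      per_family)
  w <- per_family$n / sum(per_family$n)
  metric_cols <- setdiff(names(per_family), c("family", "n"))
  weighted <- vapply(metric_cols, function(mc) {
    v <- per_family[[mc]]
    ok <- !is.na(v)
    sum(w[ok] * v[ok]) / sum(w[ok])
  }, numeric(1L))
  list(per_family = per_family, weighted = weighted)
}
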