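#' Rank features by one of five selection techniques
#'
#' All five techniques score every feature and sort decreasingly, ties
#' broken by feature name:
#' \describe{
#'   \item{f_measure}{two-class F-score: squared deviations of the class
#'     means from the grand mean over the summed within-class variances; 0
#'     for a feature with zero between-class separation.}
#'   \item{info_gain}{mutual information (bits) between the label and the
#'     feature discretized into (up to) 10 equal-frequency bins.}
#'   \item{lasso}{absolute coefficient of an L1-penalized logistic
#'     regression at the penalty chosen by internal cross-validation;
#'     zeroed-out features rank last.}
#'   \item{random_forest}{impurity-decrease importance from a 500-tree
#'     random forest.}
#'   \item{svm_weight}{absolute weight of a linear soft-margin SVM.}
#' }
#' Stochastic techniques (lasso's internal CV, random forest) are
#' reproducible given `seed`.
#'
#' @param X Numeric feature matrix with column names; at least two rows per
#'   class.
#' @param y Binary labels (two classes).
#' @param technique One of `"f_measure"`, `"info_gain"`, `"lasso"`,
#'   `"random_forest"`, `"svm_weight"`.
#' @param seed Integer seed.
#' @param num_trees Trees for the random forest.
#' @param n_bins Discretization bins for information gain.
#' @return Object of class `ranked_features`: list with `technique`,
#'   `names` (decreasing importance), `scores`, `seed`, `universe`,
#'   `params`.
#' @export
rank_features <- function(X, y,
                          technique = c("f_measure", "info_gain", "lasso",
                                        "random_forest", "svm_weight"),
                          seed = 1L, num_trees = 500L, n_bins = 10L) {
  technique <- match.arg(technique)
  yf <- factor(y)
  if (nlevels(yf) != 2L) stop("y must be binary; got ", nlevels(yf),
                              " class(es)")
  if (min(table(yf)) < 2L) stop("each class needs at least 2 rows")
  if (is.null(colnames(X))) stop("X must have column names")
  scores <- switch(technique,
    f_measure = f_score(X, yf),
    info_gain = info_gain_score(X, yf, n_bins),
    lasso = lasso_score(X, yf, seed),
    random_forest = rf_score(X, yf, seed, num_trees),
    svm_weight = svm_weight_score(X, yf))
  ord <- order(-scores, colnames(X))
  structure(list(technique = technique,
                 names = colnames(X)[ord],
                 scores = unname(scores[ord]),
                 seed = as.integer(seed),
                 universe = colnames(X),
                 params = list(num_trees = num_trees, n_bins = n_bins)),
            class = "ranked_features")
}

f_score <- function(X, yf) {
  a <- yf == levels(yf)[1L]
  m <- colMeans(X)
  m1 <- colMeans(X[a, , drop = FALSE])
  m2 <- colMeans(X[!a, , drop = FALSE])
  v1 <- apply(X[a, , drop = FALSE], 2L, var)
  v2 <- apply(X[!a, , drop = FALSE], 2L, var)
  num <- (m1 - m)^2 + (m2 - m)^2
  den <- v1 + v2
  ifelse(num == 0, 0, ifelse(den == 0, Inf, num / den))
}

info_gain_score <- function(X, yf, n_bins) {
  apply(X, 2L, function(x) {
    breaks <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
    if (length(breaks) < 2L) return(0)
    bins <- cut(x, breaks = breaks, include.lowest = TRUE)
    joint <- table(bins, yf) / length(x)
    px <- rowSums(joint); py <- colSums(joint)
    mi <- 0
    for (i in seq_along(px)) for (j in seq_along(py)) {
      p <- joint[i, j]
      if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
    }
    mi
  })
}

lasso_score <- function(X, yf, seed) {
  constant <- apply(X, 2L, function(x) length(unique(x)) == 1L)
  if (all(constant)) stop("degenerate fit: all features constant")
  set.seed(seed)
  cvfit <- glmnet::cv.glmnet(X, yf, family = "binomial", alpha = 1,
                             nfolds = 5L, standardize = TRUE)
  beta <- coef(cvfit, s = "lambda.min")
  stats::setNames(abs(as.numeric(beta[-1L])), colnames(X))
}

rf_score <- function(X, yf, seed, num_trees) {
  fit <- ranger::ranger(x = as.data.frame(X), y = yf,
                        num.trees = num_trees, importance = "impurity",
                        seed = seed, num.threads = 1L)
  imp <- fit$variable.importance
  imp[colnames(X)]
}

svm_weight_score <- function(X, yf) {
  constant <- apply(X, 2L, function(x) length(unique(x)) == 1L)
  if (all(constant)) stop("degenerate fit: all features constant")
  fit <- e1071::svm(x = X, y = yf, kernel = "linear", cost = 1,
                    scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  stats::setNames(abs(w), colnames(X))
}

#' Select the top-k features from a ranking
#'
#' @param ranked A [rank_features()] result.
#' @param k Number of features to keep (default 484, the size at which the
#'   L1 path of the reference workflow retained non-zero coefficients).
#' @return Object of class `selection_result`: list with `selected` (first
#'   k names), `k`, `technique`, `universe`.
#' @export
select_top_k <- function(ranked, k = 484L) {
  stopifnot(inherits(ranked, "ranked_features"))
  k <- as.integer(k)
  if (k < 1L || k > length(ranked$names)) {
    stop("k = ", k, " outside 1..", length(ranked$names))
  }
  structure(list(selected = ranked$names[seq_len(k)], k = k,
                 technique = ranked$technique,
                 universe = ranked$universe),
            class = "selection_result")
}

#' Overlap structure of several selections
#'
#' Intersection cardinalities for every non-empty subset of the given
#' selections (the numbers a Venn diagram is drawn from). All selections
#' must share one feature universe.
#'
#' @param results Named list of [select_top_k()] results (at least two).
#' @return data.frame with columns `techniques` (plus-joined subset label),
#'   `size` (subset size) and `intersection` (cardinality of the
#'   intersection of those selections).
#' @export
selection_overlap <- function(results) {
  if (length(results) < 2L) stop("need at least two selections")
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    names(results) <- vapply(results, `[[`, character(1L), "technique")
  }
  universes <- lapply(results, `[[`, "universe")
  if (length(unique(lapply(universes, sort))) != 1L) {
    stop("selections come from mismatched feature universes")
  }
  sets <- lapply(results, `[[`, "selected")
  nms <- names(results)
  subsets <- unlist(lapply(seq_along(nms), function(m) {
    utils::combn(nms, m, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(subsets, function(sub) {
    data.frame(techniques = paste(sub, collapse = "+"),
               size = length(sub),
               intersection = length(Reduce(intersect, sets[sub])))
  })
  do.call(rbind, rows)
}
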