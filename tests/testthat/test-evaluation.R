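test_that("confusion counts are exact and symmetric", {
  cc <- confusion(c("P", "P", "N", "N"), c("P", "N", "N", "P"), "P")
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  all_right <- confusion(c("P", "N"), c("P", "N"), "P")
  expect_equal(all_right$fp + all_right$fn, 0L)
  # swapping predictions exchanges tp<->fn and tn<->fp
  y <- sample(c("P", "N"), 40L, replace = TRUE)
  p <- sample(c("P", "N"), 40L, replace = TRUE)
  swap <- ifelse(p == "P", "N", "P")
  a <- confusion(y, p, "P"); b <- confusion(y, swap, "P")
  expect_equal(a$tp, b$fn); expect_equal(a$tn, b$fp)
  expect_error(confusion(c("P"), c("P", "N"), "P"), "length")
})

test_that("metrics evaluate the five formulas exactly", {
  m <- metrics(confusion(rep(c("P", "N"), c(4L, 0L)),
                         rep(c("P", "N"), c(3L, 1L)), "P"))
  expect_equal(unname(m["sensitivity"]), 0.75)
  balanced <- structure(list(tp = 25L, tn = 25L, fp = 25L, fn = 25L),
                        class = "confusion_counts")
  expect_equal(unname(metrics(balanced)["mcc"]), 0)
  hand <- structure(list(tp = 8L, tn = 9L, fp = 1L, fn = 2L),
                    class = "confusion_counts")
  expect_equal(unname(metrics(hand)["mcc"]), 70 / sqrt(9900),
               tolerance = 1e-9)
  expect_equal(unname(metrics(hand)["accuracy"]), 17 / 20)
  # zero denominators flag NA instead of silently giving 0
  none_called <- structure(list(tp = 0L, tn = 5L, fp = 0L, fn = 5L),
                           class = "confusion_counts")
  expect_true(is.na(metrics(none_called)["precision"]))
  expect_true(is.na(metrics(none_called)["mcc"]))
})

test_that("label swap exchanges sensitivity and specificity, |mcc| fixed", {
  set.seed(21)
  y <- sample(c("P", "N"), 60L, replace = TRUE, prob = c(0.4, 0.6))
  p <- ifelse(runif(60L) < 0.7, y, ifelse(y == "P", "N", "P"))
  mp <- metrics(confusion(y, p, "P"))
  mn <- metrics(confusion(y, p, "N"))
  expect_equal(unname(mp["sensitivity"]), unname(mn["specificity"]))
  expect_equal(unname(mp["specificity"]), unname(mn["sensitivity"]))
  expect_equal(abs(mp["mcc"]), abs(mn["mcc"]), tolerance = 1e-12)
  expect_equal(mp["accuracy"], mn["accuracy"])
})

test_that("auc_roc equals the exhaustive pairwise oracle, ties included", {
  expect_equal(auc_roc(scores = c(0.9, 0.8, 0.2, 0.1),
                       y_true = c("P", "P", "N", "N"), positive = "P"), 1)
  expect_equal(auc_roc(scores = rep(0.5, 10L),
                       y_true = rep(c("P", "N"), 5L), positive = "P"), 0.5)
  set.seed(22)
  for (rep in 1:5) {
    n <- 200L
    y <- rep(c("P", "N"), each = n)
    s <- c(rnorm(n, 0.3), rnorm(n))
    if (rep > 2) s <- round(s, 1)      # force heavy ties
    expect_equal(auc_roc(scores = s, y_true = y, positive = "P"),
                 auc_pairwise_oracle(s, y, "P"), tolerance = 1e-12)
  }
  expect_error(roc_points(1:3, rep("P", 3L), "P"), "both classes")
})

test_that("auc_pr follows the step rule and its known limits", {
  expect_equal(auc_pr(scores = c(0.9, 0.8, 0.2, 0.1),
                      y_true = c("P", "P", "N", "N"), positive = "P"), 1)
  # uninformative scores approach the positive prevalence
  set.seed(23)
  n <- 4000L; prev <- 0.25
  y <- ifelse(runif(n) < prev, "P", "N")
  s <- runif(n)
  expect_lt(abs(auc_pr(scores = s, y_true = y, positive = "P") -
                  mean(y == "P")), 0.05)
  # collapsing a threshold that changes no counts leaves the area fixed
  y2 <- c("P", "P", "N", "N")
  a1 <- auc_pr(scores = c(4, 3, 2, 1), y_true = y2, positive = "P")
  a2 <- auc_pr(scores = c(4, 3.5, 2, 1), y_true = y2, positive = "P")
  expect_equal(a1, a2)
  expect_error(pr_points(1:3, rep("N", 3L), "P"), "at least one positive")
})

test_that("cv_folds partitions with stratification within one", {
  y <- rep(c("HSP", "non-HSP"), c(60L, 40L))
  folds <- cv_folds(y, cv_plan("kfold", k = 5L, seed = 9L))
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 100L)
  tab <- table(folds, y)
  expect_true(all(abs(tab[, "HSP"] - 12) <= 1))
  expect_true(all(abs(tab[, "non-HSP"] - 8) <= 1))
  # loocv: n singleton folds
  folds1 <- cv_folds(y[1:50], cv_plan("loocv"))
  expect_equal(sort(folds1), 1:50)
  # reproducible from seed
  expect_identical(folds, cv_folds(y, cv_plan("kfold", k = 5L, seed = 9L)))
})

test_that("cross_validate tests each instance once and never trains on it", {
  d <- make_toy_clouds(n_per = 30L, seed = 31L)
  cv <- cross_validate(d$X, d$y, svm_pipeline(positive = "B"),
                       cv_plan(k = 5L, seed = 5L))
  expect_equal(sort(unique(cv$assignments)), 1:5)
  expect_false(anyNA(cv$predictions$call))
  expect_equal(nrow(cv$folds), 5L)
  # separable clouds: near-perfect metrics
  expect_gt(cv$mean[["accuracy"]], 0.95)
  expect_gt(cv$mean[["auc_roc"]], 0.99)
  # the fold column partitions the data
  expect_equal(as.integer(table(cv$assignments)), rep(12L, 5L))
})

test_that("cross_validate fails when a training fold loses a class", {
  X <- matrix(rnorm(12L), ncol = 2L,
              dimnames = list(NULL, c("a", "b")))
  y <- rep(c("P", "N"), c(1L, 5L))
  expect_error(cross_validate(X, y, svm_pipeline(positive = "P"),
                              cv_plan("loocv")),
               "absent")
})

test_that("balanced resampling reports reproducible means and errors", {
  d <- make_toy_clouds(n_per = 60L, sep = 4, seed = 33L)
  pos <- d$X[d$y == "B", ]; neg <- d$X[d$y == "A", ]
  plan <- resampling_plan(n_samples = 4L, draw = 40L, seed = 13L,
                          cv = cv_plan(k = 4L))
  pipe <- svm_pipeline(positive = "B")
  r1 <- balanced_resample_eval(pos, neg, pipe, plan,
                               pos_label = "B", neg_label = "A")
  r2 <- balanced_resample_eval(pos, neg, pipe, plan,
                               pos_label = "B", neg_label = "A")
  expect_identical(r1$mean, r2$mean)
  expect_identical(r1$se, r2$se)
  expect_equal(nrow(r1$samples), 4L)
  expect_gt(r1$mean[["accuracy"]], 0.9)
  # a single sample reports zero standard errors
  one <- balanced_resample_eval(pos, neg, pipe,
                                resampling_plan(n_samples = 1L, draw = 40L,
                                                seed = 13L,
                                                cv = cv_plan(k = 4L)),
                                pos_label = "B", neg_label = "A")
  expect_true(all(one$se == 0))
  expect_error(balanced_resample_eval(pos, neg, pipe,
                                      resampling_plan(draw = 10000L)),
               "exceeds")
})

test_that("one-vs-rest family evaluation matches its definitions", {
  set.seed(35)
  # three shifted clouds standing in for families
  n <- c(a = 30L, b = 20L, c = 10L)
  X <- do.call(rbind, lapply(seq_along(n), function(k) {
    matrix(rnorm(n[k] * 2L, mean = 5 * k), ncol = 2L)
  }))
  colnames(X) <- c("f1", "f2")
  y <- rep(names(n), n)
  res <- one_vs_rest_family_eval(X, y, plan = cv_plan(k = 5L, seed = 2L))
  expect_equal(res$per_family$family, c("a", "b", "c"))
  expect_equal(res$per_family$n, unname(as.integer(n)))
  expect_true(all(res$per_family$accuracy > 0.9))
  # weighted average is the class-size-weighted mean
  w <- res$per_family$n / sum(res$per_family$n)
  expect_equal(unname(res$weighted["accuracy"]),
               sum(w * res$per_family$accuracy), tolerance = 1e-12)
  expect_error(one_vs_rest_family_eval(X, rep("a", nrow(X))),
               "two families")
})

test_that("two-family one-vs-rest problems are label complements", {
  d <- make_toy_clouds(n_per = 25L, seed = 37L)
  res <- one_vs_rest_family_eval(d$X, d$y, plan = cv_plan(k = 5L, seed = 3L))
  pf <- res$per_family
  expect_equal(pf$sensitivity[pf$family == "A"],
               pf$specificity[pf$family == "B"], tolerance = 0.15)
  expect_equal(pf$accuracy[1L], pf$accuracy[2L], tolerance = 0.1)
})
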