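test_that("a linear kernel separates well-separated clouds perfectly", {
  d <- make_toy_clouds(n_per = 20L, sep = 6, seed = 41L)
  m <- fit_svm(d$X, d$y, kernel_spec("linear"), seed = 1L,
               probability = FALSE)
  pred <- predict_classifier(m, d$X)
  expect_equal(mean(as.character(pred$class) == d$y), 1)
})

test_that("the radial kernel handles the XOR pattern where linear cannot", {
  d <- make_xor(n_per = 30L, seed = 42L)
  rad <- fit_svm(d$X, d$y, kernel_spec("radial"), probability = FALSE)
  lin <- fit_svm(d$X, d$y, kernel_spec("linear"), probability = FALSE)
  acc <- function(m) mean(as.character(predict_classifier(m, d$X)$class)
                          == d$y)
  expect_gt(acc(rad), 0.95)
  expect_lte(acc(lin), 0.6)
})

test_that("refitting with the same seed reproduces held-out predictions", {
  d <- make_toy_clouds(n_per = 25L, sep = 3, seed = 43L)
  probe <- make_toy_clouds(n_per = 10L, sep = 3, seed = 44L)
  m1 <- fit_svm(d$X, d$y, seed = 5L)
  m2 <- fit_svm(d$X, d$y, seed = 5L)
  p1 <- predict_classifier(m1, probe$X)
  p2 <- predict_classifier(m2, probe$X)
  expect_identical(as.character(p1$class), as.character(p2$class))
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
  expect_identical(m1$train_digest, m2$train_digest)
})

test_that("fit_svm enforces its contracts", {
  d <- make_toy_clouds()
  expect_error(fit_svm(d$X, rep("A", nrow(d$X))), "single class")
  expect_error(fit_svm(d$X, c("B", rep("A", nrow(d$X) - 1L))),
               "fewer than 2")
  Xna <- d$X; Xna[1L, 1L] <- NA
  expect_error(fit_svm(Xna, d$y), "NA")
  expect_error(fit_svm(unname(d$X), d$y), "column names")
  m <- fit_svm(d$X, d$y, probability = FALSE)
  bad <- d$X; colnames(bad) <- c("f2", "f1")
  expect_error(predict_classifier(m, bad), "do not match")
})

test_that("class probabilities are in [0,1] and sum to one per row", {
  d <- make_xor()
  m <- fit_svm(d$X, d$y, seed = 2L)
  pr <- predict_classifier(m, d$X)$prob
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-9)
})

test_that("kernel_screen picks the radial kernel on radial geometry", {
  set.seed(45)
  # annulus vs core: radially separable, linearly inseparable
  r_in <- sqrt(runif(60L, 0, 1)); r_out <- sqrt(runif(60L, 4, 6))
  th <- runif(120L, 0, 2 * pi)
  X <- cbind(f1 = c(r_in, r_out) * cos(th), f2 = c(r_in, r_out) * sin(th))
  y <- rep(c("core", "ring"), each = 60L)
  scr <- kernel_screen(X, y, folds = 4L, seed = 6L, positive = "core")
  expect_equal(scr$best$kind, "radial")
  expect_named(scr$accuracy, c("radial", "linear", "polynomial", "sigmoid"))
  one <- kernel_screen(X, y, kernels = list(kernel_spec("linear")),
                       folds = 4L, positive = "core")
  expect_equal(one$best$kind, "linear")
  expect_length(one$reports, 1L)
})

# shared fixture for the hierarchical tests: tiny but learnable benchmark
make_small_hierarchy <- function(seed = 47L) {
  counts <- c(HSP20 = 25L, HSP40 = 40L, HSP60 = 25L, HSP70 = 25L,
              HSP90 = 25L, HSP100 = 25L)
  bench <- generate_benchmark(hsp_benchmark_spec(
    mult = 8, counts = counts, n_neg = 80L,
    length_range = c(60L, 120L), seed = seed))
  enc <- gpc_encoder(0:1)
  X <- encode_dataset(bench, enc)
  y1 <- ifelse(bench$labels == "non-HSP", "non-HSP", "HSP")
  s1 <- fit_svm(X, y1, seed = 1L)
  pos <- bench$labels != "non-HSP"
  s2 <- fit_svm(X[pos, ], bench$labels[pos], seed = 2L)
  dn <- generate_benchmark(dnaj_benchmark_spec(
    counts = c("Type-I" = 20L, "Type-II" = 20L, "Type-III" = 30L,
               "Type-IV" = 12L),
    length_range = c(60L, 120L), seed = seed + 1L))
  s3 <- fit_svm(encode_dataset(dn, enc), dn$labels, seed = 3L)
  list(bench = bench, enc = enc, X = X,
       model = build_hierarchical(s1, s2, s3,
                                  pipeline = list(encoder = enc,
                                                  threshold = 0.5)))
}

small_h <- make_small_hierarchy()

test_that("build_hierarchical validates classes and feature spaces", {
  m <- small_h$model
  expect_s3_class(m, "hierarchical_model")
  # a stage-2 model missing a family is rejected by name
  bench <- small_h$bench
  pos5 <- bench$labels %in% setdiff(HSP_FAMILIES, "HSP90")
  s2_5 <- fit_svm(small_h$X[pos5, ], bench$labels[pos5], seed = 4L)
  expect_error(build_hierarchical(m$stage1, s2_5, NULL,
                                  list(encoder = small_h$enc)),
               "HSP90")
  # mismatched feature spaces are rejected
  d <- make_toy_clouds()
  alien <- fit_svm(d$X, ifelse(d$y == "A", "HSP", "non-HSP"), seed = 5L)
  expect_error(build_hierarchical(alien, m$stage2, NULL,
                                  list(encoder = small_h$enc)),
               "feature space")
})

test_that("the cascade gates stage 2 and stage 3 correctly", {
  probe <- generate_benchmark(hsp_benchmark_spec(
    mult = 8,
    counts = c(HSP20 = 5L, HSP40 = 10L, HSP60 = 5L, HSP70 = 5L,
               HSP90 = 5L, HSP100 = 5L),
    n_neg = 15L, length_range = c(60L, 120L), seed = 99L))
  pred <- hierarchical_predict(small_h$model, probe)
  inv <- attr(pred, "invocations")
  n_hsp_called <- sum(pred$call != "non-HSP", na.rm = TRUE)
  n_hsp40_called <- sum(!is.na(pred$family) & pred$family == "HSP40")
  expect_equal(unname(inv["stage2"]), n_hsp_called)
  expect_equal(unname(inv["stage3"]), n_hsp40_called)
  # non-HSP calls carry no family or sub-type
  nh <- pred[pred$call == "non-HSP", ]
  expect_true(all(is.na(nh$family)) && all(is.na(nh$dnaj_type)))
  # HSP40 calls (and only those) carry a DnaJ sub-type
  h40 <- pred[!is.na(pred$family) & pred$family == "HSP40", ]
  expect_true(all(h40$dnaj_type %in% DNAJ_TYPES))
  expect_true(all(grepl("^HSP40\\(Type-", h40$call)))
  other <- pred[!is.na(pred$family) & pred$family != "HSP40", ]
  expect_true(all(is.na(other$dnaj_type)))
  # serials follow input order
  expect_equal(pred$serial, seq_along(probe$sequences))
  expect_equal(pred$id, names(probe$sequences))
})

test_that("a two-stage model stops at the family level", {
  m2 <- build_hierarchical(small_h$model$stage1, small_h$model$stage2,
                           NULL, list(encoder = small_h$enc))
  probe <- small_h$bench$sequences[1:10]
  pred <- hierarchical_predict(m2, probe)
  expect_true(all(is.na(pred$dnaj_type)))
  expect_equal(unname(attr(pred, "invocations")["stage3"]), 0L)
})

test_that("per-sequence encoding failures do not abort the batch", {
  seqs <- c(small_h$bench$sequences[1:2],
            list(short = protein_sequence("too_short", "MK")))
  pred <- hierarchical_predict(small_h$model, seqs)
  expect_equal(nrow(pred), 3L)
  expect_true(is.na(pred$call[3L]))
  expect_match(pred$error[3L], "too short")
  expect_false(anyNA(pred$call[1:2]))
})

test_that("model bundles round-trip with identical predictions", {
  dir <- withr::local_tempdir()
  save_model_bundle(small_h$model, dir)
  expect_true(file.exists(file.path(dir, "meta.json")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_equal(meta$format, "hspkit-model-bundle")
  expect_equal(length(meta$features),
               length(small_h$model$pipeline$features))
  expect_equal(unlist(meta$stage2$classes), sort(HSP_FAMILIES))
  loaded <- load_model_bundle(dir)
  probe <- small_h$bench$sequences[seq(1L, 40L, by = 4L)]
  p1 <- hierarchical_predict(small_h$model, probe)
  p2 <- hierarchical_predict(loaded, probe)
  expect_identical(p1$call, p2$call)
  expect_equal(p1$p_hsp, p2$p_hsp, tolerance = 1e-12)
  expect_error(load_model_bundle(withr::local_tempdir()), "not a model")
})
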