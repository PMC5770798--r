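#' Kernel specification for an SVM
#'
#' The four basic kernels with their defaults: cost 1 and, for kernels that
#' use it, gamma = 1/(number of features) ("auto"). Parameters irrelevant to
#' the chosen kind are recorded but ignored by the fit.
#'
#' @param kind `"linear"`, `"polynomial"`, `"radial"` or `"sigmoid"`.
#' @param cost Positive regularization cost C.
#' @param gamma Positive kernel width, or `"auto"` for 1/ncol(X).
#' @param degree Polynomial degree.
#' @param coef0 Offset for polynomial/sigmoid.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("radial", "linear", "polynomial", "sigmoid"),
                        cost = 1, gamma = "auto", degree = 3L, coef0 = 0) {
  kind <- match.arg(kind)
  if (!identical(gamma, "auto") && (!is.numeric(gamma) || gamma <= 0)) {
    stop("gamma must be positive or 'auto'")
  }
  if (cost <= 0) stop("cost must be positive")
  structure(list(kind = kind, cost = cost, gamma = gamma,
                 degree = as.integer(degree), coef0 = coef0),
            class = "kernel_spec")
}

## Internal: short content digest for provenance (first 16 hex chars of the
## md5 of the serialized object).
digest16 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  substr(unname(tools::md5sum(f)), 1L, 16L)
}

#' Fit a kernel SVM classifier
#'
#' A thin, provenance-tracking wrapper around [e1071::svm()]. Columns are
#' standardized inside the fit (the default of the underlying software),
#' which matters for composition descriptors: raw GPC entries are of order
#' 1/400, so without rescaling the radial kernel at gamma = 1/d is nearly
#' constant across observations and the fit both converges slowly and
#' underuses the signal. Constant columns are left unscaled. With
#' `probability = TRUE` a probability mapping is calibrated on the training
#' data, making class probabilities available at prediction time.
#'
#' @param X Numeric feature matrix with unique column names.
#' @param y Label vector with at least two classes, each with at least two
#'   examples.
#' @param kernel A [kernel_spec()].
#' @param seed Integer; fixed before the fit so the internal calibration is
#'   reproducible.
#' @param probability Calibrate class probabilities (needed by the
#'   hierarchical predictor; evaluation pipelines use decision values).
#' @return Object of class `trained_classifier`.
#' @export
fit_svm <- function(X, y, kernel = kernel_spec("radial"), seed = 1L,
                    probability = TRUE) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (anyNA(X)) stop("feature matrix contains NA")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop("feature matrix must have unique column names")
  }
  yf <- factor(y)
  counts <- table(yf)
  if (nlevels(yf) < 2L) stop("training labels contain a single class")
  if (any(counts < 2L)) {
    stop("class(es) with fewer than 2 examples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  gamma <- if (identical(kernel$gamma, "auto")) 1 / ncol(X) else kernel$gamma
  set.seed(seed)
  fit <- suppressWarnings(
    e1071::svm(x = X, y = yf, scale = TRUE,
               kernel = kernel$kind, cost = kernel$cost,
               gamma = gamma, degree = kernel$degree,
               coef0 = kernel$coef0, probability = probability))
  structure(list(svm = fit, kernel = kernel,
                 feature_names = colnames(X),
                 classes = levels(yf),
                 probability = probability,
                 seed = seed,
                 scaling = "standardize",
                 train_digest = digest16(list(X = X, y = as.character(y)))),
            class = "trained_classifier")
}

#' @exportS3Method base::print
print.trained_classifier <- function(x, ...) {
  cat("<trained_classifier>", x$kernel$kind, "kernel;",
      length(x$classes), "classes;", length(x$feature_names),
      "features; digest", x$train_digest, "\n")
  invisible(x)
}

#' Predict with a trained classifier
#'
#' Rejects inputs whose feature names or order differ from those the model
#' was trained on.
#'
#' @param model A `trained_classifier`.
#' @param X Feature matrix with exactly the model's columns, in order.
#' @param decision_values Also return the SVM decision values.
#' @return List with `class` (factor), `prob` (matrix of class
#'   probabilities, if the model was calibrated) and `decision` (if
#'   requested).
#' @export
predict_classifier <- function(model, X, decision_values = FALSE) {
  stopifnot(inherits(model, "trained_classifier"))
  if (!identical(colnames(X), model$feature_names)) {
    stop("feature names/order of the input do not match the model's ",
         "training features")
  }
  pred <- predict(model$svm, X, probability = model$probability,
                  decision.values = decision_values)
  out <- list(class = pred)
  if (model$probability) {
    pr <- attr(pred, "probabilities")
    out$prob <- pr[, model$classes, drop = FALSE]
  }
  if (decision_values) out$decision <- attr(pred, "decision.values")
  out
}

#' Signed decision value for a designated positive class
#'
#' libsvm labels each binary decision column "A/B" with values positive
#' toward A; this flips the sign where needed so larger always means more
#' `positive`.
#'
#' @param decision Decision-value matrix from [predict_classifier()].
#' @param positive Positive class label.
#' @return Numeric score vector.
#' @export
decision_for <- function(decision, positive) {
  cols <- colnames(decision)
  parts <- strsplit(cols, "/", fixed = TRUE)
  hit <- which(vapply(parts, function(p) positive %in% p, logical(1L)))[1L]
  if (is.na(hit)) stop("no decision column involves class '", positive, "'")
  sgn <- if (parts[[hit]][1L] == positive) 1 else -1
  sgn * decision[, hit]
}

#' Screen kernels by cross-validated accuracy
#'
#' Cross-validates each candidate kernel and picks the one with the highest
#' mean accuracy; ties are broken by the preference order radial, linear,
#' polynomial, sigmoid.
#'
#' @param X,y Feature matrix and binary labels.
#' @param kernels List of [kernel_spec()]; default all four basic kernels.
#' @param folds Number of CV folds.
#' @param seed Fold-assignment seed.
#' @param positive Positive label (defaults to first sorted label).
#' @return List with `reports` (named list of per-kernel [cross_validate()]
#'   means), `best` (the winning `kernel_spec`) and `accuracy` (named
#'   vector).
#' @export
kernel_screen <- function(X, y, kernels = lapply(c("radial", "linear",
                                                   "polynomial", "sigmoid"),
                                                 kernel_spec),
                          folds = 5L, seed = 1L,
                          positive = sort(unique(as.character(y)))[1L]) {
  kinds <- vapply(kernels, `[[`, character(1L), "kind")
  names(kernels) <- kinds
  plan <- cv_plan("kfold", k = folds, seed = seed)
  reports <- lapply(kernels, function(ks) {
    cross_validate(X, y, svm_pipeline(kernel = ks, positive = positive),
                   plan)$mean
  })
  acc <- vapply(reports, `[[`, numeric(1L), "accuracy")
  pref <- c("radial", "linear", "polynomial", "sigmoid")
  order_idx <- order(-acc, match(kinds, pref))
  list(reports = reports, best = kernels[[order_idx[1L]]], accuracy = acc)
}

#' Compose the three-stage hierarchical HSP predictor
#'
#' Stage 1 separates HSP from non-HSP; stage 2 assigns one of the six
#' families to predicted HSPs; stage 3 sub-types predicted HSP40 sequences
#' into the four DnaJ classes. All stages must share one feature space.
#'
#' @param stage1 Binary `trained_classifier` with classes HSP / non-HSP.
#' @param stage2 Six-family `trained_classifier`.
#' @param stage3 Optional four-type DnaJ `trained_classifier`; without it,
#'   prediction stops at the family level.
#' @param pipeline List describing the shared feature pipeline: `encoder`
#'   (an `hsp_encoder`), optional `features` (selected feature names applied
#'   after encoding), `threshold` (stage-1 HSP probability cutoff, default
#'   0.5).
#' @return Object of class `hierarchical_model`.
#' @export
build_hierarchical <- function(stage1, stage2, stage3 = NULL,
                               pipeline = list(encoder = gpc_encoder(),
                                               features = NULL,
                                               threshold = 0.5)) {
  pipeline <- modifyList(list(features = NULL, threshold = 0.5), pipeline)
  stopifnot(inherits(stage1, "trained_classifier"),
            inherits(stage2, "trained_classifier"),
            inherits(pipeline$encoder, "hsp_encoder"))
  if (!setequal(stage1$classes, c("HSP", "non-HSP"))) {
    stop("stage 1 must have classes HSP and non-HSP; got ",
         paste(stage1$classes, collapse = ", "))
  }
  missing_fam <- setdiff(HSP_FAMILIES, stage2$classes)
  if (length(missing_fam) > 0L) {
    stop("stage 2 is missing family class(es): ",
         paste(missing_fam, collapse = ", "))
  }
  stages <- list(stage1, stage2)
  if (!is.null(stage3)) {
    stopifnot(inherits(stage3, "trained_classifier"))
    bad <- setdiff(stage3$classes, DNAJ_TYPES)
    if (length(bad) > 0L) {
      stop("stage 3 class(es) outside the DnaJ types: ",
           paste(bad, collapse = ", "))
    }
    stages <- c(stages, list(stage3))
  }
  featsets <- lapply(stages, `[[`, "feature_names")
  if (length(unique(featsets)) != 1L) {
    stop("stages do not share one feature space")
  }
  if (!is.null(pipeline$features) &&
      !identical(pipeline$features, featsets[[1L]])) {
    stop("pipeline's selected features differ from the stages' feature ",
         "space")
  }
  if (is.null(pipeline$features)) pipeline$features <- featsets[[1L]]
  structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 pipeline = pipeline),
            class = "hierarchical_model")
}

#' @exportS3Method base::print
print.hierarchical_model <- function(x, ...) {
  cat("<hierarchical_model> encoder", x$pipeline$encoder$name,
      "|", length(x$pipeline$features), "features | stage3:",
      if (is.null(x$stage3)) "absent" else "present", "\n")
  invisible(x)
}

#' Hierarchical prediction over a batch of sequences
#'
#' Encodes each sequence through the shared pipeline, then: stage 1 calls
#' HSP when its HSP probability reaches the threshold (default 0.5),
#' otherwise "non-HSP" and the cascade halts for that sequence; stage 2
#' assigns the maximum-probability family; a stage-2 call of HSP40 (and
#' only that call) consults stage 3 for the DnaJ sub-type. Sequences that
#' fail encoding are reported inline (call `NA`, message in `error`)
#' without aborting the batch.
#'
#' @param model A [build_hierarchical()] model.
#' @param seqs List of `protein_sequence` (or a `labeled_dataset`).
#' @return data.frame with columns `serial`, `id`, `call`, `p_hsp`,
#'   `family`, `p_family`, `dnaj_type`, `p_type`, `error`; attribute
#'   `invocations` counts how many sequences reached each stage.
#' @export
hierarchical_predict <- function(model, seqs) {
  stopifnot(inherits(model, "hierarchical_model"))
  if (inherits(seqs, "labeled_dataset")) seqs <- seqs$sequences
  n <- length(seqs)
  out <- data.frame(serial = seq_len(n),
                    id = vapply(seqs, `[[`, character(1L), "id"),
                    call = NA_character_, p_hsp = NA_real_,
                    family = NA_character_, p_family = NA_real_,
                    dnaj_type = NA_character_, p_type = NA_real_,
                    error = NA_character_)
  invocations <- c(stage1 = 0L, stage2 = 0L, stage3 = 0L)
  enc <- model$pipeline$encoder
  sel <- model$pipeline$features
  thr <- model$pipeline$threshold
  for (i in seq_len(n)) {
    x <- tryCatch(enc$encode(seqs[[i]]), error = function(e) e)
    if (inherits(x, "error")) {
      out$error[i] <- conditionMessage(x)
      next
    }
    X <- matrix(x[sel], nrow = 1L, dimnames = list(NULL, sel))
    invocations["stage1"] <- invocations["stage1"] + 1L
    p1 <- predict_classifier(model$stage1, X)$prob[1L, "HSP"]
    out$p_hsp[i] <- p1
    if (p1 < thr) {
      out$call[i] <- "non-HSP"
      next
    }
    invocations["stage2"] <- invocations["stage2"] + 1L
    p2 <- predict_classifier(model$stage2, X)$prob[1L, ]
    fam <- names(p2)[which.max(p2)]
    out$family[i] <- fam
    out$p_family[i] <- max(p2)
    out$call[i] <- fam
    if (fam == "HSP40" && !is.null(model$stage3)) {
      invocations["stage3"] <- invocations["stage3"] + 1L
      p3 <- predict_classifier(model$stage3, X)$prob[1L, ]
      typ <- names(p3)[which.max(p3)]
      out$dnaj_type[i] <- typ
      out$p_type[i] <- max(p3)
      out$call[i] <- paste0("HSP40(", typ, ")")
    }
  }
  attr(out, "invocations") <- invocations
  out
}

#' Save a hierarchical model bundle
#'
#' Writes a directory with JSON metadata (kernels, classes, feature list,
#' seeds, training digests) and one serialized artifact per stage.
#'
#' @param model A `hierarchical_model`.
#' @param dir Output directory (created if needed).
#' @export
save_model_bundle <- function(model, dir) {
  stopifnot(inherits(model, "hierarchical_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stage_meta <- function(s) {
    if (is.null(s)) return(NULL)
    list(kernel = s$kernel[c("kind", "cost", "gamma", "degree", "coef0")],
         classes = s$classes, seed = s$seed,
         train_digest = s$train_digest)
  }
  meta <- list(format = "hspkit-model-bundle", version = 1L,
               encoder = model$pipeline$encoder$name,
               threshold = model$pipeline$threshold,
               n_features = length(model$pipeline$features),
               features = model$pipeline$features,
               stage1 = stage_meta(model$stage1),
               stage2 = stage_meta(model$stage2),
               stage3 = stage_meta(model$stage3))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a hierarchical model bundle
#'
#' @param dir Directory written by [save_model_bundle()].
#' @return The `hierarchical_model`.
#' @export
load_model_bundle <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  rds_path <- file.path(dir, "model.rds")
  if (!file.exists(meta_path) || !file.exists(rds_path)) {
    stop("not a model bundle (missing meta.json or model.rds): ", dir)
  }
  meta <- jsonlite::read_json(meta_path)
  if (!identical(meta$format, "hspkit-model-bundle")) {
    stop("unrecognized bundle format in ", meta_path)
  }
  model <- readRDS(rds_path)
  stopifnot(inherits(model, "hierarchical_model"))
  model
}
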