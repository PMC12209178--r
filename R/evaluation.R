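# End-to-end evaluation: repeated stratified 6:2:2 splits, train-only
# vocabulary fitting and augmentation (so no test information leaks into any
# fitted parameter), and standard binary metrics with ROC/AUC.

#' Stratified 6:2:2 split
#'
#' Splits ids into train/validation/test at a 60/20/20 ratio within each
#' label stratum; validation and test take `floor(0.2 * n)` per class and
#' the training set receives the remainder. Deterministic per seed.
#'
#' @param ids Character or integer image ids.
#' @param labels Integer 0/1 labels aligned with `ids`.
#' @param seed Integer seed.
#' @return A list of class `wbovw_split` with `train`, `val`, `test` id
#'   vectors and the `seed`.
#' @export
split_6_2_2 <- function(ids, labels, seed = 1L) {
  stopifnot(length(ids) == length(labels))
  labels <- as.integer(labels)
  for (cl in c(0L, 1L)) {
    if (sum(labels == cl) < 5L) {
      stop("need at least 5 ids in class ", cl, " for a 6:2:2 split",
           call. = FALSE)
    }
  }
  with_seed(seed, {
    train <- val <- test <- c()
    for (cl in c(0L, 1L)) {
      cl_ids <- sample(ids[labels == cl])
      n <- length(cl_ids)
      n_val <- floor(0.2 * n)
      n_test <- floor(0.2 * n)
      val <- c(val, cl_ids[seq_len(n_val)])
      test <- c(test, cl_ids[n_val + seq_len(n_test)])
      train <- c(train, cl_ids[(n_val + n_test + 1L):n])
    }
    structure(list(train = train, val = val, test = test,
                   seed = as.integer(seed)),
              class = "wbovw_split")
  })
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`; 0 when both are 0.
#'
#' @param precision,recall Fractions in \[0, 1\].
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Binary classification metrics
#'
#' Accuracy, recall, precision, F1 and the 2x2 confusion matrix, with FGR
#' (label 1) as the positive class. A zero denominator (e.g. no positive
#' predictions) yields a 0 metric and is recorded in the `flags` field.
#'
#' @param y_true,y_pred Equal-length integer 0/1 vectors.
#' @return A list with `accuracy`, `recall`, `precision`, `f1`, `confusion`
#'   (rows = truth, columns = prediction) and `flags`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  tp <- sum(y_true == 1L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  flags <- character(0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    flags <- c(flags, "no positives in y_true"); 0
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    flags <- c(flags, "no positive predictions"); 0
  }
  confusion <- matrix(c(tn, fn, fp, tp), 2L, 2L,
                      dimnames = list(truth = c("normal", "fgr"),
                                      predicted = c("normal", "fgr")))
  list(accuracy = (tp + tn) / length(y_true),
       recall = recall, precision = precision,
       f1 = f1_score(precision, recall),
       confusion = confusion, flags = flags)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold across the unique scores (ties cross
#' simultaneously, giving the diagonal tie convention) and integrates the
#' curve by the trapezoid rule, which equals the Mann-Whitney pair-counting
#' statistic with half credit for tied pairs.
#'
#' @param y_true Integer 0/1 labels; both classes must be present.
#' @param scores Class-1 probabilities or scores.
#' @return A list with `roc_points` (data.frame `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores))
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y_true[ord]
  # collapse tied scores so they cross the threshold together
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y == 1L, grp, sum)
  fp <- tapply(y == 0L, grp, sum)
  tpr <- c(0, cumsum(tp) / n_pos)
  fpr <- c(0, cumsum(fp) / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = as.numeric(fpr),
                               tpr = as.numeric(tpr)),
       auc = as.numeric(auc))
}

#' Experiment configuration
#'
#' Bundles every tunable of the pipeline with its default: vocabulary size
#' `K = 128` and blend weight `alpha = 0.15` (the operating point of the
#' method), ensemble mixing `lambda = "auto"` (validation-selected, the
#' fixed alternative being 0.3), `repeats = 10` stratified 6:2:2 splits, and
#' the preprocessing, detector, descriptor, vocabulary and classifier
#' settings documented in the respective constructors.
#'
#' @param K Number of visual words.
#' @param alpha Encoding blend weight in \[0, 1\].
#' @param lambda `"auto"` or a fixed value in \[0, 1\].
#' @param repeats Number of repeated splits.
#' @param seed Master seed; all per-repeat and per-stage seeds derive from
#'   it.
#' @param n_augment Augmented variants per training image (0 disables
#'   augmentation).
#' @param denoise,equalize Toggle wavelet denoising / masked histogram
#'   equalization.
#' @param max_keypoints Cap on keypoints kept per image (strongest absolute
#'   DoG response first); `Inf` keeps all.
#' @param scale_space A [scale_space_params()].
#' @param hog A [hog_params()].
#' @param augment_cfg An [augment_config()] (its `n_augments_per_image` is
#'   overridden by `n_augment`).
#' @param gmm_max_iter,gmm_tol EM stopping controls for [fit_gmm()].
#' @param bls_params,svm_params Named lists forwarded to [fit_bls()] /
#'   [fit_margin_classifier()].
#' @return A list of class `wbovw_config`.
#' @export
wbovw_config <- function(K = 128L, alpha = 0.15, lambda = "auto",
                         repeats = 10L, seed = 1L, n_augment = 2L,
                         denoise = TRUE, equalize = TRUE,
                         max_keypoints = 500L,
                         scale_space = scale_space_params(),
                         hog = hog_params(),
                         augment_cfg = augment_config(),
                         gmm_max_iter = 50L, gmm_tol = 1e-3,
                         bls_params = list(), svm_params = list()) {
  stopifnot(K >= 2L, alpha >= 0, alpha <= 1, repeats >= 1L)
  if (!identical(lambda, "auto")) {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
  }
  augment_cfg$n_augments_per_image <- as.integer(n_augment)
  structure(list(K = as.integer(K), alpha = alpha, lambda = lambda,
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 n_augment = as.integer(n_augment), denoise = denoise,
                 equalize = equalize, max_keypoints = max_keypoints,
                 scale_space = scale_space, hog = hog,
                 augment_cfg = augment_cfg,
                 gmm_max_iter = as.integer(gmm_max_iter), gmm_tol = gmm_tol,
                 bls_params = bls_params, svm_params = svm_params),
            class = "wbovw_config")
}

# Preprocess one ROI: wavelet denoise, then masked histogram equalization.
preprocess_roi <- function(pixels, mask, config) {
  img <- pixels
  if (config$denoise) {
    img <- denoise_wavelet(img)
    img[!mask] <- 0
  }
  if (config$equalize) {
    img <- equalize_hist(img, mask)
    img[!mask] <- 0
  }
  img
}

# Keypoints + descriptors of one preprocessed ROI, with the per-image cap.
image_descriptors <- function(img, mask, config) {
  kps <- detect_keypoints(img, config$scale_space, mask, config$hog)
  if (nrow(kps) > config$max_keypoints) {
    keep <- order(abs(kps$response), decreasing = TRUE)[
      seq_len(config$max_keypoints)]
    kps <- kps[sort(keep), , drop = FALSE]
  }
  describe_image(img, kps, config$hog, mask)
}

#' Extract ROIs and descriptors for a whole manifest
#'
#' Reads each image, extracts and preprocesses its circular ROI, and
#' computes its keypoint descriptor matrix. This is the deterministic
#' feature-extraction front end shared by [run_experiment()] and the
#' command-line tool.
#'
#' @param manifest Manifest data.frame from [load_manifest()] or a path.
#' @param config A [wbovw_config()].
#' @return A list with `desc` (named list of descriptor matrices), `rois`
#'   (named list of `pixels`/`mask` pairs) and `labels` (named integer
#'   vector).
#' @export
corpus_descriptors <- function(manifest, config = wbovw_config()) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  n_img <- nrow(manifest)
  desc <- rois <- stats::setNames(vector("list", n_img), manifest$image_id)
  for (i in seq_len(n_img)) {
    img <- read_gray_image(manifest$path[i])
    roi <- extract_roi(img, manifest$center_x[i], manifest$center_y[i],
                       manifest$radius[i])
    pre <- preprocess_roi(roi$pixels, roi$mask, config)
    rois[[i]] <- roi
    desc[[i]] <- image_descriptors(pre, roi$mask, config)
  }
  list(desc = desc, rois = rois,
       labels = stats::setNames(as.integer(manifest$label),
                                manifest$image_id))
}

#' Run the full evaluation experiment
#'
#' For each repeat: a stratified 6:2:2 split; wavelet denoising, masked
#' histogram equalization; DoG keypoints + HOG descriptors; a Gaussian
#' mixture vocabulary fitted on training descriptors only (training images
#' plus their augmented variants); alpha-blend encoding of every image;
#' BLS + margin-classifier ensemble fitted on the training encodings with
#' lambda selected on validation; metrics on the held-out test split.
#' Augmentation never touches validation or test images, and no test-set
#' information reaches any fitted parameter. All randomness derives from the
#' master seed, so two runs with the same manifest and configuration are
#' identical.
#'
#' @param manifest A manifest data.frame from [load_manifest()] (or a path
#'   to one).
#' @param config A [wbovw_config()].
#' @param verbose Log per-stage progress to stderr.
#' @return A report list of class `wbovw_report`: `per_repeat` (data.frame
#'   of accuracy, recall, precision, f1, auc, chosen lambda, degenerate
#'   encoding count per repeat), `mean` and `best` metric summaries, the
#'   pooled test `confusion` matrix, and the `config` echo.
#' @export
run_experiment <- function(manifest, config = wbovw_config(),
                           verbose = FALSE) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  stopifnot(inherits(config, "wbovw_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  n_img <- nrow(manifest)
  ids <- manifest$image_id

  say("extracting base features for %d images", n_img)
  t0 <- proc.time()[3]
  feats <- corpus_descriptors(manifest, config)
  base <- stats::setNames(lapply(ids, function(id) {
    list(roi = feats$rois[[id]], desc = feats$desc[[id]])
  }), ids)
  say("base features done in %.1fs", proc.time()[3] - t0)

  seeds <- derive_seeds(config$seed, config$repeats * 4L)
  per_repeat <- list()
  confusion <- matrix(0, 2, 2, dimnames = list(truth = c("normal", "fgr"),
                                               predicted = c("normal", "fgr")))
  for (r in seq_len(config$repeats)) {
    s <- seeds[(r - 1L) * 4L + 1:4]
    plan <- split_6_2_2(ids, manifest$label, seed = s[1])
    lab <- stats::setNames(manifest$label, ids)

    # train-only augmentation, after the split
    train_desc <- lapply(plan$train, function(id) base[[id]]$desc)
    train_lab <- unname(lab[plan$train])
    if (config$n_augment > 0L) {
      aug_seeds <- derive_seeds(s[2], length(plan$train))
      for (j in seq_along(plan$train)) {
        id <- plan$train[j]
        roi <- base[[id]]$roi
        variants <- augment(roi$pixels, config$augment_cfg,
                            seed = aug_seeds[j], mask = roi$mask)
        for (v in variants) {
          pre <- preprocess_roi(v$pixels, v$mask, config)
          train_desc <- c(train_desc,
                          list(image_descriptors(pre, v$mask, config)))
          train_lab <- c(train_lab, lab[[id]])
        }
      }
    }

    pool <- do.call(rbind, train_desc)
    say("repeat %d: fitting K=%d vocabulary on %d descriptors",
        r, config$K, nrow(pool))
    vocab <- fit_gmm(pool, K = config$K, seed = s[3],
                     max_iter = config$gmm_max_iter, tol = config$gmm_tol)

    X_train <- encode_corpus(vocab, train_desc, config$alpha)
    X_val <- encode_corpus(vocab,
                           lapply(plan$val, function(id) base[[id]]$desc),
                           config$alpha)
    X_test <- encode_corpus(vocab,
                            lapply(plan$test, function(id) base[[id]]$desc),
                            config$alpha)
    n_degenerate <- sum(attr(X_train, "degenerate")) +
      sum(attr(X_val, "degenerate")) + sum(attr(X_test, "degenerate"))

    lam_grid <- if (identical(config$lambda, "auto")) {
      seq(0, 1, by = 0.1)
    } else {
      config$lambda
    }
    model <- fit_ensemble(X_train, train_lab,
                          X_val, unname(lab[plan$val]),
                          lam_grid = lam_grid,
                          bls_params = config$bls_params,
                          svm_params = config$svm_params, seed = s[4])

    pred <- predict_ensemble(model, X_test)
    y_test <- unname(lab[plan$test])
    m <- compute_metrics(y_test, pred$label)
    roc <- roc_auc(y_test, pred$prob[, "fgr"])
    confusion <- confusion + m$confusion
    per_repeat[[r]] <- data.frame(
      repeat_index = r, accuracy = m$accuracy, recall = m$recall,
      precision = m$precision, f1 = m$f1, auc = roc$auc,
      lambda = model$lambda, n_degenerate = n_degenerate
    )
    say("repeat %d: acc=%.3f auc=%.3f lambda=%.1f",
        r, m$accuracy, roc$auc, model$lambda)
  }
  per_repeat <- do.call(rbind, per_repeat)
  metric_cols <- c("accuracy", "recall", "precision", "f1", "auc")
  structure(list(
    per_repeat = per_repeat,
    mean = as.list(colMeans(per_repeat[metric_cols])),
    best = as.list(apply(per_repeat[metric_cols], 2, max)),
    confusion = confusion,
    config = list(K = config$K, alpha = config$alpha,
                  lambda = config$lambda, repeats = config$repeats,
                  seed = config$seed, n_augment = config$n_augment,
                  max_keypoints = config$max_keypoints)
  ), class = "wbovw_report")
}

#' Serialize an evaluation report to JSON
#'
#' Deterministic full-precision JSON, so identical reports produce
#' byte-identical files.
#'
#' @param report A [run_experiment()] report.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "wbovw_report"))
  obj <- list(config = report$config,
              per_repeat = report$per_repeat,
              mean = report$mean, best = report$best,
              confusion = report$confusion)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.wbovw_report <- function(x, ...) {
  cat("WBOVW evaluation report (", nrow(x$per_repeat), " repeats)\n",
      sep = "")
  cat(sprintf(
    "  mean: accuracy %.4f recall %.4f precision %.4f f1 %.4f auc %.4f\n",
    x$mean$accuracy, x$mean$recall, x$mean$precision, x$mean$f1,
    x$mean$auc))
  cat("  pooled test confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}
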