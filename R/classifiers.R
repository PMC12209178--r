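# Binary classification of encoded images: a broad learning system (random
# feature-mapping layer, tanh enhancement layer, closed-form ridge output
# weights), an RBF-kernel margin classifier exposing signed hyperplane
# distances, and their lambda-weighted probability ensemble
#   Y_j = lambda * softmax(Y_BLS)_j + (1 - lambda) * sigmoid(dist_j).

one_hot <- function(y, n_classes = 2L) {
  y <- as.integer(y)
  stopifnot(all(y %in% 0:(n_classes - 1L)))
  m <- matrix(0, length(y), n_classes)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

#' Fit a broad learning system
#'
#' Features are expanded by `n_map` random affine mapping groups
#' `Z_i = X W_i + beta_i` (weights drawn uniformly on \[-1, 1\]), the
#' concatenated mapping nodes pass through one tanh enhancement layer
#' `H = tanh(Z W_h + beta_h)`, and the output weights solving the ridge
#' problem `min ||A W - Y||^2 + eps ||W||^2` over `A = [Z | H]` are obtained
#' in closed form as `(A'A + eps I)^{-1} A' Y`. Deterministic given the seed.
#'
#' @param X Feature matrix (rows = samples).
#' @param Y One-hot label matrix (or a 0/1 label vector, converted).
#' @param n_map Number of mapping groups.
#' @param map_dim Nodes per mapping group.
#' @param m_enh Enhancement nodes.
#' @param eps Ridge regularization, > 0.
#' @param seed Integer seed for the random layer weights.
#' @return An object of class `wbovw_bls`.
#' @export
fit_bls <- function(X, Y, n_map = 10L, map_dim = 10L, m_enh = 100L,
                    eps = 1e-3, seed = 1L) {
  X <- as.matrix(X)
  if (is.vector(Y) || is.factor(Y)) Y <- one_hot(Y)
  if (nrow(X) < 2L) stop("need at least 2 training rows", call. = FALSE)
  if (nrow(Y) != nrow(X)) stop("X and Y row counts differ", call. = FALSE)
  if (any(colSums(Y) == 0)) {
    stop("both classes must be present in the training labels",
         call. = FALSE)
  }
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  d <- ncol(X)
  model <- with_seed(seed, {
    W_map <- lapply(seq_len(n_map), function(i) {
      matrix(stats::runif(d * map_dim, -1, 1), d, map_dim)
    })
    b_map <- lapply(seq_len(n_map), function(i) {
      stats::runif(map_dim, -1, 1)
    })
    W_enh <- matrix(stats::runif(n_map * map_dim * m_enh, -1, 1),
                    n_map * map_dim, m_enh)
    b_enh <- stats::runif(m_enh, -1, 1)
    list(W_map = W_map, b_map = b_map, W_enh = W_enh, b_enh = b_enh,
         n_map = as.integer(n_map), map_dim = as.integer(map_dim),
         m_enh = as.integer(m_enh), eps = eps, seed = as.integer(seed),
         d = d)
  })
  A <- bls_design(model, X)
  n_a <- ncol(A)
  model$W_out <- solve(crossprod(A) + eps * diag(n_a), crossprod(A, Y))
  class(model) <- "wbovw_bls"
  model
}

# [Z | H] design matrix for stored random weights.
bls_design <- function(model, X) {
  Z <- do.call(cbind, lapply(seq_len(model$n_map), function(i) {
    sweep(X %*% model$W_map[[i]], 2, model$b_map[[i]], "+")
  }))
  H <- tanh(sweep(Z %*% model$W_enh, 2, model$b_enh, "+"))
  cbind(Z, H)
}

#' Raw BLS class scores
#'
#' `Y_BLS = [Z_1..Z_n | H] W` — unnormalized per-class scores; the ensemble
#' converts them to probabilities with a softmax.
#'
#' @param model A fitted [fit_bls()] model.
#' @param X Feature matrix with the training column count.
#' @return Score matrix, one row per row of `X`.
#' @export
bls_scores <- function(model, X) {
  stopifnot(inherits(model, "wbovw_bls"))
  X <- as.matrix(X)
  if (ncol(X) != model$d) {
    stop("feature dimension mismatch: expected ", model$d, ", got ", ncol(X),
         call. = FALSE)
  }
  bls_design(model, X) %*% model$W_out
}

#' Fit the margin classifier
#'
#' RBF-kernel support vector machine (via \pkg{e1071}); its signed decision
#' value is the margin quantity used as the "distance to the hyperplane" in
#' the ensemble, oriented so positive values favor class 1 (FGR).
#'
#' @param X Feature matrix.
#' @param y Integer 0/1 labels.
#' @param cost Soft-margin cost C.
#' @param gamma RBF width; defaults to `1 / ncol(X)`.
#' @return An object of class `wbovw_margin`.
#' @importFrom e1071 svm
#' @export
fit_margin_classifier <- function(X, y, cost = 1, gamma = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  fit <- e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(svm = fit, cost = cost, gamma = gamma),
            class = "wbovw_margin")
}

#' Signed distance to the separating hyperplane
#'
#' Positive values indicate class 1 (FGR).
#'
#' @param model A fitted [fit_margin_classifier()].
#' @param X Feature matrix.
#' @return Numeric vector of signed distances.
#' @export
margin_distance <- function(model, X) {
  stopifnot(inherits(model, "wbovw_margin"))
  pred <- stats::predict(model$svm, as.matrix(X), decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # e1071 orients decision values toward the first factor level; flip so
  # positive always means class "1".
  if (colnames(dv)[1] == "0/1") -as.numeric(dv) else as.numeric(dv)
}

#' Sigmoid distance-to-probability map
#'
#' @param d Finite signed distance(s).
#' @return `1 / (1 + exp(-d))`.
#' @export
svm_distance_to_prob <- function(d) {
  stopifnot(all(is.finite(d)))
  stats::plogis(d)
}

#' Lambda-weighted ensemble probability
#'
#' `Y_j = lambda * softmax(y_bls)_j + (1 - lambda) * sigmoid(dist_j)` for the
#' two classes j = 0, 1. The first term is bounded by `lambda` and the
#' second by `1 - lambda`, so each output lies in \[0, 1\] (the two class
#' outputs need not sum to 1; the predicted label is the argmax, ties going
#' to class 0).
#'
#' @param y_bls_row Length-2 BLS score vector for one sample.
#' @param dists Length-2 per-class signed distances `(dist_0, dist_1)`; for
#'   the binary margin classifier `dist_0 = -dist_1`.
#' @param lam Mixing weight in \[0, 1\].
#' @return Length-2 probability vector.
#' @export
ensemble_probability <- function(y_bls_row, dists, lam) {
  if (lam < 0 || lam > 1) stop("lambda must lie in [0, 1]", call. = FALSE)
  e <- exp(y_bls_row - max(y_bls_row))
  lam * e / sum(e) + (1 - lam) * svm_distance_to_prob(dists)
}

#' Fit the BLS + margin-classifier ensemble
#'
#' Both base models are fitted on the training split; the mixing weight
#' `lambda` is then selected from `lam_grid` by validation accuracy (ties
#' broken toward the smaller `lambda`). With an empty validation set the
#' default `lambda = 0.3` is used with a warning.
#'
#' @param X_train,y_train Training features and 0/1 labels.
#' @param X_val,y_val Validation features and labels (may be empty).
#' @param lam_grid Candidate mixing weights; a single value fixes `lambda`.
#' @param bls_params Named list of [fit_bls()] arguments.
#' @param svm_params Named list of [fit_margin_classifier()] arguments.
#' @param seed Seed forwarded to the BLS random layers.
#' @return An object of class `wbovw_ensemble` with the fitted parts,
#'   the chosen `lambda`, and the per-candidate validation accuracies.
#' @export
fit_ensemble <- function(X_train, y_train, X_val = NULL, y_val = NULL,
                         lam_grid = seq(0, 1, by = 0.1),
                         bls_params = list(), svm_params = list(),
                         seed = 1L) {
  bls <- do.call(fit_bls, c(list(X = X_train, Y = y_train, seed = seed),
                            bls_params))
  svm <- do.call(fit_margin_classifier,
                 c(list(X = X_train, y = y_train), svm_params))
  val_acc <- NULL
  if (length(lam_grid) == 1L) {
    lambda <- lam_grid
  } else if (is.null(X_val) || NROW(X_val) == 0L) {
    warning("empty validation set; falling back to lambda = 0.3")
    lambda <- 0.3
  } else {
    probs1 <- ensemble_prob_matrix(bls, svm, X_val, lam = NULL)
    val_acc <- vapply(lam_grid, function(lam) {
      p <- lam * probs1$soft + (1 - lam) * probs1$sig
      pred <- max.col(p, ties.method = "first") - 1L
      mean(pred == as.integer(y_val))
    }, numeric(1))
    lambda <- lam_grid[which.max(val_acc)]
  }
  structure(list(bls = bls, svm = svm, lambda = lambda,
                 lam_grid = lam_grid, val_accuracy = val_acc),
            class = "wbovw_ensemble")
}

# Softmax and sigmoid parts for a feature matrix, so lambda candidates can
# be scored without refitting. Returns n x 2 matrices `soft` and `sig`.
ensemble_prob_matrix <- function(bls, svm, X, lam = NULL) {
  scores <- bls_scores(bls, X)
  mx <- apply(scores, 1, max)
  e <- exp(scores - mx)
  soft <- e / rowSums(e)
  d1 <- margin_distance(svm, X)
  sig <- cbind(svm_distance_to_prob(-d1), svm_distance_to_prob(d1))
  if (is.null(lam)) list(soft = soft, sig = sig)
  else lam * soft + (1 - lam) * sig
}

#' Predict with the ensemble
#'
#' @param object A fitted [fit_ensemble()] model.
#' @param X Feature matrix.
#' @param ... Unused.
#' @return A list with `prob` (n x 2 matrix of class probabilities, columns
#'   normal / fgr) and `label` (integer 0/1 predictions; ties go to 0).
#' @export
predict_ensemble <- function(object, X, ...) {
  stopifnot(inherits(object, "wbovw_ensemble"))
  prob <- ensemble_prob_matrix(object$bls, object$svm, X, lam = object$lambda)
  colnames(prob) <- c("normal", "fgr")
  label <- max.col(prob, ties.method = "first") - 1L
  list(prob = prob, label = label)
}

#' Save / load a fitted ensemble
#'
#' Single-file container (RDS) bundling the BLS weights, the margin
#' classifier, the mixing weight and seeds; round-trips bit-exactly.
#'
#' @param model A fitted ensemble.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "wbovw_ensemble"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "wbovw_ensemble"))
  model
}
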