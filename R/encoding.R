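# Weight-scaled bag-of-visual-words encoding: each image becomes the
# alpha-blend of its mean soft responsibility vector and its hard-assignment
# histogram, U = sum_j [alpha * P_j + (1 - alpha) * Q_j] / J. This blend is
# the pipeline's core statistic; alpha = 1 recovers the probability-weighted
# average and alpha = 0 the hard visual-word histogram.

#' Hard assignment of a responsibility vector
#'
#' One-hot vector at the argmax responsibility; ties are broken toward the
#' lowest index so the assignment is deterministic.
#'
#' @param p Probability simplex vector.
#' @return 0/1 vector of the same length with exactly one 1.
#' @export
hard_assign <- function(p) {
  q <- numeric(length(p))
  q[which.max(p)] <- 1
  q
}

#' Encode one image
#'
#' Blends soft responsibilities and hard assignments over the image's
#' keypoints. Because each `P_j` and `Q_j` is a simplex vector, the encoding
#' sums to 1 for every `alpha` in \[0, 1\], and it is affine in `alpha`:
#' `U(alpha) = alpha * U(1) + (1 - alpha) * U(0)`. An image with zero
#' surviving keypoints cannot be encoded from data; it receives the uniform
#' vector `1/K` and is flagged (attribute `degenerate`), so whole-corpus
#' evaluations complete while reporting the affected images.
#'
#' @param vocab A fitted [fit_gmm()] vocabulary.
#' @param V Descriptor matrix of the image (rows = keypoints; may be empty).
#' @param alpha Blend weight in \[0, 1\]; default 0.15.
#' @return Numeric K-vector summing to 1, with attributes `J` (keypoint
#'   count) and `degenerate` (logical).
#' @export
encode_image <- function(vocab, V, alpha = 0.15) {
  stopifnot(inherits(vocab, "wbovw_vocabulary"))
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  K <- vocab$K
  J <- nrow(V)
  if (is.null(J) || J == 0L) {
    u <- rep(1 / K, K)
    attr(u, "J") <- 0L
    attr(u, "degenerate") <- TRUE
    return(u)
  }
  P <- responsibilities_matrix(vocab, V)
  amax <- max.col(P, ties.method = "first")
  Q <- matrix(0, J, K)
  Q[cbind(seq_len(J), amax)] <- 1
  u <- colSums(alpha * P + (1 - alpha) * Q) / J
  attr(u, "J") <- J
  attr(u, "degenerate") <- FALSE
  u
}

#' Encode a corpus of images
#'
#' @param vocab A fitted vocabulary.
#' @param mats List of descriptor matrices, one per image, in corpus order.
#' @param alpha Blend weight in \[0, 1\].
#' @return Matrix with one K-column row per image, attribute `degenerate`
#'   holding the logical flag vector.
#' @export
encode_corpus <- function(vocab, mats, alpha = 0.15) {
  K <- vocab$K
  n <- length(mats)
  U <- matrix(0, n, K)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    u <- encode_image(vocab, mats[[i]], alpha)
    U[i, ] <- u
    degenerate[i] <- attr(u, "degenerate")
  }
  attr(U, "degenerate") <- degenerate
  U
}
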