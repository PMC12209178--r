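# Visual vocabulary: a K-component Gaussian mixture fitted by EM over all
# training descriptors. Component densities and posterior responsibilities
# are computed in log space throughout, so far-outlying descriptors still
# produce a valid probability simplex.

# kmeans++ center selection (D^2 sampling); returns row indices of X.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  if (K > 1L) {
    for (k in 2:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[k] <- sample.int(n, 1L, prob = p)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[k], ])^2))
    }
  }
  idx
}

# N x K matrix of log(pi_k) + log N(x | mu_k, Sigma_k).
gmm_log_weighted_densities <- function(vocab, X) {
  K <- vocab$K
  d <- ncol(vocab$means)
  if (ncol(X) != d) stop("descriptor dimension mismatch", call. = FALSE)
  if (vocab$covariance_type == "diagonal") {
    iv <- 1 / vocab$variances                       # K x d
    const <- rowSums(log(2 * pi * vocab$variances)) # K
    quad <- X^2 %*% t(iv) - 2 * X %*% t(vocab$means * iv) +
      matrix(rowSums(vocab$means^2 * iv), nrow(X), K, byrow = TRUE)
    sweep(-0.5 * sweep(quad, 2, const, "+"), 2, log(vocab$weights), "+")
  } else {
    out <- matrix(0, nrow(X), K)
    for (k in seq_len(K)) {
      ch <- chol(vocab$covariances[, , k])
      z <- backsolve(ch, t(sweep(X, 2, vocab$means[k, ])), transpose = TRUE)
      out[, k] <- log(vocab$weights[k]) - sum(log(diag(ch))) -
        0.5 * d * log(2 * pi) - 0.5 * colSums(z^2)
    }
    out
  }
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Fit a Gaussian-mixture visual vocabulary by EM
#'
#' Components are initialized from a k-means++-seeded k-means partition and
#' refined by expectation-maximization until the data log-likelihood gain
#' drops below `tol` or `max_iter` is reached. Covariances are diagonal by
#' default (full covariances are impractical at 144 dimensions unless the
#' descriptor count is very large) with a variance floor; a component that
#' collapses onto too few points is re-seeded onto a random descriptor once,
#' then kept at the floor. The per-iteration log-likelihood trace is stored
#' and is non-decreasing, the standard EM guarantee.
#'
#' @param X Descriptor matrix (rows = keypoints pooled over training
#'   images).
#' @param K Number of mixture components (visual words).
#' @param seed Integer seed controlling initialization.
#' @param max_iter Maximum EM iterations.
#' @param tol Stop when the log-likelihood improves by less than this.
#' @param var_floor Lower bound applied to every variance.
#' @param covariance_type `"diagonal"` (default) or `"full"`.
#' @return An object of class `wbovw_vocabulary` with elements `K`,
#'   `weights`, `means`, `variances` (or `covariances`), `loglik_trace`,
#'   `seed`, `covariance_type`.
#' @export
fit_gmm <- function(X, K, seed = 1L, max_iter = 100L, tol = 1e-4,
                    var_floor = 1e-6,
                    covariance_type = c("diagonal", "full")) {
  covariance_type <- match.arg(covariance_type)
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (K < 1L) stop("K must be at least 1", call. = FALSE)
  if (n < K) {
    stop("fewer descriptors (", n, ") than components (", K,
         "); use a smaller K", call. = FALSE)
  }
  with_seed(seed, {
    centers <- X[kmeanspp_centers(X, K), , drop = FALSE]
    km <- if (K > 1L) {
      suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 20L))
    } else {
      list(cluster = rep(1L, n), centers = matrix(colMeans(X), 1L))
    }
    means <- km$centers
    weights <- as.numeric(tabulate(km$cluster, K)) / n
    weights <- pmax(weights, 1e-10); weights <- weights / sum(weights)
    global_var <- pmax(apply(X, 2, stats::var), var_floor)
    if (any(!is.finite(global_var))) global_var <- rep(var_floor, d)
    if (covariance_type == "diagonal") {
      variances <- matrix(0, K, d)
      for (k in seq_len(K)) {
        xk <- X[km$cluster == k, , drop = FALSE]
        variances[k, ] <- if (nrow(xk) > 1L) {
          pmax(apply(xk, 2, stats::var), var_floor)
        } else {
          global_var
        }
      }
      covariances <- NULL
    } else {
      covariances <- array(0, c(d, d, K))
      for (k in seq_len(K)) {
        xk <- X[km$cluster == k, , drop = FALSE]
        cv <- if (nrow(xk) > d) stats::cov(xk) else diag(global_var, d)
        covariances[, , k] <- cv + diag(var_floor, d)
      }
      variances <- NULL
    }
    vocab <- structure(list(K = as.integer(K), weights = weights,
                            means = means, variances = variances,
                            covariances = covariances,
                            covariance_type = covariance_type,
                            seed = as.integer(seed),
                            loglik_trace = numeric(0)),
                       class = "wbovw_vocabulary")
    reseeded <- logical(K)
    trace <- numeric(0)
    prev_ll <- -Inf
    for (it in seq_len(max_iter)) {
      lwd <- gmm_log_weighted_densities(vocab, X)
      lse <- logsumexp_rows(lwd)
      ll <- sum(lse)
      trace <- c(trace, ll)
      resp <- exp(lwd - lse)
      if (is.finite(prev_ll) && ll - prev_ll < tol) break
      prev_ll <- ll
      nk <- colSums(resp)
      collapsed <- which(nk < 1e-8)
      for (k in collapsed) {
        if (!reseeded[k]) {
          warning("mixture component ", k,
                  " collapsed; re-seeding onto a random descriptor")
          vocab$means[k, ] <- X[sample.int(n, 1L), ]
          if (covariance_type == "diagonal") {
            vocab$variances[k, ] <- global_var
          } else {
            vocab$covariances[, , k] <- diag(global_var, d)
          }
          reseeded[k] <- TRUE
        }
        nk[k] <- max(nk[k], 1e-8)
      }
      keep <- setdiff(seq_len(K), collapsed)
      vocab$weights <- pmax(nk / sum(nk), 1e-12)
      vocab$weights <- vocab$weights / sum(vocab$weights)
      mu_new <- t(resp) %*% X / nk
      vocab$means[keep, ] <- mu_new[keep, , drop = FALSE]
      if (covariance_type == "diagonal") {
        ex2 <- t(resp) %*% X^2 / nk
        v_new <- pmax(ex2 - mu_new^2, var_floor)
        vocab$variances[keep, ] <- v_new[keep, , drop = FALSE]
      } else {
        for (k in keep) {
          xc <- sweep(X, 2, vocab$means[k, ])
          cv <- crossprod(xc * resp[, k], xc) / nk[k]
          vocab$covariances[, , k] <- cv + diag(var_floor, d)
        }
      }
    }
    vocab$loglik_trace <- trace
    vocab
  })
}

#' Weighted component density
#'
#' Evaluates `pi_k * N(v | u_k, Sigma_k)`, the unnormalized contribution of
#' component `k` to the mixture density at `v`, computed in log space to
#' avoid underflow in high dimension.
#'
#' @param vocab A fitted [fit_gmm()] vocabulary.
#' @param v Descriptor vector.
#' @param k Component index (1-based).
#' @return Non-negative density value.
#' @export
component_density <- function(vocab, v, k) {
  stopifnot(inherits(vocab, "wbovw_vocabulary"))
  if (k < 1L || k > vocab$K) stop("component index out of range",
                                  call. = FALSE)
  lwd <- gmm_log_weighted_densities(vocab, matrix(v, 1L))
  exp(lwd[1L, k])
}

#' Posterior responsibilities of a descriptor
#'
#' `p_k = pi_k N(v) / sum_k' pi_k' N(v)`, evaluated with the log-sum-exp
#' trick so the result is a valid probability simplex point even when every
#' raw density underflows double precision.
#'
#' @param vocab A fitted vocabulary.
#' @param v Descriptor vector.
#' @return Numeric K-vector, entries >= 0 summing to 1.
#' @export
responsibilities <- function(vocab, v) {
  as.numeric(responsibilities_matrix(vocab, matrix(v, 1L)))
}

#' Responsibilities of many descriptors at once
#'
#' @param vocab A fitted vocabulary.
#' @param X Descriptor matrix, one row per keypoint.
#' @return Matrix of the same row count, K columns, rows summing to 1.
#' @export
responsibilities_matrix <- function(vocab, X) {
  stopifnot(inherits(vocab, "wbovw_vocabulary"))
  if (nrow(X) == 0L) return(matrix(0, 0L, vocab$K))
  lwd <- gmm_log_weighted_densities(vocab, X)
  exp(lwd - logsumexp_rows(lwd))
}

#' Save / load a vocabulary
#'
#' Single-file container (RDS) holding the component count, weights, means,
#' covariance parameters, seed and log-likelihood trace; round-trips
#' bit-exactly.
#'
#' @param vocab A fitted vocabulary.
#' @param path File path.
#' @return `write_vocabulary()` returns `path` invisibly;
#'   `read_vocabulary()` returns the vocabulary.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "wbovw_vocabulary"))
  saveRDS(vocab, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  vocab <- readRDS(path)
  stopifnot(inherits(vocab, "wbovw_vocabulary"))
  vocab
}

#' @export
print.wbovw_vocabulary <- function(x, ...) {
  cat("Gaussian-mixture visual vocabulary\n")
  cat("  components:", x$K, " dimension:", ncol(x$means),
      " covariance:", x$covariance_type, "\n")
  cat("  EM iterations:", length(x$loglik_trace),
      " final log-likelihood:",
      format(utils::tail(x$loglik_trace, 1)), "\n")
  invisible(x)
}
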