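# Broad learning system, margin classifier and the lambda ensemble.

blobs <- function(n_per, d = 4, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), ncol = d),
             matrix(rnorm(n_per * d, mean = sep / sqrt(d)), ncol = d))
  y <- rep(c(0L, 1L), each = n_per)
  list(X = X, y = y)
}

test_that("BLS output weights solve the ridge problem", {
  set.seed(1)
  X <- matrix(rnorm(20 * 8), 20, 8)
  Y <- wbovw:::one_hot(sample(0:1, 20, replace = TRUE, prob = c(0.5, 0.5)))
  eps <- 1e-3
  m <- fit_bls(X, Y, n_map = 3, map_dim = 4, m_enh = 10, eps = eps,
               seed = 5)
  A <- wbovw:::bls_design(m, X)
  expect_lt(max(abs(m$W_out - oracle_ridge(A, Y, eps))), 1e-8)

  # ridge limit: training residual decreases monotonically as eps -> 0
  res <- sapply(10^seq(-1, -9, by = -2), function(e) {
    mm <- fit_bls(X, Y, n_map = 3, map_dim = 4, m_enh = 10, eps = e,
                  seed = 5)
    norm(wbovw:::bls_design(mm, X) %*% mm$W_out - Y, "F")
  })
  expect_true(all(diff(res) <= 1e-10))
})

test_that("the output-weight norm is non-increasing in the ridge epsilon", {
  set.seed(2)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rep(0:1, 15)
  norms <- sapply(10^seq(-4, 0), function(eps) {
    m <- fit_bls(X, y, n_map = 2, map_dim = 3, m_enh = 8, eps = eps,
                 seed = 3)
    norm(m$W_out, "2")
  })
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("BLS scores reproduce the stored forward pass", {
  b <- blobs(15, seed = 4)
  m <- fit_bls(b$X, b$y, n_map = 2, map_dim = 3, m_enh = 6, seed = 9)
  S <- bls_scores(m, b$X)
  # independent forward-pass recomputation from the stored weights
  Z <- do.call(cbind, lapply(1:2, function(i) {
    sweep(b$X %*% m$W_map[[i]], 2, m$b_map[[i]], "+")
  }))
  H <- tanh(sweep(Z %*% m$W_enh, 2, m$b_enh, "+"))
  expect_lt(max(abs(S - cbind(Z, H) %*% m$W_out)), 1e-12)

  # duplicate rows give identical scores; training scores equal A W exactly
  S2 <- bls_scores(m, b$X[c(1, 1), ])
  expect_identical(S2[1, ], S2[2, ])
  expect_error(bls_scores(m, b$X[, 1:3]), "dimension")
})

test_that("BLS input validation rejects degenerate problems", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(fit_bls(X, rep(0L, 5)), "classes")
  expect_error(fit_bls(X, c(0, 1, 0, 1, 0), eps = 0), "eps")
  expect_error(fit_bls(X[1, , drop = FALSE], 1L), "2 training rows")
})

test_that("the sigmoid distance map has the right fixed points", {
  expect_equal(svm_distance_to_prob(0), 0.5)
  expect_equal(svm_distance_to_prob(log(3)), 0.75)
  expect_equal(svm_distance_to_prob(50), 1, tolerance = 1e-12)
  expect_equal(svm_distance_to_prob(-50), 0, tolerance = 1e-12)
  d <- seq(-5, 5, 0.5)
  expect_true(all(diff(svm_distance_to_prob(d)) > 0))
})

test_that("margin distances separate well-separated classes by sign", {
  b <- blobs(25, sep = 6, seed = 11)
  m <- fit_margin_classifier(b$X, b$y)
  d <- margin_distance(m, b$X)
  expect_true(mean(d[b$y == 1] > 0) > 0.95)
  expect_true(mean(d[b$y == 0] < 0) > 0.95)
})

test_that("ensemble probabilities follow the lambda blend", {
  # endpoints
  yb <- c(1, 0); dists <- c(log(3), -log(3))
  soft <- exp(yb) / sum(exp(yb))
  expect_equal(ensemble_probability(yb, dists, 1), soft)
  expect_equal(ensemble_probability(yb, dists, 0),
               svm_distance_to_prob(dists))
  # symmetry
  expect_equal(ensemble_probability(c(0, 0), c(0, 0), 0.4), c(0.5, 0.5))
  # hand evaluation at lambda = 0.3
  want <- 0.3 * soft + 0.7 * c(0.75, 0.25)
  expect_equal(ensemble_probability(yb, c(log(3), -log(3)), 0.3), want)
  # bounds: term-wise caps
  set.seed(6)
  for (i in 1:50) {
    lam <- runif(1)
    p <- ensemble_probability(rnorm(2, sd = 3), rnorm(2, sd = 3), lam)
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_error(ensemble_probability(yb, dists, 1.5), "lambda")
})

test_that("lambda selection prefers accuracy and breaks ties downward", {
  b <- blobs(20, sep = 8, seed = 21)
  v <- blobs(10, sep = 8, seed = 22)
  m <- fit_ensemble(b$X, b$y, v$X, v$y, seed = 1)
  # separable: every lambda is perfect on validation, tie -> 0
  expect_equal(m$lambda, 0)
  expect_equal(max(m$val_accuracy), 1)

  m2 <- fit_ensemble(b$X, b$y, v$X, v$y, seed = 1)
  expect_equal(m$lambda, m2$lambda)

  expect_warning(m3 <- fit_ensemble(b$X, b$y, NULL, NULL, seed = 1),
                 "0.3")
  expect_equal(m3$lambda, 0.3)
})

test_that("lambda moves toward the better base model", {
  # degrade the BLS by training it on heavily label-noised data while the
  # margin classifier sees clean labels, then replicate the selection rule
  b <- blobs(40, sep = 5, seed = 31)
  v <- blobs(20, sep = 5, seed = 32)
  set.seed(33)
  y_noisy <- b$y
  flip <- sample(length(y_noisy), length(y_noisy) * 0.45)
  y_noisy[flip] <- 1L - y_noisy[flip]
  bls <- fit_bls(b$X, y_noisy, seed = 2)
  svm <- fit_margin_classifier(b$X, b$y)
  grid <- seq(0, 1, 0.1)
  acc <- sapply(grid, function(lam) {
    d1 <- margin_distance(svm, v$X)
    s <- bls_scores(bls, v$X)
    pred <- sapply(seq_len(nrow(v$X)), function(i) {
      p <- ensemble_probability(s[i, ], c(-d1[i], d1[i]), lam)
      which.max(p) - 1L
    })
    mean(pred == v$y)
  })
  expect_lt(grid[which.max(acc)], 0.5)
})

test_that("lambda endpoints reproduce the single models exactly", {
  b <- blobs(25, sep = 3, seed = 41)
  t <- blobs(15, sep = 3, seed = 42)
  m1 <- fit_ensemble(b$X, b$y, lam_grid = 1, seed = 3)
  m0 <- fit_ensemble(b$X, b$y, lam_grid = 0, seed = 3)

  p1 <- predict_ensemble(m1, t$X)
  s <- bls_scores(m1$bls, t$X)
  bls_pred <- max.col(s, ties.method = "first") - 1L
  expect_identical(p1$label, bls_pred)

  p0 <- predict_ensemble(m0, t$X)
  svm_pred <- as.integer(margin_distance(m0$svm, t$X) > 0)
  expect_identical(p0$label, svm_pred)
  expect_true(all(p0$prob >= 0 & p0$prob <= 1))
})

test_that("model serialization round-trips and predicts identically", {
  b <- blobs(15, seed = 51)
  m <- fit_ensemble(b$X, b$y, lam_grid = 0.3, seed = 4)
  path <- tempfile(fileext = ".rds")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(predict_ensemble(m2, b$X), predict_ensemble(m, b$X))
})
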