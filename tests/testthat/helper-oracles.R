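# Shared fixtures and independent brute-force oracles used across the suite.
# Every oracle is a direct, unoptimized transcription of the definition it
# checks, kept independent of the package's implementation path.

seeded_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

ramp_image_x <- function(h, w) {
  matrix(rep((0:(w - 1)) / max(w - 1, 1), each = h), h, w)
}

ramp_image_y <- function(h, w) {
  matrix(rep((0:(h - 1)) / max(h - 1, 1), w), h, w)
}

# Direct 2-D convolution with symmetric reflection padding.
oracle_conv2d <- function(img, kern2d) {
  h <- nrow(img); w <- ncol(img)
  hw <- (nrow(kern2d) - 1L) %/% 2L
  refl <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    j <- ifelse(j >= n, 2L * n - 1L - j, j)
    j + 1L
  }
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    acc <- 0
    for (dr in -hw:hw) for (dc in -hw:hw) {
      acc <- acc + kern2d[dr + hw + 1L, dc + hw + 1L] *
        img[refl(r + dr, h), refl(c + dc, w)]
    }
    out[r, c] <- acc
  }
  out
}

# Exhaustive 26-neighbor strict extremum scan over one octave's DoG levels
# (list of matrices). Returns a data.frame of 0-based x, y and level.
oracle_extrema <- function(levels, thr) {
  L <- length(levels)
  h <- nrow(levels[[1]]); w <- ncol(levels[[1]])
  hits <- list()
  for (l in 2:(L - 1)) {
    for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
      v <- levels[[l]][r, c]
      if (abs(v) < thr) next
      nb <- c()
      for (dl in -1:1) for (dr in -1:1) for (dc in -1:1) {
        if (dl == 0 && dr == 0 && dc == 0) next
        nb <- c(nb, levels[[l + dl]][r + dr, c + dc])
      }
      if (v > max(nb) || v < min(nb)) {
        hits[[length(hits) + 1L]] <- data.frame(x = c - 1L, y = r - 1L,
                                                level = l, response = v)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(x = integer(0), y = integer(0), level = integer(0),
                      response = numeric(0)))
  }
  do.call(rbind, hits)
}

# Per-pixel gradient-field oracle: central differences, one-sided borders,
# unsigned orientation in [0, 180).
oracle_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- gy <- mag <- ori <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    gx[r, c] <- img[r, min(c + 1, w)] - img[r, max(c - 1, 1)]
    gy[r, c] <- img[min(r + 1, h), c] - img[max(r - 1, 1), c]
    mag[r, c] <- sqrt(gx[r, c]^2 + gy[r, c]^2)
    a <- atan2(gy[r, c], gx[r, c]) * 180 / pi
    a <- a %% 180
    if (a >= 180) a <- 0
    ori[r, c] <- a
  }
  list(gx = gx, gy = gy, magnitude = mag, orientation = ori)
}

# Per-pixel HOG window oracle: loop pixels, hard-bin, normalize per
# sub-region, concatenate in row-major sub-region order.
oracle_hog_window <- function(mag, ori, grid = 4L, n_bins = 9L,
                              eps = 1e-6) {
  side <- nrow(mag)
  cell <- side %/% grid
  desc <- c()
  for (gy in 1:grid) for (gx in 1:grid) {
    v <- numeric(n_bins)
    for (r in ((gy - 1) * cell + 1):(gy * cell)) {
      for (c in ((gx - 1) * cell + 1):(gx * cell)) {
        b <- min(floor(ori[r, c] / (180 / n_bins)) + 1, n_bins)
        v[b] <- v[b] + mag[r, c]
      }
    }
    desc <- c(desc, v / sqrt(sum(v^2) + eps^2))
  }
  desc
}

# Mann-Whitney pair-counting AUC with half credit for ties.
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# SVD pseudo-inverse ridge solution of min ||AW - Y||^2 + eps ||W||^2.
oracle_ridge <- function(A, Y, eps) {
  sv <- svd(A)
  d <- sv$d / (sv$d^2 + eps)
  sv$v %*% (d * (t(sv$u) %*% Y))
}

# Build one synthetic ROI image, preprocessed, with its mask (small default
# geometry keeps unit tests fast).
synthetic_roi <- function(label, seed, image_size = 128L, roi_radius = 50,
                          n_primitives = 60L) {
  spec <- synthetic_spec(label, image_size = image_size,
                         roi_radius = roi_radius,
                         n_primitives = n_primitives, seed = seed)
  img <- apply_speckle(render_texture(spec), spec$speckle_sigma,
                       seed = seed + 1L)
  roi <- extract_roi(img, (image_size - 1) / 2, (image_size - 1) / 2,
                     roi_radius)
  roi
}
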