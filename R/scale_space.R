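# Gaussian scale space, difference-of-Gaussians stacks, and 26-neighbor
# extremum detection. Keypoints are reported in base-image pixel coordinates
# (x = column, y = row, 0-based).

#' Scale-space parameters
#'
#' @param n_octaves Number of octaves (each half the linear size of the
#'   previous).
#' @param s Intervals per octave; the scale factor between adjacent levels is
#'   `k = 2^(1/s)` and each octave holds `s + 3` Gaussian levels.
#' @param sigma0 Base smoothing scale of the first level of each octave, in
#'   pixels of that octave.
#' @param contrast_threshold Minimum absolute DoG response for a keypoint,
#'   on \[0, 1\] intensity images.
#' @return A list of class `wbovw_scale_space_params`.
#' @export
scale_space_params <- function(n_octaves = 4L, s = 3L, sigma0 = 1.6,
                               contrast_threshold = 0.01) {
  stopifnot(n_octaves >= 1L, s >= 1L, sigma0 > 0, contrast_threshold >= 0)
  structure(list(n_octaves = as.integer(n_octaves), s = as.integer(s),
                 sigma0 = sigma0, k = 2^(1 / s),
                 contrast_threshold = contrast_threshold),
            class = "wbovw_scale_space_params")
}

# Fold arbitrary integer indices into 1..n by symmetric (edge-repeating)
# reflection, the border policy of all convolutions here.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  j + 1L
}

#' Discrete Gaussian kernel
#'
#' Samples the isotropic Gaussian at integer offsets `-h..h` with half-width
#' `h = ceiling(3 * sigma)` and normalizes the weights to sum to 1.
#'
#' @param sigma Standard deviation in pixels; must be positive.
#' @return Numeric vector of length `2 * ceiling(3 * sigma) + 1`.
#' @export
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  hw <- ceiling(3 * sigma)
  t <- (-hw):hw
  w <- exp(-t^2 / (2 * sigma^2))
  w / sum(w)
}

# 1-D convolution along rows (axis = "y") or columns (axis = "x") with
# symmetric reflection padding, vectorized over kernel taps.
convolve_axis <- function(img, kern, axis) {
  hw <- (length(kern) - 1L) %/% 2L
  if (axis == "y") {
    n <- nrow(img)
    pad <- img[reflect_index(seq.int(1L - hw, n + hw), n), , drop = FALSE]
    out <- matrix(0, n, ncol(img))
    for (t in seq_along(kern)) {
      out <- out + kern[t] * pad[seq.int(t, t + n - 1L), , drop = FALSE]
    }
  } else {
    n <- ncol(img)
    pad <- img[, reflect_index(seq.int(1L - hw, n + hw), n), drop = FALSE]
    out <- matrix(0, nrow(img), n)
    for (t in seq_along(kern)) {
      out <- out + kern[t] * pad[, seq.int(t, t + n - 1L), drop = FALSE]
    }
  }
  out
}

#' Gaussian-filter an image
#'
#' Separable convolution with the normalized kernel of [gaussian_kernel()]
#' (half-width `ceiling(3 * sigma)`), symmetric reflection at the borders.
#' Because the kernel sums to 1, a constant image is reproduced exactly.
#'
#' @param img Image matrix.
#' @param sigma Smoothing scale in pixels.
#' @return Smoothed image matrix.
#' @export
gaussian_filter_image <- function(img, sigma) {
  kern <- gaussian_kernel(sigma)
  convolve_axis(convolve_axis(img, kern, "y"), kern, "x")
}

#' Build the Gaussian pyramid
#'
#' Each octave holds `s + 3` levels smoothed at `sigma0 * k^i` (relative to
#' the octave's own pixel grid), built incrementally; the next octave is
#' seeded by 2x decimation of the level at `2 * sigma0`. Absolute scales
#' (relative scale times `2^(octave - 1)`) are recorded per level.
#'
#' @param img Image matrix.
#' @param p [scale_space_params()].
#' @return A list of class `wbovw_gaussian_pyramid`: one element per octave,
#'   each with `levels` (list of matrices) and `sigmas` / `sigmas_abs`.
#' @export
build_scale_space <- function(img, p) {
  validate_gray_image(img)
  stopifnot(inherits(p, "wbovw_scale_space_params"))
  min_side <- min(dim(img))
  max_oct <- max(1L, floor(log2(min_side / 8)))
  if (min_side < 2^p$n_octaves * 8) {
    stop("image too small for ", p$n_octaves,
         " octaves; at most ", max_oct, " feasible", call. = FALSE)
  }
  n_levels <- p$s + 3L
  sig_rel <- p$sigma0 * p$k^(0:(n_levels - 1L))
  octaves <- vector("list", p$n_octaves)
  base <- img
  for (o in seq_len(p$n_octaves)) {
    levels <- vector("list", n_levels)
    levels[[1]] <- gaussian_filter_image(base, p$sigma0)
    for (i in 2:n_levels) {
      sig_inc <- sqrt(sig_rel[i]^2 - sig_rel[i - 1L]^2)
      levels[[i]] <- gaussian_filter_image(levels[[i - 1L]], sig_inc)
    }
    octaves[[o]] <- list(levels = levels, sigmas = sig_rel,
                         sigmas_abs = sig_rel * 2^(o - 1L))
    # seed next octave from the level at 2 * sigma0 (index s + 1)
    seedlev <- levels[[p$s + 1L]]
    base <- seedlev[seq(1, nrow(seedlev), 2), seq(1, ncol(seedlev), 2),
                    drop = FALSE]
  }
  structure(octaves, class = "wbovw_gaussian_pyramid")
}

#' Build the difference-of-Gaussians stack
#'
#' Element-wise difference of adjacent Gaussian levels within each octave,
#' `D = L(k * sigma) - L(sigma)`; values may be negative.
#'
#' @param pyr A [build_scale_space()] pyramid.
#' @return A list of class `wbovw_dog_stack` mirroring the octave structure,
#'   each with `levels` (one fewer than the pyramid) and `sigmas`.
#' @export
build_dog <- function(pyr) {
  stopifnot(inherits(pyr, "wbovw_gaussian_pyramid"))
  out <- lapply(pyr, function(oct) {
    n <- length(oct$levels)
    if (n < 2L) stop("need at least 2 Gaussian levels per octave",
                     call. = FALSE)
    list(levels = lapply(seq_len(n - 1L),
                         function(i) oct$levels[[i + 1L]] - oct$levels[[i]]),
         sigmas = oct$sigmas[seq_len(n - 1L)],
         sigmas_abs = oct$sigmas_abs[seq_len(n - 1L)])
  })
  structure(out, class = "wbovw_dog_stack")
}

#' Detect 26-neighbor scale-space extrema
#'
#' A voxel at an interior position of the DoG stack is a keypoint iff its
#' value is strictly greater than all 26 neighbors (8 in its own level plus
#' 9 in each adjacent level) or strictly smaller than all 26, and its
#' absolute response is at least `contrast_threshold`. Ties are rejected,
#' so constant regions yield no keypoints. Coordinates are mapped back to
#' base-image resolution by the octave's decimation factor.
#'
#' @param dog A [build_dog()] stack.
#' @param contrast_threshold Minimum `|D|` at the extremum.
#' @return A data.frame with columns `x`, `y` (0-based base-image pixels),
#'   `octave`, `level`, `sigma` (absolute), `response`.
#' @export
detect_extrema <- function(dog, contrast_threshold = 0.01) {
  stopifnot(inherits(dog, "wbovw_dog_stack"))
  res <- list()
  for (o in seq_along(dog)) {
    lev <- dog[[o]]$levels
    L <- length(lev)
    if (L < 3L) stop("each octave needs at least 3 DoG levels", call. = FALSE)
    h <- nrow(lev[[1]]); w <- ncol(lev[[1]])
    if (h < 3L || w < 3L) next
    ri <- 2:(h - 1L); ci <- 2:(w - 1L)
    for (l in 2:(L - 1L)) {
      ctr <- lev[[l]][ri, ci, drop = FALSE]
      is_max <- abs(ctr) >= contrast_threshold
      is_min <- is_max
      for (dl in -1:1) {
        m <- lev[[l + dl]]
        for (dy in -1:1) for (dx in -1:1) {
          if (dl == 0L && dy == 0L && dx == 0L) next
          nb <- m[ri + dy, ci + dx, drop = FALSE]
          is_max <- is_max & (ctr > nb)
          is_min <- is_min & (ctr < nb)
          if (!any(is_max) && !any(is_min)) break
        }
        if (!any(is_max) && !any(is_min)) break
      }
      hits <- which(is_max | is_min, arr.ind = TRUE)
      if (nrow(hits) > 0L) {
        scale <- 2^(o - 1L)
        res[[length(res) + 1L]] <- data.frame(
          x = (hits[, 2L] + 1L - 1L) * scale,  # 0-based col in octave * 2^(o-1)
          y = (hits[, 1L] + 1L - 1L) * scale,
          octave = o, level = l,
          sigma = dog[[o]]$sigmas_abs[l],
          response = ctr[hits]
        )
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), octave = integer(0),
                      level = integer(0), sigma = numeric(0),
                      response = numeric(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$octave, out$level, out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect keypoints in an image
#'
#' Composition of [build_scale_space()], [build_dog()] and
#' [detect_extrema()]. Keypoints whose descriptor window (side determined by
#' the keypoint scale, see [hog_params()]) would cross the image border or
#' leave the ROI mask are dropped, so every surviving keypoint can be
#' described. An image with no extrema yields an empty data.frame; the
#' degenerate-encoding policy is handled downstream.
#'
#' @param img Preprocessed ROI image matrix.
#' @param p [scale_space_params()].
#' @param mask Optional logical ROI mask (same shape as `img`).
#' @param hog [hog_params()] used only to size the descriptor window.
#' @return Keypoint data.frame as in [detect_extrema()].
#' @export
detect_keypoints <- function(img, p = scale_space_params(), mask = NULL,
                             hog = hog_params()) {
  kp <- detect_extrema(build_dog(build_scale_space(img, p)),
                       p$contrast_threshold)
  if (nrow(kp) == 0L) return(kp)
  h <- nrow(img); w <- ncol(img)
  side <- vapply(kp$sigma, hog_window_side, numeric(1), p = hog)
  lo_x <- kp$x - side %/% 2L
  lo_y <- kp$y - side %/% 2L
  hi_x <- lo_x + side - 1L
  hi_y <- lo_y + side - 1L
  keep <- lo_x >= 0 & lo_y >= 0 & hi_x <= w - 1L & hi_y <= h - 1L
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(img)))
    # summed-area table of the mask: a window is valid iff fully inside
    sat <- rbind(0, cbind(0, apply(apply(mask, 2, cumsum), 1, cumsum) |> t()))
    idx <- which(keep)
    for (i in idx) {
      r0 <- lo_y[i] + 1L; r1 <- hi_y[i] + 1L
      c0 <- lo_x[i] + 1L; c1 <- hi_x[i] + 1L
      cnt <- sat[r1 + 1L, c1 + 1L] - sat[r0, c1 + 1L] -
        sat[r1 + 1L, c0] + sat[r0, c0]
      if (cnt < side[i]^2) keep[i] <- FALSE
    }
  }
  out <- kp[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
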