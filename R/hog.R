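# Histogram-of-oriented-gradients descriptors around detected keypoints:
# central-difference gradients, unsigned orientation in [0, 180), 4x4
# sub-regions x 9 bins = 144 dimensions per keypoint.

#' HOG descriptor parameters
#'
#' The descriptor window around a keypoint scales with the keypoint's
#' absolute sigma: `side = max(16, round(window_scale_multiplier * sigma))`,
#' rounded up to a multiple of `grid` so the sub-regions tile the window
#' exactly. Orientation bins are 20 degrees wide over \[0, 180), unsigned.
#'
#' @param window_scale_multiplier Window side per unit of keypoint scale.
#' @param grid Sub-region grid size per axis (default 4, hence 16 cells).
#' @param n_bins Orientation bins over \[0, 180) (default 9).
#' @param norm_epsilon Regularizer of the per-cell L2 normalization
#'   `v / sqrt(sum(v^2) + eps^2)`.
#' @param normalize `"subregion"` (default) normalizes each 9-bin cell;
#'   `"global"` normalizes the concatenated vector once.
#' @return A list of class `wbovw_hog_params`.
#' @export
hog_params <- function(window_scale_multiplier = 6, grid = 4L, n_bins = 9L,
                       norm_epsilon = 1e-6,
                       normalize = c("subregion", "global")) {
  normalize <- match.arg(normalize)
  stopifnot(window_scale_multiplier > 0, grid >= 1L, n_bins >= 1L,
            norm_epsilon > 0)
  structure(list(window_scale_multiplier = window_scale_multiplier,
                 grid = as.integer(grid), n_bins = as.integer(n_bins),
                 norm_epsilon = norm_epsilon, normalize = normalize),
            class = "wbovw_hog_params")
}

#' Descriptor window side for a keypoint scale
#'
#' @param sigma Keypoint absolute scale in pixels.
#' @param p [hog_params()].
#' @return Integer window side, a multiple of `p$grid`, at least 16.
#' @export
hog_window_side <- function(sigma, p = hog_params()) {
  side <- max(16, round(p$window_scale_multiplier * sigma))
  g <- p$grid
  as.integer(ceiling(side / g) * g)
}

#' Compute the gradient field of an image
#'
#' Central differences `I(x+1, y) - I(x-1, y)` (one-sided at the borders),
#' magnitude `sqrt(gx^2 + gy^2)`, and unsigned orientation in degrees folded
#' into \[0, 180): a pure vertical gradient (`gx = 0`) maps to 90 degrees,
#' and a zero gradient contributes nothing since its magnitude is 0.
#'
#' @param img Image matrix with both sides >= 3.
#' @return A list of class `wbovw_gradient_field` with matrices `gx`, `gy`,
#'   `magnitude`, `orientation` (degrees in \[0, 180)).
#' @export
compute_gradients <- function(img) {
  validate_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 3L || w < 3L) stop("image sides must be >= 3", call. = FALSE)
  gx <- matrix(0, h, w)
  gx[, 2:(w - 1L)] <- img[, 3:w] - img[, 1:(w - 2L)]
  gx[, 1L] <- img[, 2L] - img[, 1L]
  gx[, w] <- img[, w] - img[, w - 1L]
  gy <- matrix(0, h, w)
  gy[2:(h - 1L), ] <- img[3:h, ] - img[1:(h - 2L), ]
  gy[1L, ] <- img[2L, ] - img[1L, ]
  gy[h, ] <- img[h, ] - img[h - 1L, ]
  mag <- sqrt(gx^2 + gy^2)
  ori <- (atan2(gy, gx) * 180 / pi) %% 180
  ori[ori >= 180] <- 0  # guard the floating-point edge of the fold
  structure(list(gx = gx, gy = gy, magnitude = mag, orientation = ori),
            class = "wbovw_gradient_field")
}

# Orientation bin index (1-based) for angles in [0, 180).
orientation_bin <- function(ori, n_bins) {
  pmin(as.integer(floor(ori / (180 / n_bins))) + 1L, n_bins)
}

#' Orientation histogram of one sub-region
#'
#' Each pixel's gradient magnitude is accumulated wholly into the single bin
#' containing its orientation (hard assignment, no bilinear vote), then the
#' 9-vector is L2-normalized as `v / sqrt(sum(v^2) + eps^2)`, so a region of
#' zero gradients stays the zero vector.
#'
#' @param field A [compute_gradients()] field.
#' @param rows,cols 1-based index ranges of the sub-region.
#' @param p [hog_params()].
#' @param raw If `TRUE`, skip normalization (used by the global-normalization
#'   variant).
#' @return Numeric vector of length `p$n_bins`.
#' @export
subregion_histogram <- function(field, rows, cols, p = hog_params(),
                                raw = FALSE) {
  stopifnot(inherits(field, "wbovw_gradient_field"))
  mag <- field$magnitude[rows, cols]
  bin <- orientation_bin(field$orientation[rows, cols], p$n_bins)
  v <- vapply(seq_len(p$n_bins),
              function(b) sum(mag[bin == b]), numeric(1))
  if (raw) v else v / sqrt(sum(v^2) + p$norm_epsilon^2)
}

#' HOG descriptor of one keypoint
#'
#' The window centered on the keypoint is split into a `grid x grid` tiling
#' of equal square sub-regions; their orientation histograms are concatenated
#' in row-major sub-region order (left-to-right within a row of cells, top
#' row first), giving `grid^2 * n_bins` = 144 dimensions at the defaults.
#'
#' @param field A [compute_gradients()] field of the full image.
#' @param x,y Keypoint position, 0-based pixels.
#' @param sigma Keypoint absolute scale.
#' @param p [hog_params()].
#' @param mask Optional logical ROI mask; the window must lie fully inside.
#' @return Numeric descriptor vector, or an error of class
#'   `wbovw_window_oob` if the window crosses the border or the mask.
#' @export
keypoint_descriptor <- function(field, x, y, sigma, p = hog_params(),
                                mask = NULL) {
  stopifnot(inherits(field, "wbovw_gradient_field"))
  h <- nrow(field$magnitude); w <- ncol(field$magnitude)
  side <- hog_window_side(sigma, p)
  lo_x <- x - side %/% 2L; lo_y <- y - side %/% 2L
  hi_x <- lo_x + side - 1L; hi_y <- lo_y + side - 1L
  oob <- function() {
    stop(structure(class = c("wbovw_window_oob", "error", "condition"),
                   list(message = "descriptor window out of bounds",
                        call = sys.call(-1))))
  }
  if (lo_x < 0 || lo_y < 0 || hi_x > w - 1L || hi_y > h - 1L) oob()
  rows <- (lo_y + 1L):(hi_y + 1L)
  cols <- (lo_x + 1L):(hi_x + 1L)
  if (!is.null(mask) && !all(mask[rows, cols])) oob()
  cell <- side %/% p$grid
  desc <- numeric(0)
  for (gy in seq_len(p$grid)) {
    r <- rows[((gy - 1L) * cell + 1L):(gy * cell)]
    for (gx in seq_len(p$grid)) {
      c <- cols[((gx - 1L) * cell + 1L):(gx * cell)]
      desc <- c(desc, subregion_histogram(field, r, c, p,
                                          raw = (p$normalize == "global")))
    }
  }
  if (p$normalize == "global") {
    desc <- desc / sqrt(sum(desc^2) + p$norm_epsilon^2)
  }
  desc
}

#' Describe all keypoints of an image
#'
#' One descriptor row per keypoint, in keypoint order. Keypoints whose
#' window leaves the image or mask are dropped (they should already have
#' been filtered by [detect_keypoints()]); the returned matrix may have zero
#' rows.
#'
#' @param img Image matrix.
#' @param kps Keypoint data.frame from [detect_keypoints()].
#' @param p [hog_params()].
#' @param mask Optional logical ROI mask.
#' @return Numeric matrix, one row per surviving keypoint,
#'   `p$grid^2 * p$n_bins` columns.
#' @export
describe_image <- function(img, kps, p = hog_params(), mask = NULL) {
  d <- p$grid^2 * p$n_bins
  if (nrow(kps) == 0L) return(matrix(0, 0L, d))
  field <- compute_gradients(img)
  rows <- vector("list", nrow(kps))
  keep <- logical(nrow(kps))
  for (j in seq_len(nrow(kps))) {
    v <- tryCatch(
      keypoint_descriptor(field, kps$x[j], kps$y[j], kps$sigma[j], p, mask),
      wbovw_window_oob = function(e) NULL
    )
    if (!is.null(v)) {
      rows[[j]] <- v
      keep[j] <- TRUE
    }
  }
  if (!any(keep)) return(matrix(0, 0L, d))
  do.call(rbind, rows[keep])
}
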