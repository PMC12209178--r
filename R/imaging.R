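# Image and manifest I/O, circular ROI extraction, preprocessing
# (wavelet denoising, masked histogram equalization) and texture-preserving
# augmentation. All images are numeric matrices in [0,1]; see
# validate_gray_image() for the coordinate convention.

#' Read a grayscale image from PNG or TIFF
#'
#' 8- or 16-bit files are rescaled to \[0, 1\]. Multi-channel images are
#' converted to grayscale by averaging the color channels.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A grayscale image matrix.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (expected png/tif/tiff)",
         call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    arr <- apply(arr[, , seq_len(min(nch, 3L)), drop = FALSE], c(1, 2), mean)
  }
  img <- clamp01(as.matrix(arr))
  validate_gray_image(img)
  img
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img Image matrix in \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  validate_gray_image(img)
  png::writePNG(img, path)
  invisible(path)
}

#' Load an ROI annotation manifest
#'
#' The manifest lists one circular region of interest per image together with
#' its binary label. Accepted formats: CSV with header
#' `image_id,center_x,center_y,radius,label` or a JSON array of objects with
#' the same fields. Labels may be the strings `"normal"` / `"fgr"` or the
#' integers 0 / 1; they are returned as integers with FGR = 1 (the positive
#' class). Center coordinates are 0-based pixels, `radius` is in pixels.
#' An optional `path` column gives the image file relative to the manifest;
#' otherwise `<image_id>.png` next to the manifest is assumed.
#'
#' @param path Manifest file path.
#' @return A data.frame with columns `image_id`, `center_x`, `center_y`,
#'   `radius`, `label` (integer 0/1) and `path` (absolute image path), with
#'   attribute `"dir"` set to the manifest directory.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("image_id", "center_x", "center_y", "radius", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) > 0L) {
    lab <- df$label
    if (is.character(lab) || is.factor(lab)) {
      lab <- tolower(trimws(as.character(lab)))
      known <- c(normal = 0L, fgr = 1L, "0" = 0L, "1" = 1L)
      bad <- setdiff(unique(lab), names(known))
      if (length(bad) > 0L) {
        stop("unknown label value(s): ", paste(bad, collapse = ", "),
             " (expected 'normal' or 'fgr')", call. = FALSE)
      }
      df$label <- unname(known[lab])
    } else {
      if (!all(df$label %in% c(0, 1))) {
        stop("numeric labels must be 0 (normal) or 1 (fgr)", call. = FALSE)
      }
      df$label <- as.integer(df$label)
    }
    if (any(!is.finite(df$radius)) || any(df$radius <= 0)) {
      stop("all ROI radii must be positive", call. = FALSE)
    }
  } else {
    df$label <- integer(0)
  }
  dir <- dirname(normalizePath(path))
  if (nrow(df) == 0L) {
    df$path <- character(0)
  } else if (is.null(df$path)) {
    df$path <- file.path(dir, paste0(df$image_id, ".png"))
  } else {
    rel <- !grepl("^(/|[A-Za-z]:)", df$path)
    df$path[rel] <- file.path(dir, df$path[rel])
  }
  attr(df, "dir") <- dir
  df
}

#' Extract a circular region of interest
#'
#' Crops the `(2 * radius + 1)`-pixel square centered on the annotation and
#' masks out everything outside the inscribed circle. Portions of the square
#' falling outside the image are zero-padded and marked outside the mask, so
#' downstream stages (keypoint windows, histogram equalization) ignore them.
#'
#' @param img Image matrix.
#' @param center_x,center_y Circle center in 0-based pixel coordinates
#'   (x = column, y = row).
#' @param radius Circle radius in pixels.
#' @return A list with `pixels` (square crop, outside-circle pixels set to 0)
#'   and `mask` (logical matrix, `TRUE` inside the circle and inside the
#'   original image).
#' @export
extract_roi <- function(img, center_x, center_y, radius) {
  validate_gray_image(img)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  w <- ncol(img); h <- nrow(img)
  if (center_x + radius < 0 || center_x - radius > w - 1 ||
      center_y + radius < 0 || center_y - radius > h - 1) {
    stop("ROI circle lies fully outside the image", call. = FALSE)
  }
  ri <- as.integer(round(radius))
  side <- 2L * ri + 1L
  xs <- seq.int(center_x - ri, center_x + ri)  # 0-based columns
  ys <- seq.int(center_y - ri, center_y + ri)  # 0-based rows
  inside_x <- xs >= 0L & xs <= w - 1L
  inside_y <- ys >= 0L & ys <= h - 1L
  pixels <- matrix(0, side, side)
  pixels[which(inside_y), which(inside_x)] <-
    img[ys[inside_y] + 1L, xs[inside_x] + 1L, drop = FALSE]
  dx <- matrix(xs - center_x, side, side, byrow = TRUE)
  dy <- matrix(ys - center_y, side, side)
  in_circle <- (dx^2 + dy^2) <= radius^2
  in_image <- outer(inside_y, inside_x, "&")
  mask <- in_circle & in_image
  pixels[!mask] <- 0
  list(pixels = pixels, mask = mask)
}

# --- Haar wavelet shrinkage -------------------------------------------------

# One analysis level of the separable orthonormal Haar transform. Odd
# dimensions are handled by replicating the last row/column; the caller crops
# after synthesis.
haar_analysis <- function(m) {
  if (nrow(m) %% 2L == 1L) m <- rbind(m, m[nrow(m), , drop = FALSE])
  if (ncol(m) %% 2L == 1L) m <- cbind(m, m[, ncol(m), drop = FALSE])
  s2 <- sqrt(2)
  ro <- m[seq(1, nrow(m), 2), , drop = FALSE]
  re <- m[seq(2, nrow(m), 2), , drop = FALSE]
  lo <- (ro + re) / s2; hi <- (ro - re) / s2
  split2 <- function(a) {
    co <- a[, seq(1, ncol(a), 2), drop = FALSE]
    ce <- a[, seq(2, ncol(a), 2), drop = FALSE]
    list(l = (co + ce) / s2, h = (co - ce) / s2)
  }
  L <- split2(lo); H <- split2(hi)
  list(ll = L$l, lh = L$h, hl = H$l, hh = H$h)
}

haar_synthesis <- function(bands) {
  s2 <- sqrt(2)
  merge2 <- function(l, h) {
    a <- matrix(0, nrow(l), 2L * ncol(l))
    a[, seq(1, ncol(a), 2)] <- (l + h) / s2
    a[, seq(2, ncol(a), 2)] <- (l - h) / s2
    a
  }
  lo <- merge2(bands$ll, bands$lh)
  hi <- merge2(bands$hl, bands$hh)
  m <- matrix(0, 2L * nrow(lo), ncol(lo))
  m[seq(1, nrow(m), 2), ] <- (lo + hi) / s2
  m[seq(2, nrow(m), 2), ] <- (lo - hi) / s2
  m
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Wavelet denoising by soft-threshold shrinkage
#'
#' Two-level separable Haar decomposition with the universal threshold
#' `sigma * sqrt(2 * log(n))`, where `sigma` is estimated from the median
#' absolute deviation of the finest-level diagonal detail coefficients.
#' Detail bands at both levels are soft-thresholded; the output is clipped
#' back to \[0, 1\]. Deterministic for a fixed input.
#'
#' @param img Image matrix.
#' @param n_levels Number of decomposition levels (default 2).
#' @return Denoised image matrix.
#' @export
denoise_wavelet <- function(img, n_levels = 2L) {
  validate_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  if (min(h, w) < 2L^n_levels) return(img)
  b1 <- haar_analysis(img)
  sigma <- stats::median(abs(b1$hh)) / 0.6745
  thr <- sigma * sqrt(2 * log(h * w))
  if (thr == 0) return(img)
  b2 <- if (n_levels >= 2L) haar_analysis(b1$ll) else NULL
  b1$lh <- soft_threshold(b1$lh, thr)
  b1$hl <- soft_threshold(b1$hl, thr)
  b1$hh <- soft_threshold(b1$hh, thr)
  if (!is.null(b2)) {
    b2$lh <- soft_threshold(b2$lh, thr)
    b2$hl <- soft_threshold(b2$hl, thr)
    b2$hh <- soft_threshold(b2$hh, thr)
    b1$ll <- haar_synthesis(b2)[seq_len(nrow(b1$ll)), seq_len(ncol(b1$ll)),
                                drop = FALSE]
  }
  out <- haar_synthesis(b1)[seq_len(h), seq_len(w), drop = FALSE]
  clamp01(out)
}

#' Histogram equalization over a pixel mask
#'
#' Standard 256-bin cumulative-histogram equalization where the histogram is
#' accumulated over masked-in pixels only, so the zero-padded exterior of a
#' circular ROI cannot distort the mapping. The mapping is the empirical CDF,
#' hence monotone: pixel rank order is preserved. Pixels outside the mask are
#' returned unchanged.
#'
#' @param img Image matrix.
#' @param mask Logical matrix of the same shape; at least one `TRUE` entry.
#' @return Equalized image matrix.
#' @export
equalize_hist <- function(img, mask = NULL) {
  validate_gray_image(img)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  if (!identical(dim(mask), dim(img))) {
    stop("mask must have the same shape as the image", call. = FALSE)
  }
  if (!any(mask)) stop("mask excludes every pixel", call. = FALSE)
  nbins <- 256L
  bins <- pmin(as.integer(floor(img * nbins)), nbins - 1L)  # 0..255
  counts <- tabulate(bins[mask] + 1L, nbins = nbins)
  cdf <- cumsum(counts) / sum(counts)
  out <- img
  out[mask] <- cdf[bins[mask] + 1L]
  out
}

# --- Geometric resampling ---------------------------------------------------

# Bilinear sample at continuous 0-based (x, y); coordinates are clamped to
# the image border (edge replication).
sample_bilinear <- function(img, xs, ys) {
  w <- ncol(img); h <- nrow(img)
  xs <- pmin(pmax(xs, 0), w - 1)
  ys <- pmin(pmax(ys, 0), h - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- xs - x0; fy <- ys - y0
  idx <- function(r, c) img[cbind(r + 1, c + 1)]
  (1 - fy) * ((1 - fx) * idx(y0, x0) + fx * idx(y0, x1)) +
    fy * ((1 - fx) * idx(y1, x0) + fx * idx(y1, x1))
}

#' Rotate an image about its center
#'
#' Bilinear resampling; output has the same size as the input, with border
#' samples clamped by edge replication. Exact identity at `angle_deg = 0`.
#'
#' @param img Image matrix.
#' @param angle_deg Counter-clockwise rotation in degrees.
#' @return Rotated image matrix.
#' @export
rotate_image <- function(img, angle_deg) {
  validate_gray_image(img)
  if (angle_deg == 0) return(img)
  w <- ncol(img); h <- nrow(img)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  th <- angle_deg * pi / 180
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE) - cx
  ys <- matrix(0:(h - 1), h, w) - cy
  # inverse map: rotate output coords by -theta to find source coords
  sx <- cos(th) * xs + sin(th) * ys + cx
  sy <- -sin(th) * xs + cos(th) * ys + cy
  out <- matrix(sample_bilinear(img, as.vector(sx), as.vector(sy)), h, w)
  clamp01(out)
}

# Crop a sub-window retaining `crop_fraction` of the area (offset in 0-based
# pixels from the top-left), then resize back to the original size.
crop_resize <- function(img, crop_fraction, off_x = 0, off_y = 0) {
  if (crop_fraction == 1 && off_x == 0 && off_y == 0) return(img)
  w <- ncol(img); h <- nrow(img)
  lin <- sqrt(crop_fraction)
  cw <- max(2L, round(w * lin)); ch <- max(2L, round(h * lin))
  off_x <- min(max(off_x, 0), w - cw)
  off_y <- min(max(off_y, 0), h - ch)
  xs <- off_x + (0:(w - 1)) * (cw - 1) / (w - 1)
  ys <- off_y + (0:(h - 1)) * (ch - 1) / (h - 1)
  gx <- matrix(xs, h, w, byrow = TRUE)
  gy <- matrix(ys, h, w)
  matrix(sample_bilinear(img, as.vector(gx), as.vector(gy)), h, w)
}

#' Augmentation configuration
#'
#' Parameters for the texture-preserving augmentation policy: brightness
#' shift, contrast scaling about mid-gray, rotation about the image center,
#' and random crop-then-resize. Scaling, affine and shear transforms are
#' deliberately excluded because they distort the fine texture that carries
#' the class signal.
#'
#' @param brightness_delta_range Additive intensity shift interval.
#' @param contrast_factor_range Multiplicative contrast interval (pivot 0.5).
#' @param rotation_range_deg Rotation interval in degrees.
#' @param crop_fraction Fraction of image area retained by the random crop.
#' @param n_augments_per_image Number of variants generated per image.
#' @param seed Integer seed making the draws reproducible.
#' @return A list of class `wbovw_augment_config`.
#' @export
augment_config <- function(brightness_delta_range = c(-0.1, 0.1),
                           contrast_factor_range = c(0.9, 1.1),
                           rotation_range_deg = c(-15, 15),
                           crop_fraction = 0.9,
                           n_augments_per_image = 2L,
                           seed = 1L) {
  stopifnot(length(brightness_delta_range) == 2L,
            diff(brightness_delta_range) >= 0,
            length(contrast_factor_range) == 2L,
            diff(contrast_factor_range) >= 0,
            length(rotation_range_deg) == 2L,
            diff(rotation_range_deg) >= 0,
            crop_fraction > 0, crop_fraction <= 1,
            n_augments_per_image >= 0)
  structure(list(brightness_delta_range = brightness_delta_range,
                 contrast_factor_range = contrast_factor_range,
                 rotation_range_deg = rotation_range_deg,
                 crop_fraction = crop_fraction,
                 n_augments_per_image = as.integer(n_augments_per_image),
                 seed = as.integer(seed)),
            class = "wbovw_augment_config")
}

#' Generate augmented variants of an image
#'
#' Each variant applies, in order: brightness shift, contrast scale about
#' mid-gray, rotation about the center, and a random crop resized back to the
#' original size, with parameters drawn uniformly from the configured ranges.
#' Draws are reproducible given the seed, and a configuration whose ranges
#' are all degenerate at the identity returns exact copies of the input.
#'
#' @param img Image matrix.
#' @param cfg An [augment_config()].
#' @param seed Seed for this call; defaults to `cfg$seed`.
#' @param mask Optional logical ROI mask. When supplied, the same geometric
#'   transforms are applied to the mask (conservatively: a transformed mask
#'   pixel stays in only if fully interior), and each variant is returned as
#'   a list with `pixels` and `mask`.
#' @return A list of `cfg$n_augments_per_image` image matrices, or of
#'   `pixels`/`mask` pairs when `mask` is given.
#' @export
augment <- function(img, cfg, seed = cfg$seed, mask = NULL) {
  validate_gray_image(img)
  stopifnot(inherits(cfg, "wbovw_augment_config"))
  if (!is.null(mask)) stopifnot(identical(dim(mask), dim(img)))
  n <- cfg$n_augments_per_image
  if (n == 0L) return(list())
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      delta <- stats::runif(1, cfg$brightness_delta_range[1],
                            cfg$brightness_delta_range[2])
      factor <- stats::runif(1, cfg$contrast_factor_range[1],
                             cfg$contrast_factor_range[2])
      angle <- stats::runif(1, cfg$rotation_range_deg[1],
                            cfg$rotation_range_deg[2])
      u_off <- stats::runif(2)
      geom <- function(m) {
        out <- rotate_image(m, angle)
        if (cfg$crop_fraction < 1) {
          lin <- sqrt(cfg$crop_fraction)
          max_x <- ncol(img) - max(2L, round(ncol(img) * lin))
          max_y <- nrow(img) - max(2L, round(nrow(img) * lin))
          out <- crop_resize(out, cfg$crop_fraction,
                             off_x = u_off[1] * max_x,
                             off_y = u_off[2] * max_y)
        }
        out
      }
      out <- img
      if (delta != 0 || factor != 1) {
        out <- clamp01((out - 0.5) * factor + 0.5 + delta)
      }
      out <- clamp01(geom(out))
      if (is.null(mask)) return(out)
      m <- geom(matrix(as.numeric(mask), nrow(mask), ncol(mask))) >= 0.999
      list(pixels = out, mask = m)
    })
  })
}
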