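# Synthetic ultrasound-like texture generator. The two classes differ only
# in their local texture primitive -- isotropic Gaussian dots (normal) versus
# short anisotropic Gaussian rods at random orientations (FGR) -- embedded in
# multiplicative speckle inside a circular ROI, the structure the encoder is
# meant to discriminate. Everything is deterministic from seeds, so the full
# pipeline is testable without any clinical image.

#' Specification of one synthetic texture image
#'
#' @param label `"normal"` (dot primitives) or `"fgr"` (rod primitives).
#' @param image_size Square image side in pixels.
#' @param roi_radius ROI circle radius in pixels, centered in the image.
#' @param n_primitives Number of texture primitives placed in the ROI.
#' @param dot_radius Gaussian sd of a dot primitive (normal class), px.
#' @param rod_length,rod_width Rod primitive extents (FGR class), px; the
#'   Gaussian sds along/across the rod axis are half these values.
#' @param rod_angle_jitter Unused orientation constraint placeholder; rods
#'   are drawn at uniformly random orientations plus this jitter range.
#' @param primitive_contrast Peak intensity delta a primitive adds.
#' @param speckle_sigma Multiplicative speckle scale applied afterwards.
#' @param background_level Base intensity of the canvas.
#' @param seed Integer seed.
#' @return A list of class `wbovw_synthetic_spec`.
#' @export
synthetic_spec <- function(label = c("normal", "fgr"), image_size = 256L,
                           roi_radius = 100, n_primitives = 150L,
                           dot_radius = 2, rod_length = 8, rod_width = 2,
                           rod_angle_jitter = 180, primitive_contrast = 0.4,
                           speckle_sigma = 0.15, background_level = 0.35,
                           seed = 1L) {
  label <- match.arg(label)
  stopifnot(image_size >= 16L, roi_radius > 0,
            roi_radius <= image_size / 2, n_primitives >= 0L,
            dot_radius > 0, rod_length > 0, rod_width > 0,
            speckle_sigma >= 0, primitive_contrast >= 0,
            background_level >= 0, background_level <= 1)
  margin <- if (label == "normal") 3 * dot_radius else rod_length
  if (n_primitives > 0L && roi_radius <= margin) {
    stop("primitives do not fit inside the ROI", call. = FALSE)
  }
  structure(list(label = label, image_size = as.integer(image_size),
                 roi_radius = roi_radius,
                 n_primitives = as.integer(n_primitives),
                 dot_radius = dot_radius, rod_length = rod_length,
                 rod_width = rod_width, rod_angle_jitter = rod_angle_jitter,
                 primitive_contrast = primitive_contrast,
                 speckle_sigma = speckle_sigma,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "wbovw_synthetic_spec")
}

#' Render a noise-free synthetic texture
#'
#' Places `n_primitives` Gaussian-profiled primitives at uniformly random
#' positions inside the ROI circle on a constant background: isotropic dots
#' for the normal class, anisotropic rods at uniformly random orientations
#' for FGR. Speckle is added separately by [apply_speckle()]. Deterministic
#' per `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return Image matrix in \[0, 1\].
#' @export
render_texture <- function(spec) {
  stopifnot(inherits(spec, "wbovw_synthetic_spec"))
  n <- spec$image_size
  img <- matrix(spec$background_level, n, n)
  if (spec$n_primitives == 0L) return(img)
  c0 <- (n - 1) / 2
  margin <- if (spec$label == "normal") 3 * spec$dot_radius else
    spec$rod_length
  r_max <- spec$roi_radius - margin
  with_seed(spec$seed, {
    # uniform positions in the disc via rejection-free polar sampling
    rr <- r_max * sqrt(stats::runif(spec$n_primitives))
    th <- stats::runif(spec$n_primitives, 0, 2 * pi)
    px <- c0 + rr * cos(th)
    py <- c0 + rr * sin(th)
    angles <- stats::runif(spec$n_primitives, 0, pi)
    half <- ceiling(if (spec$label == "normal") 3 * spec$dot_radius else
      spec$rod_length)
    for (i in seq_len(spec$n_primitives)) {
      cx <- px[i]; cy <- py[i]
      xs <- max(0, floor(cx) - half):min(n - 1, floor(cx) + half + 1)
      ys <- max(0, floor(cy) - half):min(n - 1, floor(cy) + half + 1)
      dx <- outer(rep(1, length(ys)), xs - cx)
      dy <- outer(ys - cy, rep(1, length(xs)))
      if (spec$label == "normal") {
        prof <- exp(-(dx^2 + dy^2) / (2 * spec$dot_radius^2))
      } else {
        a <- angles[i]
        u <- dx * cos(a) + dy * sin(a)    # along the rod axis
        v <- -dx * sin(a) + dy * cos(a)   # across
        s_u <- spec$rod_length / 2
        s_v <- spec$rod_width / 2
        prof <- exp(-(u^2 / (2 * s_u^2) + v^2 / (2 * s_v^2)))
      }
      img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] +
        spec$primitive_contrast * prof
    }
  })
  clamp01(img)
}

#' Apply multiplicative speckle noise
#'
#' `out = img * (1 + sigma * eta)` with `eta` i.i.d. standard normal per
#' pixel, clipped to \[0, 1\]. Deterministic per seed; `sigma = 0` is the
#' identity.
#'
#' @param img Image matrix.
#' @param sigma Speckle scale, >= 0.
#' @param seed Integer seed.
#' @return Noisy image matrix.
#' @export
apply_speckle <- function(img, sigma, seed = 1L) {
  validate_gray_image(img)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(img)
  with_seed(seed, {
    eta <- matrix(stats::rnorm(length(img)), nrow(img), ncol(img))
    clamp01(img * (1 + sigma * eta))
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `2 * n_per_class` PNG images (speckled textures, dot class and rod
#' class) plus a manifest CSV in the [load_manifest()] dialect, with the ROI
#' circle centered in each image. Per-image seeds derive from the master
#' seed, so regeneration is byte-identical. The default `n_per_class = 40`
#' mirrors a balanced 40 + 40 cohort.
#'
#' @param n_per_class Images per class.
#' @param out_dir Output directory (created if needed).
#' @param master_seed Integer master seed.
#' @param spec_normal,spec_fgr Template [synthetic_spec()]s for each class;
#'   their seeds are overridden per image.
#' @return Path to the written manifest CSV, invisibly.
#' @export
generate_dataset <- function(n_per_class = 40L, out_dir,
                             master_seed = 1L,
                             spec_normal = synthetic_spec("normal"),
                             spec_fgr = synthetic_spec("fgr")) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir,
                  call. = FALSE)
  }
  n_total <- 2L * n_per_class
  seeds <- derive_seeds(master_seed, 2L * n_total)
  rows <- vector("list", n_total)
  i <- 0L
  for (cl in c("normal", "fgr")) {
    spec <- if (cl == "normal") spec_normal else spec_fgr
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      spec$seed <- seeds[2L * i - 1L]
      img <- render_texture(spec)
      img <- apply_speckle(img, spec$speckle_sigma, seed = seeds[2L * i])
      id <- sprintf("%s_%03d", cl, j)
      write_gray_image(img, file.path(out_dir, paste0(id, ".png")))
      rows[[i]] <- data.frame(
        image_id = id,
        center_x = (spec$image_size - 1) / 2,
        center_y = (spec$image_size - 1) / 2,
        radius = spec$roi_radius, label = cl
      )
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
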