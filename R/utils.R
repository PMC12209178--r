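#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` after seeding the default RNG, restoring the caller's RNG
#' state afterwards so seeded helpers never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a master seed, kept within 32-bit range.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Validate a grayscale image matrix
#'
#' Images throughout the package are plain numeric matrices with values in
#' \[0, 1\], indexed `img[row, col]`. Pixel coordinates in the API follow the
#' convention `(x, y)` = (column, row), 0-based, so `I(x, y) = img[y + 1, x + 1]`.
#'
#' @param img Numeric matrix.
#' @return `img`, invisibly, after validation.
#' @export
validate_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (any(!is.finite(img))) {
    stop("image contains non-finite values", call. = FALSE)
  }
  if (min(img) < 0 || max(img) > 1) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  invisible(img)
}
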