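# Enhancement pipeline: grayscale -> (closing -> Black-Hat | blur -> adaptive
# threshold). All neighbourhood operations use reflect-101 borders (reflection
# about the edge pixel, the edge itself not duplicated) so that results are
# defined bit-exactly everywhere, including corners.

# Index vector implementing reflect-101 for an offset d over n positions.
reflect_idx <- function(n, d) {
  i <- seq_len(n) + d
  i <- ifelse(i < 1L, 2L - i, i)
  i <- ifelse(i > n, 2L * n - i, i)
  i
}

# Shift a matrix by (dy, dx) with reflect-101 borders.
shift_reflect <- function(m, dy, dx) {
  m[reflect_idx(nrow(m), dy), reflect_idx(ncol(m), dx), drop = FALSE]
}

#' Convert a colour image to grayscale
#'
#' Uses the ITU-R BT.601 luma weights (0.299, 0.587, 0.114) and rounds
#' half-up to the nearest integer intensity, matching common imaging practice
#' for 8-bit rasters.
#'
#' @param img A 3-channel [lesion_image()].
#' @return Matrix image on 0..255.
#' @examples
#' img <- lesion_image(array(100, dim = c(4, 4, 3)))
#' all(to_grayscale(img) == 100)
#' @export
to_grayscale <- function(img) {
  if (!is_lesion_image(img)) stop("to_grayscale() expects a 3-channel image")
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  floor(g + 0.5)
}

morph_extreme <- function(img, k, which = c("max", "min")) {
  which <- match.arg(which)
  img <- as_gray_matrix(img)
  if (nrow(k) > nrow(img) || ncol(k) > ncol(img)) {
    stop("structuring element larger than the image")
  }
  ry <- (nrow(k) - 1L) / 2L
  rx <- (ncol(k) - 1L) / 2L
  acc <- NULL
  pick <- if (which == "max") pmax else pmin
  for (dy in -ry:ry) {
    for (dx in -rx:rx) {
      if (!k[dy + ry + 1L, dx + rx + 1L]) next
      s <- shift_reflect(img, dy, dx)
      acc <- if (is.null(acc)) s else pick(acc, s)
    }
  }
  acc
}

#' Morphological dilation and erosion
#'
#' Flat grayscale dilation (windowed maximum) and erosion (windowed minimum)
#' over the support of a [structuring_element()], with reflect-101 borders.
#'
#' @param img Matrix image.
#' @param k A [structuring_element()].
#' @return Matrix image of the same size.
#' @export
morph_dilate <- function(img, k) morph_extreme(img, k, "max")

#' @rdname morph_dilate
#' @export
morph_erode <- function(img, k) morph_extreme(img, k, "min")

#' Morphological closing
#'
#' Dilation followed by erosion. Closing fills dark gaps smaller than the
#' structuring element; it is extensive (output >= input) and idempotent.
#'
#' @inheritParams morph_dilate
#' @return Matrix image of the same size.
#' @export
morph_close <- function(img, k) morph_erode(morph_dilate(img, k), k)

#' Black-Hat transform
#'
#' Morphological closing minus the original image: highlights dark structures
#' (hairs, pigmented spots, lesion borders) that are smaller than the
#' structuring element and surrounded by lighter skin. Always non-negative.
#'
#' @inheritParams morph_dilate
#' @return Matrix image of the same size, values >= 0.
#' @examples
#' k <- structuring_element("rectangle", 3)
#' im <- matrix(255, 8, 8); im[4, 4] <- 0
#' bh <- black_hat(im, k)   # 255 at the dark pixel, 0 elsewhere
#' @export
black_hat <- function(img, k) {
  morph_close(img, k) - as_gray_matrix(img)
}

# Sampled, normalised 1-D Gaussian kernel.
gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- -radius:radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with reflect-101 borders.
convolve_separable <- function(img, kr, kc = kr) {
  img <- as_gray_matrix(img)
  rr <- (length(kr) - 1L) / 2L
  out <- 0
  for (d in -rr:rr) out <- out + kr[d + rr + 1L] * shift_reflect(img, d, 0L)
  rc <- (length(kc) - 1L) / 2L
  out2 <- 0
  for (d in -rc:rc) out2 <- out2 + kc[d + rc + 1L] * shift_reflect(out, 0L, d)
  out2
}

#' Gaussian blur
#'
#' Separable Gaussian smoothing with kernel truncated at `ceiling(3 * sigma)`
#' samples per side, normalised to unit sum, reflect-101 borders.
#'
#' @param img Matrix image.
#' @param sigma Positive standard deviation in pixels.
#' @return Matrix image of the same size (fractional intensities).
#' @export
gaussian_blur <- function(img, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  convolve_separable(img, gaussian_kernel_1d(sigma))
}

#' Adaptive-threshold configuration
#'
#' @param window Odd window side >= 3 of the local neighbourhood. The default
#'   (61 on a 224-pixel image) spans roughly a quarter of the frame so the
#'   local mean estimates the surrounding skin rather than the lesion
#'   interior; windows much smaller than the lesion turn its interior white.
#' @param C Constant subtracted from the local Gaussian-weighted mean; larger
#'   `C` makes the output whiter (less sensitive).
#' @param sigma Standard deviation of the pre-threshold noise-reduction blur.
#' @param weight_sigma Standard deviation of the Gaussian window weights;
#'   default `(window - 1) / 2`, i.e. the window spans one standard deviation
#'   each side, giving a broad, gently centre-weighted local mean suited to
#'   lesion-scale structure.
#' @return List of class `threshold_config`.
#' @export
threshold_config <- function(window = 61, C = 5, sigma = 1.0,
                             weight_sigma = (window - 1) / 2) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be an odd integer >= 3")
  if (!is.finite(C)) stop("C must be finite")
  if (sigma <= 0 || weight_sigma <= 0) stop("sigma values must be positive")
  structure(list(window = window, C = C, sigma = sigma,
                 weight_sigma = weight_sigma), class = "threshold_config")
}

# Gaussian window weights over the n-wide window, normalised to unit sum.
adaptive_weights_1d <- function(window, weight_sigma = (window - 1) / 2) {
  x <- -((window - 1) / 2):((window - 1) / 2)
  k <- exp(-x^2 / (2 * weight_sigma^2))
  k / sum(k)
}

#' Adaptive Gaussian thresholding
#'
#' Binarises an image against a per-pixel threshold: the Gaussian-weighted
#' mean of the `window x window` neighbourhood minus the constant `C`. A pixel
#' becomes white (255) iff its intensity strictly exceeds its local threshold;
#' ties go to black. The Gaussian window weights use `cfg$weight_sigma` and
#' reflect-101 borders. Pre-blurring (see [gaussian_blur()]) is the caller's
#' responsibility.
#'
#' @param img Matrix image.
#' @param cfg A [threshold_config()].
#' @return Matrix image containing only 0 and 255.
#' @export
adaptive_threshold <- function(img, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "threshold_config"))
  img <- as_gray_matrix(img)
  w <- adaptive_weights_1d(cfg$window, cfg$weight_sigma)
  thr <- convolve_separable(img, w) - cfg$C
  ifelse(img > thr, 255, 0)
}

# Row-interpolation matrix (n_out x n_in): "area" averages the overlapped
# source interval, "bilinear" samples at half-pixel-aligned centres.
resample_matrix <- function(n_in, n_out, method = c("area", "bilinear")) {
  method <- match.arg(method)
  A <- matrix(0, n_out, n_in)
  if (method == "area") {
    s <- n_in / n_out
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * s; hi <- i * s
      j0 <- floor(lo) + 1L; j1 <- ceiling(hi)
      for (j in j0:min(j1, n_in)) {
        ov <- min(hi, j) - max(lo, j - 1)
        if (ov > 0) A[i, j] <- ov / s
      }
    }
  } else {
    s <- n_in / n_out
    for (i in seq_len(n_out)) {
      src <- (i - 0.5) * s + 0.5            # 1-based half-pixel convention
      j0 <- floor(src); f <- src - j0
      j0c <- min(max(j0, 1L), n_in); j1c <- min(max(j0 + 1L, 1L), n_in)
      A[i, j0c] <- A[i, j0c] + (1 - f)
      A[i, j1c] <- A[i, j1c] + f
    }
  }
  A
}

#' Resize a colour image
#'
#' Resamples to `target` (height, width): area averaging when an axis shrinks
#' (each output pixel is the exact mean of the source interval it covers),
#' bilinear interpolation when it grows. A same-size input is returned
#' unchanged, so resizing is idempotent.
#'
#' @param img A [lesion_image()].
#' @param target Integer vector (height, width); default `c(224, 224)`.
#' @return A [lesion_image()] of the target geometry.
#' @export
resize_image <- function(img, target = c(224, 224)) {
  if (!is_lesion_image(img)) stop("resize_image() expects a 3-channel image")
  d <- dim(img)
  if (any(d[1:2] < 1L)) stop("empty raster")
  if (d[1] == target[1] && d[2] == target[2]) return(img)
  mr <- resample_matrix(d[1], target[1], if (target[1] < d[1]) "area" else "bilinear")
  mc <- resample_matrix(d[2], target[2], if (target[2] < d[2]) "area" else "bilinear")
  out <- array(0, dim = c(target[1], target[2], 3L))
  for (ch in 1:3) out[, , ch] <- mr %*% img[, , ch] %*% t(mc)
  lesion_image(out, img_id = attr(img, "img_id"))
}

#' Encode and decode diagnostic class names
#'
#' Fixed bijection between the six class names and integer codes 0..5:
#' ACK = 0, BCC = 1, MEL = 2, NEV = 3, SCC = 4, SEK = 5. Matching is
#' case-insensitive; unknown names are an error.
#'
#' @param name Character vector of class names.
#' @return Integer codes in 0..5.
#' @examples
#' encode_class(c("ACK", "sek"))  # 0 5
#' @export
encode_class <- function(name) {
  code <- match(toupper(name), CLASS_NAMES) - 1L
  if (anyNA(code)) {
    stop("unknown class name(s): ", paste(unique(name[is.na(code)]), collapse = ", "))
  }
  code
}

#' @rdname encode_class
#' @param code Integer codes 0..5.
#' @export
decode_class <- function(code) {
  if (any(code < 0L | code > 5L | code != floor(code))) stop("class codes must be integers 0..5")
  CLASS_NAMES[code + 1L]
}

#' Build the enhanced image triplet
#'
#' Produces the three 224 x 224 x 3 inputs consumed by the feature extractor:
#' the original image, its Black-Hat transform and its adaptive-threshold
#' binarisation (both computed on the grayscale image and replicated across
#' the three channels). The adaptive branch is blurred with `cfg$sigma` before
#' thresholding; the Black-Hat branch uses the raw grayscale.
#'
#' @param img A 224 x 224 x 3 [lesion_image()] (resize first if needed).
#' @param k A [structuring_element()]; default 9 x 9 ellipse.
#' @param cfg A [threshold_config()].
#' @return List of class `enhanced_triplet` with members `original`,
#'   `blackhat`, `adaptive`.
#' @export
enhance_triplet <- function(img, k = structuring_element("ellipse", 9),
                            cfg = threshold_config()) {
  if (!is_lesion_image(img)) stop("enhance_triplet() expects a 3-channel image")
  g <- to_grayscale(img)
  bh <- black_hat(g, k)
  ad <- adaptive_threshold(gaussian_blur(g, cfg$sigma), cfg)
  structure(
    list(original = img,
         blackhat = replicate_channels(bh),
         adaptive = replicate_channels(ad)),
    class = "enhanced_triplet", img_id = attr(img, "img_id")
  )
}
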