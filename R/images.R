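#' @keywords internal
"_PACKAGE"

# Raster conventions used throughout the package:
#   * colour images ("lesion images") are height x width x 3 numeric arrays
#     with intensities on the 8-bit scale 0..255 (stored as doubles);
#   * grayscale images are height x width matrices on the same scale;
#   * binary images are matrices containing only the values 0 and 255.
# Filters may produce fractional intensities; quantisation happens only at
# grayscale conversion and at PNG export.

#' The six diagnostic classes, in code order
#'
#' Fixed vocabulary and integer coding of the lesion classes: actinic keratosis
#' (ACK = 0), basal cell carcinoma (BCC = 1), melanoma (MEL = 2), nevus
#' (NEV = 3), squamous cell carcinoma (SCC = 4) and seborrheic keratosis
#' (SEK = 5).
#'
#' @format Character vector of length 6; position `i` holds the name of the
#'   class with integer code `i - 1`.
#' @export
CLASS_NAMES <- c("ACK", "BCC", "MEL", "NEV", "SCC", "SEK")

#' Construct a lesion (colour) image
#'
#' Validates and tags a height x width x 3 intensity array on the 0..255 scale.
#'
#' @param pixels Numeric array with three channels (RGB).
#' @param img_id Optional string identifier carried as an attribute.
#' @return The array, with class `lesion_image` and an `img_id` attribute.
#' @export
lesion_image <- function(pixels, img_id = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("a lesion image must be a height x width x 3 array")
  }
  if (anyNA(pixels) || !is.numeric(pixels)) stop("pixel values must be finite numerics")
  structure(pixels, class = "lesion_image", img_id = img_id)
}

#' @rdname lesion_image
#' @param x Object to test.
#' @export
is_lesion_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

as_gray_matrix <- function(img) {
  if (is.matrix(img)) return(img)
  stop("expected a single-channel (matrix) image")
}

#' Structuring element for morphological operations
#'
#' Builds the flat kernel used by [morph_close()] and [black_hat()]. Sizes must
#' be odd and at least 3 so the kernel has a well-defined centre pixel.
#'
#' @param shape One of `"ellipse"`, `"rectangle"`, `"cross"`.
#' @param size Odd integer side length, or a length-2 vector `(height, width)`.
#' @return Logical matrix marking the kernel support; class
#'   `structuring_element`.
#' @examples
#' structuring_element("ellipse", 9)
#' @export
structuring_element <- function(shape = c("ellipse", "rectangle", "cross"), size = 9) {
  shape <- match.arg(shape)
  if (length(size) == 1L) size <- c(size, size)
  size <- as.integer(size)
  if (any(size < 3L) || any(size %% 2L == 0L)) {
    stop("structuring element sizes must be odd integers >= 3")
  }
  h <- size[1]; w <- size[2]
  cy <- (h + 1L) / 2L; cx <- (w + 1L) / 2L
  ry <- (h - 1L) / 2L; rx <- (w - 1L) / 2L
  dy <- matrix(seq_len(h) - cy, h, w)
  dx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  m <- switch(shape,
    rectangle = matrix(TRUE, h, w),
    cross     = dy == 0 | dx == 0,
    # inclusive ellipse: boundary pixels belong to the kernel
    ellipse   = (dy / ry)^2 + (dx / rx)^2 <= 1 + 1e-9
  )
  structure(m, class = c("structuring_element", "matrix"), shape = shape)
}

#' Read a lesion photograph from PNG or JPEG
#'
#' @param path File path ending in `.png`, `.jpg` or `.jpeg`.
#' @return A [lesion_image()] on the 0..255 scale; grayscale files are
#'   replicated to 3 channels, alpha channels are dropped.
#' @export
read_lesion_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext)
  )
  if (is.matrix(raw)) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  lesion_image(raw * 255, img_id = sub("\\.[^.]+$", "", basename(path)))
}

#' Write an image as PNG
#'
#' Accepts colour arrays or single-channel matrices on the 0..255 scale;
#' values are clipped to the valid range before export.
#'
#' @param img Image array or matrix.
#' @param path Output path.
#' @export
write_image_png <- function(img, path) {
  x <- pmin(pmax(unclass(img) / 255, 0), 1)
  png::writePNG(x, target = path)
  invisible(path)
}

#' Replicate a single-channel image across 3 channels
#'
#' @param gray Matrix image.
#' @return A [lesion_image()] with identical channels.
#' @export
replicate_channels <- function(gray) {
  gray <- as_gray_matrix(gray)
  lesion_image(array(rep(gray, 3L), dim = c(dim(gray), 3L)))
}
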