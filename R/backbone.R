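# Patch-transformer feature-extraction contract: 224 x 224 x 3 image ->
# 14 x 14 x 768 feature map. The encoder geometry follows ViT-B/16 (16-pixel
# patches, 768-dim embeddings); weights come either from a seeded random
# initialisation (the "seeded-test" backbone, small depth, CPU-friendly) or
# from a user-supplied pretrained weight list (the adapter).

#' Backbone specification
#'
#' Describes the feature-extractor geometry and weight source. The output
#' contract is fixed: a 14 x 14 x 768 spatial feature map per image. The
#' seeded-test backbone is a randomly initialised encoder with the same
#' input/output geometry as ViT-B/16 but configurable (small) depth, so every
#' downstream stage is testable deterministically on one CPU; the
#' `"pretrained"` source is an adapter that consumes an externally supplied
#' weight list with the full 12-block geometry.
#'
#' @param weights_source `"seeded-test"` or `"pretrained"`.
#' @param seed Integer seed for the seeded-test initialisation.
#' @param depth Number of encoder blocks (>= 1); default 2 for the test
#'   backbone, 12 for pretrained geometry.
#' @param n_heads Attention heads (must divide 768).
#' @param mlp_hidden Hidden width of the per-block MLP.
#' @param patch_size,embed_dim,image_side Fixed contract geometry.
#' @return List of class `backbone_spec`.
#' @export
backbone_spec <- function(weights_source = c("seeded-test", "pretrained"),
                          seed = 1L,
                          depth = if (weights_source[1] == "pretrained") 12L else 2L,
                          n_heads = if (weights_source[1] == "pretrained") 12L else 4L,
                          mlp_hidden = if (weights_source[1] == "pretrained") 3072L else 768L,
                          patch_size = 16L, embed_dim = 768L, image_side = 224L) {
  weights_source <- match.arg(weights_source)
  if (image_side %% patch_size != 0L) stop("image side must be divisible by patch size")
  if (embed_dim %% n_heads != 0L) stop("embed_dim must be divisible by n_heads")
  if (depth < 1L) stop("depth must be >= 1")
  structure(list(
    weights_source = weights_source, seed = as.integer(seed), depth = as.integer(depth),
    n_heads = as.integer(n_heads), mlp_hidden = as.integer(mlp_hidden),
    patch_size = as.integer(patch_size), embed_dim = as.integer(embed_dim),
    image_side = as.integer(image_side),
    grid = as.integer(image_side / patch_size)
  ), class = "backbone_spec")
}

#' Split an image into a row-major patch sequence
#'
#' Tiles the image into non-overlapping `patch_size x patch_size` blocks in
#' row-major grid order (left-to-right, then top-to-bottom). Each patch is
#' flattened by R's column-major array order over (row, column, channel), so
#' `unpatchify()` reconstructs the image exactly.
#'
#' @param img A [lesion_image()] whose sides are divisible by `patch_size`.
#' @param patch_size Patch side in pixels.
#' @return Numeric matrix with one patch per row
#'   (`(side/patch_size)^2` rows, `patch_size^2 * 3` columns), with
#'   attribute `grid` giving the patch-grid side.
#' @export
patchify <- function(img, patch_size = 16L) {
  if (!is_lesion_image(img)) stop("patchify() expects a 3-channel image")
  d <- dim(img)
  if (d[1] %% patch_size != 0L || d[2] %% patch_size != 0L) {
    stop("image dimensions must be divisible by the patch size")
  }
  gy <- d[1] %/% patch_size; gx <- d[2] %/% patch_size
  out <- matrix(0, gy * gx, patch_size * patch_size * 3L)
  p <- 0L
  for (i in seq_len(gy)) {
    rows <- ((i - 1L) * patch_size + 1L):(i * patch_size)
    for (j in seq_len(gx)) {
      cols <- ((j - 1L) * patch_size + 1L):(j * patch_size)
      p <- p + 1L
      out[p, ] <- as.vector(unclass(img)[rows, cols, ])
    }
  }
  structure(out, grid = c(gy, gx), patch_size = patch_size)
}

#' @rdname patchify
#' @param patches Matrix produced by `patchify()`.
#' @export
unpatchify <- function(patches) {
  g <- attr(patches, "grid"); ps <- attr(patches, "patch_size")
  out <- array(0, dim = c(g[1] * ps, g[2] * ps, 3L))
  p <- 0L
  for (i in seq_len(g[1])) {
    rows <- ((i - 1L) * ps + 1L):(i * ps)
    for (j in seq_len(g[2])) {
      cols <- ((j - 1L) * ps + 1L):(j * ps)
      p <- p + 1L
      out[rows, cols, ] <- array(patches[p, ], dim = c(ps, ps, 3L))
    }
  }
  lesion_image(out)
}

# Per-channel normalisation constants (the conventional ImageNet statistics,
# applied identically to all three triplet members on the 0..1 scale).
NORM_MEAN <- c(0.485, 0.456, 0.406)
NORM_SD   <- c(0.229, 0.224, 0.225)

rnorm_mat <- function(n, m, sd = 0.02) matrix(stats::rnorm(n * m, sd = sd), n, m)

#' Build a backbone from a specification
#'
#' Materialises the encoder weights. For the seeded-test source all weights
#' are drawn N(0, 0.02^2) from `spec$seed` (restoring the caller's RNG state);
#' for the pretrained source a weight list with the same structure must be
#' supplied — typically converted from a released ViT-B/16 checkpoint.
#'
#' @param spec A [backbone_spec()].
#' @param weights For `weights_source = "pretrained"`, a list with elements
#'   `embed_w`, `embed_b`, `pos`, and per-block `wq, wk, wv, wo, bo, w1, b1,
#'   w2, b2` (list `blocks`).
#' @return List of class `vit_backbone`.
#' @export
build_backbone <- function(spec, weights = NULL) {
  stopifnot(inherits(spec, "backbone_spec"))
  n_tok <- spec$grid^2
  d <- spec$embed_dim
  raw <- spec$patch_size^2 * 3L
  if (spec$weights_source == "pretrained") {
    if (is.null(weights)) {
      stop("pretrained backbone requires a user-supplied weight list ",
           "(no checkpoint is bundled); see ?build_backbone")
    }
    w <- weights
  } else {
    w <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(spec$seed)
      list(
        embed_w = rnorm_mat(raw, d),
        embed_b = stats::rnorm(d, sd = 0.02),
        pos = rnorm_mat(n_tok, d),
        blocks = lapply(seq_len(spec$depth), function(i) list(
          wq = rnorm_mat(d, d), wk = rnorm_mat(d, d), wv = rnorm_mat(d, d),
          wo = rnorm_mat(d, d), bo = stats::rnorm(d, sd = 0.02),
          w1 = rnorm_mat(d, spec$mlp_hidden), b1 = stats::rnorm(spec$mlp_hidden, sd = 0.02),
          w2 = rnorm_mat(spec$mlp_hidden, d), b2 = stats::rnorm(d, sd = 0.02)
        ))
      )
    })
  }
  structure(list(spec = spec, weights = w), class = "vit_backbone")
}

layer_norm <- function(x, eps = 1e-6) {
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  (x - mu) / sqrt(v + eps)
}

gelu <- function(x) x * stats::pnorm(x)

softmax_rows <- function(x) {
  x <- exp(x - apply(x, 1, max))
  x / rowSums(x)
}

encoder_block <- function(x, b, n_heads) {
  d <- ncol(x); dh <- d %/% n_heads
  h <- layer_norm(x)
  q <- h %*% b$wq; k <- h %*% b$wk; v <- h %*% b$wv
  out <- matrix(0, nrow(x), d)
  for (hd in seq_len(n_heads)) {
    idx <- ((hd - 1L) * dh + 1L):(hd * dh)
    a <- softmax_rows(tcrossprod(q[, idx], k[, idx]) / sqrt(dh))
    out[, idx] <- a %*% v[, idx]
  }
  x <- x + sweep(out %*% b$wo, 2, b$bo, "+")
  h <- layer_norm(x)
  x + sweep(gelu(sweep(h %*% b$w1, 2, b$b1, "+")) %*% b$w2, 2, b$b2, "+")
}

#' Extract a spatial feature map from one image
#'
#' Normalises the image (0..1 scale, per-channel standardisation), embeds its
#' 16 x 16 patches, adds position embeddings, runs the encoder blocks and
#' reshapes the final (layer-normalised) token sequence row-major into a
#' `grid x grid x 768` spatial map. No class token is used, so the token
#' sequence and the spatial map correspond one-to-one. Deterministic for a
#' fixed backbone and input.
#'
#' @param img A [lesion_image()] of the spec's geometry (224 x 224 x 3).
#' @param backbone A [build_backbone()] result, or a [backbone_spec()]
#'   (built on the fly for convenience).
#' @param provenance Optional string recording which triplet member the map
#'   came from; stored as an attribute.
#' @return `grid x grid x 768` numeric array of class `feature_map`.
#' @export
extract_features <- function(img, backbone, provenance = NULL) {
  if (inherits(backbone, "backbone_spec")) backbone <- build_backbone(backbone)
  stopifnot(inherits(backbone, "vit_backbone"))
  spec <- backbone$spec
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[1] != spec$image_side || d[2] != spec$image_side) {
    stop("extract_features() expects a ", spec$image_side, "x", spec$image_side, "x3 image")
  }
  x <- unclass(img) / 255
  for (ch in 1:3) x[, , ch] <- (x[, , ch] - NORM_MEAN[ch]) / NORM_SD[ch]
  tok <- patchify(lesion_image(x), spec$patch_size)
  w <- backbone$weights
  z <- sweep(tok %*% w$embed_w, 2, w$embed_b, "+") + w$pos
  for (b in w$blocks) z <- encoder_block(z, b, spec$n_heads)
  z <- layer_norm(z)
  g <- spec$grid
  fm <- array(0, dim = c(g, g, spec$embed_dim))
  for (i in seq_len(g)) fm[i, , ] <- z[((i - 1L) * g + 1L):(i * g), ]
  structure(fm, class = "feature_map", provenance = provenance)
}
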