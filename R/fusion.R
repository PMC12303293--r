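# Fusion of the three branch feature maps and the image-branch prediction
# head: element-wise multiplication against the original-image features,
# width-axis concatenation, global average pooling, and a dense softmax layer
# trained with class-weighted categorical focal loss.

#' Element-wise feature-map multiplication
#'
#' Multiplies two feature maps of identical shape entry by entry. Used to
#' modulate the original-image features by the Black-Hat and adaptive-threshold
#' branch features, emphasising dark contours and locally salient structure.
#'
#' @param fa,fb Feature maps (arrays) of identical shape.
#' @return Array of the same shape.
#' @export
multiply_features <- function(fa, fb) {
  if (!identical(dim(fa), dim(fb))) stop("feature maps must have identical shapes")
  structure(unclass(fa) * unclass(fb), class = "feature_map",
            provenance = paste(attr(fa, "provenance"), attr(fb, "provenance"), sep = "*"))
}

#' Concatenate branch feature maps along the width axis
#'
#' Joins the original-image map and the two multiplicative fusion maps along
#' the spatial x-axis, in the fixed order (original, Black-Hat product,
#' adaptive product): three `h x w x c` maps become one `h x 3w x c` map.
#' Slicing the output columns recovers each input exactly.
#'
#' @param f_orig,m_bh,m_ad Feature maps of identical shape.
#' @return Array of class `fused_feature_map`, width tripled.
#' @export
concat_features <- function(f_orig, m_bh, m_ad) {
  if (!identical(dim(f_orig), dim(m_bh)) || !identical(dim(f_orig), dim(m_ad))) {
    stop("feature maps must have identical shapes")
  }
  d <- dim(f_orig)
  out <- array(0, dim = c(d[1], 3L * d[2], d[3]))
  out[, seq_len(d[2]), ] <- f_orig
  out[, d[2] + seq_len(d[2]), ] <- m_bh
  out[, 2L * d[2] + seq_len(d[2]), ] <- m_ad
  structure(out, class = "fused_feature_map")
}

#' Global average pooling
#'
#' Reduces a spatial feature map to one value per channel: the mean over all
#' spatial positions. Because fusion concatenates along the width axis, the
#' GAP of the fused map equals the arithmetic mean of the three branch GAPs.
#'
#' @param fm `h x w x c` array.
#' @return Numeric vector of length `c`.
#' @export
global_average_pool <- function(fm) {
  d <- dim(fm)
  colMeans(matrix(unclass(fm), d[1] * d[2], d[3]))
}

#' Dense layer + softmax prediction
#'
#' Computes class probabilities `softmax(W v + b)` with the numerically stable
#' shifted exponential (invariant to adding a constant to all logits).
#'
#' @param v Feature vector.
#' @param head_weights List with `W` (6 x length(v)) and `b` (length 6).
#' @return Named probability vector over the six classes, summing to 1.
#' @export
dense_softmax <- function(v, head_weights) {
  if (!all(is.finite(v))) stop("non-finite feature vector")
  z <- drop(head_weights$W %*% v + head_weights$b)
  if (!all(is.finite(z))) stop("non-finite logits")
  e <- exp(z - max(z))
  p <- e / sum(e)
  names(p) <- CLASS_NAMES
  p
}

#' Inverse-frequency class weights
#'
#' Balanced weights `w_c = N / (K * n_c)` for `N` samples over `K` classes,
#' so a perfectly balanced label set gets unit weights everywhere.
#'
#' @param labels Integer class codes `0..n_classes-1`.
#' @param n_classes Number of classes (default 6).
#' @return Numeric vector of length `n_classes`; errors if a class is absent.
#' @export
compute_class_weights <- function(labels, n_classes = 6L) {
  counts <- tabulate(labels + 1L, nbins = n_classes)
  if (any(counts == 0L)) {
    stop("class(es) absent from labels: ", paste(which(counts == 0L) - 1L, collapse = ", "))
  }
  length(labels) / (n_classes * counts)
}

#' Head training configuration
#'
#' @param gamma Focal-loss focusing exponent (>= 0); `gamma = 0` reduces the
#'   loss to class-weighted cross-entropy.
#' @param alpha Focal-loss balance factor.
#' @param class_weights Optional length-6 positive weights; computed from the
#'   training labels via [compute_class_weights()] when `NULL`.
#' @param epochs Full-batch gradient steps.
#' @param learning_rate Step size (features are standardised internally, so
#'   the default is stable).
#' @param momentum Classical momentum coefficient.
#' @param val_frac Fraction of the training set carved out (stratified) to
#'   select the best epoch; 0 disables early stopping.
#' @param seed Seed for initialisation and the validation carve-out.
#' @return List of class `head_config`.
#' @export
head_config <- function(gamma = 2, alpha = 0.25, class_weights = NULL,
                        epochs = 300L, learning_rate = 0.5, momentum = 0.9,
                        val_frac = 0, seed = 1L) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (!is.null(class_weights) && (length(class_weights) != 6L || any(class_weights <= 0))) {
    stop("class_weights must be 6 positive reals")
  }
  structure(list(gamma = gamma, alpha = alpha, class_weights = class_weights,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, val_frac = val_frac, seed = as.integer(seed)),
            class = "head_config")
}

#' Categorical focal loss
#'
#' `-alpha * w_y * (1 - p_y)^gamma * log(p_y)` for true class `y`, where `w_y`
#' is the class weight. The probability is clipped at `1e-12` to keep the loss
#' finite for degenerate inputs. At `gamma = 0`, `alpha = 1` this is exactly
#' class-weighted cross-entropy.
#'
#' @param p Probability vector over the six classes.
#' @param y True class code 0..5.
#' @param cfg A [head_config()]; uses unit class weights when none are set.
#' @return Non-negative scalar.
#' @export
focal_loss <- function(p, y, cfg = head_config()) {
  w <- if (is.null(cfg$class_weights)) rep(1, 6) else cfg$class_weights
  u <- min(max(p[y + 1L], 1e-12), 1)
  -cfg$alpha * w[y + 1L] * (1 - u)^cfg$gamma * log(u)
}

# Mean focal loss and its gradient w.r.t. logits for a batch.
# x: n x d standardised features, W: 6 x d, b: 6, y: codes 0..5.
focal_forward_backward <- function(x, w_mat, b, y, cfg, cw) {
  z <- x %*% t(w_mat)
  z <- sweep(z, 2, b, "+")
  p <- softmax_rows(z)
  n <- nrow(x)
  iy <- cbind(seq_len(n), y + 1L)
  u <- pmin(pmax(p[iy], 1e-12), 1)
  wv <- cw[y + 1L]
  loss <- mean(-cfg$alpha * wv * (1 - u)^cfg$gamma * log(u))
  # dL/du, then chain through the softmax: du/dz_k = u * (1[k = y] - p_k)
  dl_du <- cfg$alpha * wv * (cfg$gamma * (1 - u)^pmax(cfg$gamma - 1, 0) * log(u) -
                               (1 - u)^cfg$gamma / u)
  onehot <- matrix(0, n, 6); onehot[iy] <- 1
  gz <- (dl_du * u) * (onehot - p) / n
  list(loss = loss, gw = t(gz) %*% x, gb = colSums(gz), probs = p)
}

#' Fit the image-branch softmax head
#'
#' Trains the dense 768 -> 6 softmax layer on global-average-pooled fused
#' features by full-batch gradient descent with momentum on the class-weighted
#' categorical focal loss. Features are standardised column-wise (statistics
#' stored in the head); initial weights are small seeded Gaussians, so the fit
#' is deterministic for a fixed seed. With `val_frac > 0`, a stratified
#' carve-out selects the epoch with the lowest validation loss.
#'
#' @param features `n x d` matrix of pooled feature vectors, or a list of
#'   fused feature maps (pooled internally).
#' @param labels Integer class codes 0..5, length `n`.
#' @param cfg A [head_config()].
#' @return List of class `image_head` with the layer weights, standardisation
#'   statistics, config and loss history.
#' @export
fit_image_head <- function(features, labels, cfg = head_config()) {
  if (is.list(features)) features <- t(vapply(features, global_average_pool,
                                              numeric(dim(features[[1]])[3])))
  x <- as.matrix(features)
  if (nrow(x) == 0L) stop("empty feature set")
  if (nrow(x) != length(labels)) stop("features and labels disagree in length")
  cw <- cfg$class_weights
  if (is.null(cw)) cw <- compute_class_weights(labels)
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  idx_val <- integer(0)
  if (cfg$val_frac > 0) {
    for (cls in unique(labels)) {
      members <- which(labels == cls)
      n_v <- floor(length(members) * cfg$val_frac + 0.5)
      if (n_v > 0 && n_v < length(members)) {
        idx_val <- c(idx_val, sample(members, n_v))
      }
    }
  }
  idx_tr <- setdiff(seq_len(nrow(xs)), idx_val)

  w_mat <- matrix(stats::rnorm(6 * ncol(xs), sd = 0.01), 6, ncol(xs))
  b <- rep(0, 6)
  vw <- 0 * w_mat; vb <- b
  best <- list(loss = Inf, w = w_mat, b = b)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    fb <- focal_forward_backward(xs[idx_tr, , drop = FALSE], w_mat, b,
                                 labels[idx_tr], cfg, cw)
    vw <- cfg$momentum * vw - cfg$learning_rate * fb$gw
    vb <- cfg$momentum * vb - cfg$learning_rate * fb$gb
    w_mat <- w_mat + vw; b <- b + vb
    history[ep] <- fb$loss
    if (length(idx_val) > 0) {
      vl <- focal_forward_backward(xs[idx_val, , drop = FALSE], w_mat, b,
                                   labels[idx_val], cfg, cw)$loss
      if (vl < best$loss) best <- list(loss = vl, w = w_mat, b = b)
    }
  }
  if (length(idx_val) > 0) { w_mat <- best$w; b <- best$b }
  structure(list(W = w_mat, b = b, center = ctr, scale = scl, cfg = cfg,
                 class_weights = cw, loss_history = history, version = "1"),
            class = "image_head")
}

#' Predict image-branch probabilities
#'
#' @param head An [fit_image_head()] result.
#' @param features `n x d` matrix of pooled feature vectors (or a single
#'   vector, or a list of fused maps).
#' @return `n x 6` matrix of probabilities, rows summing to 1.
#' @export
predict_image_probs <- function(head, features) {
  if (is.list(features)) features <- t(vapply(features, global_average_pool,
                                              numeric(dim(features[[1]])[3])))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  xs <- sweep(sweep(as.matrix(features), 2, head$center), 2, head$scale, "/")
  z <- sweep(xs %*% t(head$W), 2, head$b, "+")
  p <- softmax_rows(z)
  colnames(p) <- CLASS_NAMES
  p
}

#' Pool the fused features of an enhanced triplet
#'
#' Convenience composition of the image branch up to the head input: extracts
#' the three branch feature maps, forms the two multiplicative fusion maps,
#' concatenates along the width axis and global-average-pools to a single
#' 768-vector.
#'
#' @param triplet An [enhance_triplet()] result.
#' @param backbone A built backbone.
#' @return Numeric vector of length `embed_dim`.
#' @export
fused_gap_features <- function(triplet, backbone) {
  stopifnot(inherits(triplet, "enhanced_triplet"))
  f_o <- extract_features(triplet$original, backbone, "original")
  f_b <- extract_features(triplet$blackhat, backbone, "blackhat")
  f_a <- extract_features(triplet$adaptive, backbone, "adaptive")
  fused <- concat_features(f_o, multiply_features(f_o, f_b),
                           multiply_features(f_o, f_a))
  global_average_pool(fused)
}
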