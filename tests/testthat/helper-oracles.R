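# Independent brute-force oracles used to cross-check the vectorised
# implementations. These deliberately use naive per-pixel loops and share no
# code with the package internals beyond the documented conventions
# (reflect-101 borders, the stated kernel definitions).

oracle_reflect <- function(i, n) {
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

# Windowed extreme (max/min) over the structuring-element support.
oracle_morph <- function(img, k, f) {
  ry <- (nrow(k) - 1L) / 2L
  rx <- (ncol(k) - 1L) / 2L
  out <- img
  for (y in seq_len(nrow(img))) {
    for (x in seq_len(ncol(img))) {
      vals <- c()
      for (dy in -ry:ry) {
        for (dx in -rx:rx) {
          if (k[dy + ry + 1L, dx + rx + 1L]) {
            vals <- c(vals, img[oracle_reflect(y + dy, nrow(img)),
                                oracle_reflect(x + dx, ncol(img))])
          }
        }
      }
      out[y, x] <- f(vals)
    }
  }
  out
}

oracle_black_hat <- function(img, k) {
  oracle_morph(oracle_morph(img, k, max), k, min) - img
}

# Direct per-pixel evaluation of the local-threshold rule: white iff the
# pixel strictly exceeds the Gaussian-weighted window mean minus C.
oracle_adaptive <- function(img, window, C, weight_sigma = (window - 1) / 2) {
  r <- (window - 1L) / 2L
  x <- -r:r
  w1 <- exp(-x^2 / (2 * weight_sigma^2))
  w2 <- outer(w1, w1)
  w2 <- w2 / sum(w2)
  n <- nrow(img); m <- ncol(img)
  out <- img
  for (y in seq_len(n)) {
    for (xx in seq_len(m)) {
      win <- img[oracle_reflect(y + (-r:r), n), oracle_reflect(xx + (-r:r), m)]
      thr <- sum(w2 * win) - C
      out[y, xx] <- if (img[y, xx] > thr) 255 else 0
    }
  }
  out
}

random_gray <- function(n, m = n) matrix(sample(0:255, n * m, replace = TRUE), n, m)

with_seed_image <- function(side, seed) {
  set.seed(seed)
  random_lesion_array(side)
}

random_lesion_array <- function(side = 32) {
  lesion_image(array(runif(side * side * 3, 0, 255), dim = c(side, side, 3)))
}

# Printed per-class report used by the arithmetic-reproduction tests: the
# published per-class PPV/recall/F1/NPV values of the six lesion classes on
# the 460-sample test set.
published_per_class <- function() {
  data.frame(
    class = c("ACK", "BCC", "MEL", "NEV", "SCC", "SEK"),
    ppv = c(0.972028, 1, 1, 1, 0.840909, 1),
    recall = c(0.952055, 1, 1, 1, 0.948718, 0.957447),
    f1 = c(0.961938, 1, 1, 1, 0.891566, 0.978261),
    npv = c(0.977918, 1, 1, 1, 0.995192, 0.995181)
  )
}
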