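random_map <- function(h = 4, w = 4, c = 3) {
  structure(array(rnorm(h * w * c), dim = c(h, w, c)), class = "feature_map")
}

test_that("feature multiplication is element-wise with identity and annihilator", {
  set.seed(30)
  fa <- random_map()
  ones <- structure(array(1, dim = dim(fa)), class = "feature_map")
  expect_equal(unclass(multiply_features(fa, ones)), unclass(fa), ignore_attr = TRUE)
  expect_true(all(multiply_features(fa, 0 * fa) == 0))

  fb <- random_map(2, 2, 3); fa2 <- random_map(2, 2, 3)
  prod <- multiply_features(fa2, fb)
  for (i in 1:2) for (j in 1:2) for (ch in 1:3) {
    expect_identical(prod[i, j, ch], fa2[i, j, ch] * fb[i, j, ch])
  }
  expect_equal(unclass(multiply_features(fb, fa2)), unclass(prod), ignore_attr = TRUE)
  expect_error(multiply_features(fa, fb), "identical shapes")
})

test_that("width-axis concatenation is ordered and sliceable", {
  set.seed(31)
  a <- random_map(14, 14, 5); b <- random_map(14, 14, 5); c <- random_map(14, 14, 5)
  fused <- concat_features(a, b, c)
  expect_equal(dim(fused), c(14L, 42L, 5L))
  expect_equal(fused[, 1:14, ], unclass(a), ignore_attr = TRUE)
  expect_equal(fused[, 15:28, ], unclass(b), ignore_attr = TRUE)
  expect_equal(fused[, 29:42, ], unclass(c), ignore_attr = TRUE)
  # explicit index arithmetic on a small case
  a2 <- random_map(2, 3, 2); b2 <- random_map(2, 3, 2); c2 <- random_map(2, 3, 2)
  f2 <- concat_features(a2, b2, c2)
  for (i in 1:2) for (j in 1:3) for (ch in 1:2) {
    expect_identical(f2[i, j, ch], a2[i, j, ch])
    expect_identical(f2[i, 3 + j, ch], b2[i, j, ch])
    expect_identical(f2[i, 6 + j, ch], c2[i, j, ch])
  }
  expect_error(concat_features(a, b, random_map(7, 14, 5)), "identical shapes")
})

test_that("global average pooling averages each channel over space", {
  const <- structure(array(3.5, dim = c(4, 6, 2)), class = "fused_feature_map")
  expect_equal(global_average_pool(const), c(3.5, 3.5))

  set.seed(32)
  fm <- random_map(5, 7, 4)
  got <- global_average_pool(fm)
  want <- numeric(4)
  for (ch in 1:4) {
    s <- 0
    for (i in 1:5) for (j in 1:7) s <- s + fm[i, j, ch]
    want[ch] <- s / 35
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("GAP of the width-concatenated map is the mean of branch GAPs", {
  set.seed(33)
  for (rep in 1:10) {
    a <- random_map(14, 14, 8); b <- random_map(14, 14, 8); c <- random_map(14, 14, 8)
    lhs <- global_average_pool(concat_features(a, b, c))
    rhs <- (global_average_pool(a) + global_average_pool(b) +
              global_average_pool(c)) / 3
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("dense softmax normalises and is shift invariant", {
  hw <- list(W = matrix(0, 6, 8), b = rep(0, 6))
  expect_equal(unname(dense_softmax(rnorm(8), hw)), rep(1 / 6, 6))

  hw1 <- list(W = diag(1, 6, 6), b = rep(0, 6))
  p <- dense_softmax(c(1, 0, 0, 0, 0, 0), hw1)
  want <- exp(c(1, 0, 0, 0, 0, 0)); want <- want / sum(want)
  expect_equal(unname(p), want, tolerance = 1e-12)

  hw2 <- list(W = diag(1, 6, 6), b = rep(10, 6))
  expect_equal(unname(dense_softmax(c(1, 0, 0, 0, 0, 0), hw2)), want,
               tolerance = 1e-9)
  expect_error(dense_softmax(c(Inf, rnorm(5)), hw1), "non-finite")
})

test_that("focal loss has the cross-entropy reduction and monotonicity", {
  cfg <- head_config(gamma = 0, alpha = 1)
  p <- c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1)
  expect_equal(focal_loss(p, 0L, cfg), log(2), tolerance = 1e-12)

  perfect <- c(1, 0, 0, 0, 0, 0)
  for (g in c(0, 1, 2, 5)) {
    cfgg <- head_config(gamma = g, alpha = 0.25)
    expect_equal(focal_loss(perfect, 0L, cfgg), 0)
    p9 <- c(0.9, rep(0.02, 5)); p5 <- c(0.5, rep(0.1, 5))
    expect_lt(focal_loss(p9, 0L, cfgg), focal_loss(p5, 0L, cfgg))
    expect_gte(focal_loss(p5, 0L, cfgg), 0)
  }
  expect_error(head_config(gamma = -1), "gamma")
})

test_that("focal loss gradient matches a finite-difference check", {
  set.seed(34)
  x <- matrix(rnorm(5 * 4), 5, 4)
  y <- c(0L, 2L, 5L, 1L, 2L)
  w_mat <- matrix(rnorm(24, sd = 0.3), 6, 4)
  b <- rnorm(6, sd = 0.1)
  cfg <- head_config(gamma = 2, alpha = 0.25)
  cw <- rep(1, 6)
  fb <- dermastack:::focal_forward_backward(x, w_mat, b, y, cfg, cw)
  eps <- 1e-6
  for (probe in list(c(1, 1), c(3, 2), c(6, 4))) {
    wp <- w_mat; wp[probe[1], probe[2]] <- wp[probe[1], probe[2]] + eps
    wm <- w_mat; wm[probe[1], probe[2]] <- wm[probe[1], probe[2]] - eps
    num <- (dermastack:::focal_forward_backward(x, wp, b, y, cfg, cw)$loss -
              dermastack:::focal_forward_backward(x, wm, b, y, cfg, cw)$loss) / (2 * eps)
    expect_equal(fb$gw[probe[1], probe[2]], num, tolerance = 1e-5)
  }
})

test_that("class weights follow N / (K * n_c)", {
  expect_equal(compute_class_weights(rep(0:5, each = 4)), rep(1, 6))
  expect_equal(compute_class_weights(rep(c(0L, 1L), c(10, 30)), n_classes = 2L),
               c(2, 2 / 3), tolerance = 1e-12)
  set.seed(35)
  lab <- rep(0:5, times = c(3, 9, 4, 7, 2, 5))
  expect_equal(compute_class_weights(sample(lab)), compute_class_weights(lab))
  expect_error(compute_class_weights(c(0L, 1L, 2L)), "absent")
})

separable_features <- function(n_per_class, d = 12, sep = 4, seed = 1) {
  set.seed(seed)
  labels <- rep(0:5, each = n_per_class)
  centers <- matrix(rnorm(6 * d), 6, d) * sep
  x <- centers[labels + 1, ] + matrix(rnorm(length(labels) * d), ncol = d)
  list(x = x, labels = labels)
}

test_that("the image head learns separable features and is seed-deterministic", {
  fx <- separable_features(30)
  tr <- sort(unlist(lapply(0:5, function(cl) which(fx$labels == cl)[1:24])))
  te <- setdiff(seq_along(fx$labels), tr)
  cfg <- head_config(epochs = 150, seed = 9)
  head <- fit_image_head(fx$x[tr, ], fx$labels[tr], cfg)
  acc <- mean((apply(predict_image_probs(head, fx$x[te, ]), 1, which.max) - 1L)
              == fx$labels[te])
  expect_gt(acc, 0.95)

  head2 <- fit_image_head(fx$x[tr, ], fx$labels[tr], cfg)
  expect_identical(head$W, head2$W)
  expect_identical(head$b, head2$b)

  # training loss decreases on average
  h <- head$loss_history
  expect_lt(mean(tail(h, 10)), mean(head(h, 10)))
})

test_that("the image head cannot learn label-shuffled features", {
  fx <- separable_features(40, seed = 2)
  set.seed(77)
  shuffled <- sample(fx$labels)
  tr <- seq_len(192); te <- setdiff(seq_along(shuffled), tr)
  head <- fit_image_head(fx$x[tr, ], shuffled[tr], head_config(epochs = 120, seed = 3))
  acc <- mean((apply(predict_image_probs(head, fx$x[te, ]), 1, which.max) - 1L)
              == shuffled[te])
  expect_lt(abs(acc - 1 / 6), 0.12)
  expect_error(fit_image_head(fx$x[0, , drop = FALSE], integer(0)), "empty")
})
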