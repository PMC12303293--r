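test_that("grayscale conversion follows the luma convention", {
  uni <- lesion_image(array(100, dim = c(4, 4, 3)))
  expect_true(all(to_grayscale(uni) == 100))

  red <- array(0, dim = c(3, 3, 3)); red[, , 1] <- 255
  # independent per-pixel dot product with the BT.601 weights, rounded half-up
  expect_true(all(to_grayscale(lesion_image(red)) ==
                    floor(255 * 0.299 + 0.5)))

  g <- random_gray(8)
  expect_equal(to_grayscale(replicate_channels(g)), g)
  expect_error(to_grayscale(g), "3-channel")
})

test_that("structuring elements validate their geometry", {
  expect_error(structuring_element("ellipse", 4), "odd")
  expect_error(structuring_element("rectangle", 1), "odd")
  expect_true(all(structuring_element("rectangle", 3)))
  cross <- structuring_element("cross", 5)
  expect_equal(sum(cross), 9)
})

test_that("morphological closing fills dark gaps and is extensive and idempotent", {
  k <- structuring_element("rectangle", 3)
  const <- matrix(77, 10, 10)
  expect_equal(morph_close(const, k), const)

  holed <- matrix(255, 9, 9); holed[5, 5] <- 0
  expect_true(all(morph_close(holed, k) == 255))

  set.seed(101)
  for (i in 1:5) {
    img <- random_gray(16)
    closed <- morph_close(img, k)
    expect_true(all(closed >= img))                      # extensive
    expect_equal(morph_close(closed, k), closed)         # idempotent
    img2 <- pmin(img + sample(0:20, 256, TRUE), 255)
    expect_true(all(morph_close(img2, k) >= closed))     # order-preserving
  }
  expect_error(morph_close(matrix(0, 2, 2), k), "larger")
})

test_that("black-hat equals the brute-force morphology oracle bit-exactly", {
  set.seed(7)
  for (k in list(structuring_element("rectangle", 3),
                 structuring_element("ellipse", 5))) {
    img <- random_gray(16)
    expect_identical(black_hat(img, k), oracle_black_hat(img, k))
  }
  k <- structuring_element("rectangle", 3)
  expect_true(all(black_hat(matrix(42, 8, 8), k) == 0))
  holed <- matrix(255, 9, 9); holed[4, 6] <- 0
  bh <- black_hat(holed, k)
  expect_equal(bh[4, 6], 255)
  expect_equal(sum(bh), 255)
  set.seed(8)
  expect_true(all(black_hat(random_gray(12), k) >= 0))
})

test_that("gaussian blur preserves constants and normalises its kernel", {
  expect_equal(gaussian_blur(matrix(5, 6, 6), 1.3), matrix(5, 6, 6))

  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  out <- gaussian_blur(imp, 1)
  r <- ceiling(3 * 1)
  k1 <- exp(-(-r:r)^2 / 2); k1 <- k1 / sum(k1)
  # separable response: cross-sections through the centre are k1 scaled by
  # the orthogonal centre weight
  expect_equal(out[8, 8 + (-r:r)], k1 * k1[r + 1], tolerance = 1e-12)
  expect_equal(out[8 + (-r:r), 8], k1 * k1[r + 1], tolerance = 1e-12)
  expect_lt(abs(sum(out) - 1), 1e-3)                     # mass conserved
  expect_error(gaussian_blur(imp, 0), "positive")
})

test_that("adaptive threshold implements the strict local-mean rule", {
  cfg <- threshold_config(window = 21, C = 5, sigma = 1)
  const <- matrix(128, 32, 32)
  expect_true(all(adaptive_threshold(const, cfg) == 255))          # c > c - C
  cfg0 <- threshold_config(window = 21, C = 0, sigma = 1)
  expect_true(all(adaptive_threshold(const, cfg0) == 0))           # strict tie

  img <- matrix(200, 32, 32); img[13:20, 13:20] <- 80
  got <- adaptive_threshold(img, cfg)
  expect_identical(got, oracle_adaptive(img, 21, 5))
  expect_true(all(got %in% c(0, 255)))
  expect_error(threshold_config(window = 20), "odd")
})

test_that("resize uses area averaging down and is idempotent", {
  img <- random_lesion_array(224)
  expect_identical(resize_image(img), img)

  const <- lesion_image(array(90, dim = c(448, 448, 3)))
  small <- resize_image(const)
  expect_equal(dim(small), c(224L, 224L, 3L))
  expect_true(all(abs(small - 90) < 1e-9))

  # pixel checkerboard halved by area interpolation -> uniform block mean,
  # since every output pixel covers exactly two black and two white pixels
  cb <- array(0, dim = c(448, 448, 3))
  blocks <- outer(seq_len(448), seq_len(448), function(i, j) (i + j) %% 2)
  for (ch in 1:3) cb[, , ch] <- 255 * blocks
  half <- resize_image(lesion_image(cb), c(224, 224))
  expect_true(all(abs(half - 127.5) < 1e-9))
  expect_identical(resize_image(half, c(224, 224)), half)
})

test_that("class encoding is the fixed case-insensitive bijection", {
  expect_equal(encode_class("ACK"), 0L)
  expect_equal(encode_class("SEK"), 5L)
  expect_equal(encode_class(c("bcc", "Mel", "NEV", "scc")), 1:4)
  expect_error(encode_class("XYZ"), "unknown")
  expect_equal(encode_class(decode_class(0:5)), 0:5)
  expect_error(decode_class(6), "0..5")
})

test_that("enhanced triplet members equal the individually invoked components", {
  k <- structuring_element("ellipse", 9)
  cfg <- threshold_config()
  const <- lesion_image(array(140, dim = c(224, 224, 3)))
  tri <- enhance_triplet(const, k, cfg)
  expect_true(all(tri$blackhat == 0))
  expect_true(all(tri$adaptive == 255))

  img <- random_lesion_array(224)
  tri <- enhance_triplet(img, k, cfg)
  g <- to_grayscale(img)
  expect_equal(tri$blackhat[, , 2], black_hat(g, k))
  expect_equal(tri$adaptive[, , 3],
               adaptive_threshold(gaussian_blur(g, cfg$sigma), cfg))
  expect_equal(unclass(tri$original), unclass(img), ignore_attr = TRUE)
  for (m in tri) expect_equal(dim(m), c(224L, 224L, 3L))
})

test_that("PNG round trip preserves 8-bit pixel values", {
  img <- lesion_image(array(sample(0:255, 16 * 16 * 3, TRUE), dim = c(16, 16, 3)))
  path <- tempfile(fileext = ".png")
  write_image_png(img, path)
  back <- read_lesion_image(path)
  expect_equal(unclass(back), unclass(img), ignore_attr = TRUE, tolerance = 1e-9)
})
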