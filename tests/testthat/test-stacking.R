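test_that("fold plans are stratified, balanced and deterministic", {
  lab <- rep(0:5, each = 10)
  plan <- make_fold_plan(lab, K = 10, seed = 1)
  for (k in 1:10) {
    expect_equal(sort(lab[plan$fold == k]), 0:5)   # one of each class per fold
  }
  plan2 <- make_fold_plan(lab, K = 10, seed = 1)
  expect_identical(plan$fold, plan2$fold)
  expect_false(identical(plan$fold, make_fold_plan(lab, K = 10, seed = 2)$fold))

  set.seed(44)
  for (rep in 1:8) {
    counts <- sample(3:40, 6, replace = TRUE)
    lab <- sample(rep(0:5, times = counts))
    K <- 3L
    plan <- make_fold_plan(lab, K, seed = rep)
    sizes <- tabulate(plan$fold, K)
    expect_lte(diff(range(sizes)), 1L)
    for (cl in 0:5) {
      per_fold <- tabulate(plan$fold[lab == cl], K)
      expect_lte(max(abs(per_fold - counts[cl + 1] / K)), 1)
    }
  }
  expect_error(make_fold_plan(rep(0:5, each = 3), K = 10), "fewer than K")
})

test_that("stacked vectors concatenate the halves image-first", {
  u <- rep(1 / 6, 6)
  expect_equal(unname(stack_probs(u, u)), rep(1 / 6, 12))

  set.seed(45)
  for (rep in 1:10) {
    p1 <- rgamma(6, 1); p1 <- p1 / sum(p1)
    p2 <- rgamma(6, 1); p2 <- p2 / sum(p2)
    z <- stack_probs(p1, p2)
    expect_length(z, 12L)
    expect_equal(unname(z[1:6]), p1)
    expect_equal(sum(z[1:6]), 1, tolerance = 1e-6)
    expect_equal(sum(z[7:12]), 1, tolerance = 1e-6)
  }
  expect_error(stack_probs(c(0.5, 0.5), u), "probability vector")
  expect_error(stack_probs(rep(0.5, 6), u), "probability vector")
})

# Small paired fixture with signal in both modalities.
oof_fixture <- function(n = 96, seed = 5) {
  set.seed(seed)
  labels <- sample(rep(0:5, length.out = n))
  centers <- matrix(rnorm(6 * 8), 6, 8) * 3
  feats <- centers[labels + 1, ] + matrix(rnorm(n * 8), ncol = 8)
  cfg <- synth_config(n_samples = n, seed = seed)
  table <- clean_metadata(generate_clinical_records(cfg, labels, seed))$table
  list(feats = feats, table = table, labels = labels)
}

fast_cfgs <- function() {
  list(head = head_config(epochs = 60, seed = 1),
       clin = clinical_config(nrounds = 25, seed = 1))
}

test_that("every sample gets exactly one leakage-free out-of-fold vector", {
  fx <- oof_fixture()
  plan <- make_fold_plan(fx$labels, K = 4, seed = 2)
  cfgs <- fast_cfgs()
  oof <- make_oof_stack(fx$feats, fx$table, fx$labels, plan, cfgs$head, cfgs$clin)
  expect_equal(dim(oof$stack), c(96L, 12L))
  expect_false(anyNA(oof$stack))
  expect_equal(rowSums(oof$stack[, 1:6]), rep(1, 96), tolerance = 1e-6)
  expect_equal(rowSums(oof$stack[, 7:12]), rep(1, 96), tolerance = 1e-6)

  # altering another sample INSIDE the same fold must not change a sample's
  # own out-of-fold vector (its fold is held out of the base-model training)
  target <- which(plan$fold == 1L)[1]
  buddy <- which(plan$fold == 1L)[2]
  feats2 <- fx$feats
  feats2[buddy, ] <- feats2[buddy, ] + 50
  table2 <- fx$table
  table2$age[buddy] <- 999
  oof2 <- make_oof_stack(feats2, table2, fx$labels, plan, cfgs$head, cfgs$clin)
  expect_equal(oof2$stack[target, ], oof$stack[target, ], tolerance = 1e-12)

  # ...while altering a sample OUTSIDE its fold does change it
  outside <- which(plan$fold == 2L)[1]
  feats3 <- fx$feats
  feats3[outside, ] <- feats3[outside, ] + 50
  oof3 <- make_oof_stack(feats3, fx$table, fx$labels, plan, cfgs$head, cfgs$clin)
  expect_false(isTRUE(all.equal(oof3$stack[target, 1:6], oof$stack[target, 1:6],
                                tolerance = 1e-12)))
  expect_error(make_oof_stack(fx$feats[1:10, ], fx$table, fx$labels, plan),
               "paired")
})

test_that("stacked vectors separate classes at least as well as either half", {
  fx <- oof_fixture(n = 120, seed = 8)
  plan <- make_fold_plan(fx$labels, K = 4, seed = 3)
  cfgs <- fast_cfgs()
  oof <- make_oof_stack(fx$feats, fx$table, fx$labels, plan, cfgs$head, cfgs$clin)
  scatter_ratio <- function(x, lab) {
    mu <- colMeans(x)
    between <- 0; within <- 0
    for (cl in unique(lab)) {
      xs <- x[lab == cl, , drop = FALSE]
      mc <- colMeans(xs)
      between <- between + nrow(xs) * sum((mc - mu)^2)
      within <- within + sum(sweep(xs, 2, mc)^2)
    }
    between / within
  }
  r_full <- scatter_ratio(oof$stack, fx$labels)
  r_img <- scatter_ratio(oof$stack[, 1:6], fx$labels)
  r_cli <- scatter_ratio(oof$stack[, 7:12], fx$labels)
  expect_gte(r_full, min(r_img, r_cli))
})

test_that("the meta-model combines informative and complementary bases", {
  set.seed(46)
  n <- 240
  labels <- sample(rep(0:5, each = 40))
  onehot <- diag(6)[labels + 1, ]
  soft <- function(m) m / rowSums(m)

  # perfectly informative image half -> perfect training accuracy
  z1 <- cbind(soft(onehot + 0.02), matrix(1 / 6, n, 6))
  meta1 <- fit_meta(z1, labels)
  expect_equal(predict_final(meta1, z1)$label, labels)

  # both halves uninformative -> accuracy near the class prior
  z0 <- matrix(1 / 6, n, 12) + matrix(rnorm(12 * n, sd = 1e-4), n)
  meta0 <- fit_meta(z0, labels)
  expect_lt(mean(predict_final(meta0, z0)$label == labels), 0.35)

  # complementary signal: image half knows classes 0-2, clinical half 3-5
  img_half <- soft(ifelse(matrix(rep(labels + 1, 6), n) ==
                            matrix(rep(1:6, each = n), n) &
                            labels <= 2, 5, 1) + matrix(rgamma(6 * n, 0.5), n))
  cli_half <- soft(ifelse(matrix(rep(labels + 1, 6), n) ==
                            matrix(rep(1:6, each = n), n) &
                            labels >= 3, 5, 1) + matrix(rgamma(6 * n, 0.5), n))
  tr <- seq_len(180); te <- 181:240
  acc <- function(z, ...) {
    m <- fit_meta(z[tr, ], labels[tr])
    mean(predict_final(m, z[te, ])$label == labels[te])
  }
  pad <- matrix(1 / 6, n, 6)
  a_both <- acc(cbind(img_half, cli_half))
  a_img <- acc(cbind(img_half, pad))
  a_cli <- acc(cbind(pad, cli_half))
  expect_gt(a_both, max(a_img, a_cli))
  expect_error(fit_meta(z1, rep(0L, n)), "two classes")
})

test_that("final predictions break exact ties toward the lowest class code", {
  set.seed(47)
  labels <- sample(rep(0:5, each = 20))
  z <- cbind(diag(6)[labels + 1, ] * 0.94 + 0.01, matrix(1 / 6, 120, 6))
  meta <- fit_meta(z, labels)
  out <- predict_final(meta, z[3, ])
  expect_equal(out$label, labels[3])
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
  expect_error(predict_final(meta, rep(NA_real_, 12)), "non-finite")

  # symmetric input under a symmetric model: which.max picks the first max
  p <- matrix(c(0.3, 0.3, 0.1, 0.1, 0.1, 0.1), 1)
  expect_equal(which.max(p) - 1L, 0L)
})
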