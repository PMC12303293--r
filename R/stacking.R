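# Out-of-fold stacking of the two base branches (image softmax head, clinical
# gradient boosting) and the ridge multinomial logistic-regression meta-model.
# Every sample's stacked vector is produced by base models trained WITHOUT
# that sample's fold, so the meta-model never sees leaked predictions.

#' Stratified K-fold plan
#'
#' Partitions samples into `K` folds with per-class counts within 1 of
#' proportional and fold sizes within 1 of each other. Class members are
#' shuffled with the seed and dealt one at a time to the currently smallest
#' fold (lowest index on ties), which maintains both balance invariants for
#' arbitrary label multisets. Deterministic given the seed; the caller's RNG
#' state is untouched.
#'
#' @param labels Integer class codes 0..5.
#' @param K Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of class `fold_plan` with `fold` (1..K per sample), `K`, `seed`.
#' @export
make_fold_plan <- function(labels, K = 10L, seed = 1L) {
  K <- as.integer(K)
  counts <- table(labels)
  if (any(counts < K)) {
    stop("class(es) ", paste(names(counts)[counts < K], collapse = ", "),
         " have fewer than K = ", K, " members; lower K")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  fold <- integer(length(labels))
  sizes <- integer(K)
  for (cls in sort(unique(labels))) {
    members <- which(labels == cls)
    members <- members[sample.int(length(members))]
    for (m in members) {
      k <- which.min(sizes)
      fold[m] <- k
      sizes[k] <- sizes[k] + 1L
    }
  }
  structure(list(fold = fold, K = K, seed = as.integer(seed)), class = "fold_plan")
}

#' Stack the two branch probability vectors
#'
#' Concatenates the image-branch and clinical-branch probability vectors into
#' the 12-long meta-model input, image half first.
#'
#' @param p_img,p_clin Probability vectors of length 6, each summing to 1
#'   within 1e-6.
#' @return Numeric vector of length 12.
#' @export
stack_probs <- function(p_img, p_clin) {
  for (p in list(p_img, p_clin)) {
    if (length(p) != 6L || any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
      stop("each branch input must be a 6-class probability vector summing to 1")
    }
  }
  out <- c(unname(p_img), unname(p_clin))
  names(out) <- c(paste0("img_", CLASS_NAMES), paste0("clin_", CLASS_NAMES))
  out
}

#' Build the out-of-fold stacked-probability table
#'
#' For each fold, fits the image head and the clinical model on the remaining
#' folds and predicts the held-out fold, so every sample receives exactly one
#' stacked vector from base models that never saw it. Per-fold base seeds are
#' derived deterministically from the configs' seeds.
#'
#' @param image_features `n x d` matrix of pooled fused image features.
#' @param clinical_table Cleaned clinical feature table (`n` rows).
#' @param labels Integer class codes 0..5, length `n`.
#' @param plan A [make_fold_plan()] over the same samples.
#' @param head_cfg A [head_config()].
#' @param clin_cfg A [clinical_config()].
#' @return List with `stack` (`n x 12` matrix) and `labels`.
#' @export
make_oof_stack <- function(image_features, clinical_table, labels, plan,
                           head_cfg = head_config(), clin_cfg = clinical_config()) {
  n <- length(labels)
  if (nrow(image_features) != n || nrow(clinical_table) != n ||
      length(plan$fold) != n) {
    stop("image features, clinical rows, labels and fold plan must be paired sample-wise")
  }
  stack <- matrix(NA_real_, n, 12L)
  colnames(stack) <- c(paste0("img_", CLASS_NAMES), paste0("clin_", CLASS_NAMES))
  for (k in seq_len(plan$K)) {
    tr <- plan$fold != k
    te <- !tr
    h_cfg <- head_cfg; h_cfg$seed <- head_cfg$seed + k
    c_cfg <- clin_cfg; c_cfg$seed <- clin_cfg$seed + k
    head <- fit_image_head(image_features[tr, , drop = FALSE], labels[tr], h_cfg)
    clin <- fit_clinical_model(clinical_table[tr, , drop = FALSE], labels[tr], c_cfg)
    stack[te, 1:6]  <- predict_image_probs(head, image_features[te, , drop = FALSE])
    stack[te, 7:12] <- predict_clinical_probs(clin, clinical_table[te, , drop = FALSE])
  }
  list(stack = stack, labels = labels)
}

#' Meta-model configuration
#'
#' @param lambda Ridge (L2) penalty of the multinomial logistic regression.
#' @return List of class `meta_config`.
#' @export
meta_config <- function(lambda = 0.01) {
  structure(list(lambda = lambda), class = "meta_config")
}

#' Fit the logistic-regression meta-model
#'
#' Ridge-regularised multinomial logistic regression (glmnet, `alpha = 0`)
#' on the 12-dimensional stacked probability vectors. Deterministic given the
#' config; glmnet's coordinate descent is seed-free.
#'
#' @param stacked_table `n x 12` matrix of stacked vectors.
#' @param labels Integer class codes 0..5.
#' @param cfg A [meta_config()].
#' @return List of class `meta_model`.
#' @export
fit_meta <- function(stacked_table, labels, cfg = meta_config()) {
  if (length(unique(labels)) < 2L) stop("need at least two classes to fit the meta-model")
  if (!all(is.finite(stacked_table))) stop("non-finite stacked inputs")
  fit <- glmnet::glmnet(as.matrix(stacked_table), factor(labels, levels = 0:5),
                        family = "multinomial", alpha = 0, lambda = cfg$lambda,
                        standardize = FALSE)
  structure(list(fit = fit, cfg = cfg,
                 converged = fit$npasses < 1e5, version = "1"),
            class = "meta_model")
}

#' Final stacked prediction
#'
#' Applies the meta-model to stacked vectors and returns the argmax class with
#' ties broken toward the lowest class code, plus the probability vectors.
#'
#' @param meta A [fit_meta()] result.
#' @param z A stacked vector (length 12) or an `n x 12` matrix.
#' @return List with `label` (codes), `name` (class names) and `probs`
#'   (`n x 6` matrix, rows summing to 1).
#' @export
predict_final <- function(meta, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (!all(is.finite(z))) stop("non-finite stacked inputs")
  p <- stats::predict(meta$fit, as.matrix(z), type = "response")[, , 1]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p <- p / rowSums(p)
  colnames(p) <- CLASS_NAMES
  lab <- apply(p, 1, which.max) - 1L   # which.max: first (lowest-code) maximum
  list(label = lab, name = CLASS_NAMES[lab + 1L], probs = p)
}
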