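# Evaluation arithmetic: 6 x 6 confusion counts, one-vs-rest per-class
# PPV/recall/F1/NPV, macro (unweighted) aggregation, dataset splitting, and
# recovery of integer confusion counts from printed per-class ratios.

round_half_up <- function(x) floor(x + 0.5)

#' Confusion matrix of true vs predicted class codes
#'
#' @param y_true,y_pred Equal-length integer vectors of class codes 0..5.
#' @return 6 x 6 integer matrix; rows are the true class, columns the
#'   predicted class, in code order.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label sequences differ in length")
  if (any(c(y_true, y_pred) < 0L | c(y_true, y_pred) > 5L)) {
    stop("class codes must lie in 0..5")
  }
  cm <- matrix(0L, 6, 6, dimnames = list(true = CLASS_NAMES, pred = CLASS_NAMES))
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  cm
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Per-class PPV, recall, F1 and NPV
#'
#' One-vs-rest metrics for each of the six classes: PPV = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = their harmonic mean, NPV = TN/(TN+FN), with
#' TN computed against the total evaluated count. Ratios with a zero
#' denominator are flagged `NA` with a warning — never silently zeroed.
#'
#' @param cm 6 x 6 confusion matrix (rows true, columns predicted).
#' @param n_total Total evaluated samples; defaults to `sum(cm)` but can be
#'   threaded explicitly when the matrix is partial.
#' @return Data frame of class `metrics_report`: one row per class with
#'   columns `class, tp, fp, fn, tn, ppv, recall, f1, npv`.
#' @export
per_class_metrics <- function(cm, n_total = sum(cm)) {
  if (any(cm < 0)) stop("negative counts in confusion matrix")
  rows <- lapply(seq_len(6), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- n_total - tp - fp - fn
    ppv <- safe_ratio(tp, tp + fp)
    rec <- safe_ratio(tp, tp + fn)
    f1 <- if (is.na(ppv) || is.na(rec) || (ppv + rec) == 0) NA_real_ else 2 * ppv * rec / (ppv + rec)
    npv <- safe_ratio(tn, tn + fn)
    data.frame(class = CLASS_NAMES[i], tp = tp, fp = fp, fn = fn, tn = tn,
               ppv = ppv, recall = rec, f1 = f1, npv = npv)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out[, c("ppv", "recall", "f1", "npv")])) {
    warning("undefined per-class metric(s) flagged NA (zero denominator)")
  }
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Macro (unweighted) averages of per-class metrics
#'
#' Unweighted mean of the six per-class PPV, recall and F1 values — the
#' aggregation whose arithmetic ties the per-class table to the overall
#' metrics row. Errors if any per-class value is undefined.
#'
#' @param report A [per_class_metrics()] data frame (or any data frame with
#'   `ppv`, `recall`, `f1` columns, e.g. a printed per-class table).
#' @return Named list `ppv`, `recall`, `f1`.
#' @export
macro_average <- function(report) {
  if (anyNA(report[, c("ppv", "recall", "f1")])) {
    stop("cannot macro-average: undefined per-class metric present")
  }
  list(ppv = mean(report$ppv), recall = mean(report$recall), f1 = mean(report$f1))
}

#' Accuracy from a confusion matrix
#'
#' @param cm Confusion matrix.
#' @return `trace / total`.
#' @export
accuracy_from_cm <- function(cm) sum(diag(cm)) / sum(cm)

#' Recover minimal integer confusion counts from printed ratios
#'
#' Given a per-class PPV and recall printed to `digits` decimals and the total
#' evaluated count, finds the smallest TP with non-negative integer FP and FN
#' such that `TP/(TP+FP)` and `TP/(TP+FN)` round to the printed values; TN is
#' the remainder. Useful to reconstruct count-level results (e.g. NPV) that a
#' report omits.
#'
#' @param ppv,recall Printed values in (0, 1].
#' @param n_total Total evaluated count.
#' @param digits Printed precision (default 6).
#' @return List `tp`, `fp`, `fn`, `tn`, `npv`.
#' @export
recover_confusion_counts <- function(ppv, recall, n_total, digits = 6) {
  stopifnot(ppv > 0, recall > 0, ppv <= 1, recall <= 1)
  for (tp in seq_len(n_total)) {
    fp <- round_half_up(tp / ppv - tp)
    fn <- round_half_up(tp / recall - tp)
    if (fp < 0 || fn < 0) next
    ok_p <- round(tp / (tp + fp), digits) == round(ppv, digits)
    ok_r <- round(tp / (tp + fn), digits) == round(recall, digits)
    tn <- n_total - tp - fp - fn
    if (ok_p && ok_r && tn >= 0) {
      return(list(tp = tp, fp = fp, fn = fn, tn = tn, npv = tn / (tn + fn)))
    }
  }
  stop("no integer counts reproduce the printed ratios at n_total = ", n_total)
}

# Largest-remainder allocation of `size` picks across classes, proportional to
# class counts; guarantees per-class picks within 1 of exact proportionality.
stratified_take <- function(labels, idx, size, rng_sample) {
  cls <- split(idx, labels[idx])
  exact <- vapply(cls, length, 1L) * size / length(idx)
  base <- floor(exact)
  rem <- size - sum(base)
  frac_order <- order(exact - base, decreasing = TRUE)
  base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1L
  unlist(lapply(seq_along(cls), function(i) {
    members <- rng_sample(cls[[i]])
    members[seq_len(base[i])]
  }), use.names = FALSE)
}

#' Train/validation/test split plan
#'
#' Splits `n` samples into test = `round-half-up(test_frac * n)` and train =
#' the remainder (so 2298 samples at 80/20 give 1838 train, 460 test), then
#' carves `val_frac` of the training set out as a validation set. With
#' `stratify = TRUE` both carve-outs keep per-class counts within one sample
#' of proportional. Deterministic given the seed.
#'
#' @param n_samples Number of samples.
#' @param labels Class codes (required when `stratify = TRUE`).
#' @param test_frac Test fraction (default 0.2).
#' @param val_frac Fraction of the *training* set used for validation.
#' @param seed Integer seed.
#' @param stratify Stratify both splits by class.
#' @return List of class `split_plan` with disjoint index vectors `train`,
#'   `validation`, `test` whose union is `1..n`.
#' @export
split_dataset <- function(n_samples, labels = NULL, test_frac = 0.2,
                          val_frac = 0.2, seed = 1L, stratify = TRUE) {
  if (test_frac <= 0 || test_frac >= 1 || val_frac < 0 || val_frac >= 1) {
    stop("invalid split ratios")
  }
  if (stratify && is.null(labels)) stop("stratified split needs labels")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  rng_sample <- function(x) if (length(x) == 1L) x else sample(x)
  all_idx <- seq_len(n_samples)
  n_test <- round_half_up(test_frac * n_samples)
  test <- if (stratify) {
    stratified_take(labels, all_idx, n_test, rng_sample)
  } else {
    sort(sample(all_idx, n_test))
  }
  train_full <- setdiff(all_idx, test)
  n_val <- round_half_up(val_frac * length(train_full))
  validation <- if (n_val == 0L) integer(0) else if (stratify) {
    stratified_take(labels, train_full, n_val, rng_sample)
  } else {
    sort(sample(train_full, n_val))
  }
  train <- setdiff(train_full, validation)
  structure(list(train = sort(train), validation = sort(validation),
                 test = sort(test), seed = as.integer(seed),
                 stratify = stratify), class = "split_plan")
}

#' Write a metrics report and its macro row as CSV
#'
#' @param report A [per_class_metrics()] result.
#' @param path Output CSV path; a companion `*_macro.csv` is written when the
#'   macro average is defined.
#' @export
write_metrics_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  macro <- tryCatch(macro_average(report), error = function(e) NULL)
  if (!is.null(macro)) {
    utils::write.csv(as.data.frame(macro),
                     sub("\\.csv$", "_macro.csv", path), row.names = FALSE)
  }
  invisible(path)
}
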