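# Clinical-metadata branch: cleaning of the PAD-UFES-20-schema table and a
# gradient-boosted six-class model (xgboost) that consumes missing values
# natively — no imputation anywhere.

# Canonical column sets of the metadata schema (lower-case header names).
META_ID_COLS <- c("patient_id", "lesion_id", "img_id")
META_BOOL_COLS <- c("smoke", "drink", "pesticide", "skin_cancer_history",
                    "cancer_history", "has_piped_water", "has_sewage_system",
                    "itch", "grew", "hurt", "changed", "bled", "elevation",
                    "biopsied")
META_CAT_COLS <- c("background_father", "background_mother", "gender", "region")
META_NUM_COLS <- c("age", "fitzpatrick", "diameter_1", "diameter_2")
# Dropped before modelling: identifiers carry no clinical signal, `diagnostic`
# is the label, and `region` (the anatomical macro-region, the schema's "area")
# is omitted so the model is not anchored to body location.
META_DROP_COLS <- c(META_ID_COLS, "diagnostic", "region")

#' Canonical metadata column order
#'
#' @return Character vector of the 26 schema column names.
#' @export
metadata_columns <- function() {
  c(META_ID_COLS, "smoke", "drink", "background_father", "background_mother",
    "age", "pesticide", "gender", "skin_cancer_history", "cancer_history",
    "has_piped_water", "has_sewage_system", "fitzpatrick", "region",
    "diameter_1", "diameter_2", "diagnostic", "itch", "grew", "hurt",
    "changed", "bled", "elevation", "biopsied")
}

encode_bool <- function(x) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.numeric(x)) return(as.numeric(x))
  v <- toupper(trimws(as.character(x)))
  out <- rep(NA_real_, length(v))
  out[v %in% c("TRUE", "T", "1", "YES")] <- 1
  out[v %in% c("FALSE", "F", "0", "NO")] <- 0
  out
}

#' Clean a clinical-metadata table for modelling
#'
#' Drops the identifier columns, the diagnostic label and the anatomical
#' region; encodes booleans as 0/1 and categoricals as ordinal integer codes
#' (gradient-boosted trees are insensitive to the ordering); keeps every
#' missing value as `NA` — cleaning never imputes. Labels are returned as
#' integer codes via [encode_class()].
#'
#' @param records Data frame following the 26-column metadata schema (header
#'   names as in [metadata_columns()], case-insensitive). Empty strings are
#'   read as missing.
#' @param encodings Optional list of category level maps from a previous call,
#'   to encode new data consistently with a training table.
#' @return List with `table` (numeric feature data frame, one row per record,
#'   attribute `"encodings"`), and `labels` (codes 0..5, or `NULL` if the
#'   input has no `diagnostic` column).
#' @export
clean_metadata <- function(records, encodings = NULL) {
  names(records) <- tolower(names(records))
  if (!"img_id" %in% names(records)) stop("metadata must carry an img_id column")
  if (anyDuplicated(records$img_id)) stop("duplicate img_id in metadata")
  records[records == ""] <- NA

  labels <- NULL
  if ("diagnostic" %in% names(records)) labels <- encode_class(records$diagnostic)

  keep <- setdiff(intersect(metadata_columns(), names(records)), META_DROP_COLS)
  out <- list()
  enc_out <- list()
  for (col in keep) {
    v <- records[[col]]
    if (col %in% META_BOOL_COLS) {
      out[[col]] <- encode_bool(v)
    } else if (col %in% META_NUM_COLS) {
      out[[col]] <- suppressWarnings(as.numeric(v))
    } else { # categorical
      v <- as.character(v)
      levs <- if (!is.null(encodings) && !is.null(encodings[[col]])) {
        encodings[[col]]
      } else {
        sort(unique(v[!is.na(v)]))
      }
      enc_out[[col]] <- levs
      out[[col]] <- as.numeric(match(v, levs))   # unseen level -> NA
    }
  }
  tab <- as.data.frame(out)[, keep, drop = FALSE]
  attr(tab, "encodings") <- if (is.null(encodings)) enc_out else encodings
  attr(tab, "img_id") <- records$img_id
  list(table = tab, labels = labels)
}

#' Clinical-model configuration
#'
#' Gradient-boosting hyperparameters: 300 trees of depth 6, learning rate 0.1,
#' multiclass softmax objective, single-threaded for determinism.
#'
#' @param nrounds,max_depth,eta Boosting rounds, tree depth, learning rate.
#' @param seed Seed for xgboost's internal randomness.
#' @return List of class `clinical_config`.
#' @export
clinical_config <- function(nrounds = 300L, max_depth = 6L, eta = 0.1, seed = 1L) {
  structure(list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
                 eta = eta, seed = as.integer(seed)), class = "clinical_config")
}

#' Fit the gradient-boosted clinical model
#'
#' Trains an xgboost multiclass model on the cleaned feature table. Missing
#' entries are passed through as `NA` and routed by the trees' default
#' directions — no pre-imputation. Deterministic for a fixed seed and config.
#'
#' @param table Cleaned feature data frame from [clean_metadata()].
#' @param labels Integer class codes 0..5.
#' @param cfg A [clinical_config()].
#' @return List of class `clinical_model`.
#' @export
fit_clinical_model <- function(table, labels, cfg = clinical_config()) {
  if (nrow(table) == 0L) stop("empty feature table")
  if (nrow(table) != length(labels)) stop("table and labels disagree in length")
  if (length(unique(labels)) < 2L) stop("need at least two classes to fit")
  x <- as.matrix(table)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = labels)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = 6L,
                  max_depth = cfg$max_depth, eta = cfg$eta,
                  seed = cfg$seed, nthread = 1L),
    data = dtrain, nrounds = cfg$nrounds, verbose = 0
  )
  structure(list(booster = booster, feature_names = colnames(table),
                 encodings = attr(table, "encodings"), cfg = cfg, version = "1"),
            class = "clinical_model")
}

#' Predict clinical-branch probabilities
#'
#' @param model A [fit_clinical_model()] result.
#' @param rows Cleaned feature rows with the training schema (data frame or
#'   matrix); all-missing rows are valid.
#' @return `n x 6` matrix of probabilities, rows summing to 1.
#' @export
predict_clinical_probs <- function(model, rows) {
  if (is.null(dim(rows))) rows <- as.data.frame(as.list(rows))
  if (!identical(colnames(rows), model$feature_names)) {
    if (!all(model$feature_names %in% colnames(rows))) {
      stop("feature schema mismatch: expected columns ",
           paste(model$feature_names, collapse = ", "))
    }
    rows <- rows[, model$feature_names, drop = FALSE]
  }
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(as.matrix(rows)))
  p <- matrix(p, ncol = 6L)
  colnames(p) <- CLASS_NAMES
  p
}
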