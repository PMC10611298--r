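# Preprocessing: missing-data handling, one-hot encoding, the 80:20
# split, train-statistics min-max normalization and balanced class
# weights.

#' Default 10-feature input set
#'
#' The commonly used UCI heart-disease subset: age, sex, cp, trestbps,
#' chol, fbs, restecg, thalach, exang, oldpeak.
#'
#' @return character vector of 10 feature names.
#' @export
default_features <- function() {
  c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg", "thalach",
    "exang", "oldpeak")
}

col_mode <- function(v) {
  tab <- sort(table(v), decreasing = TRUE)
  as.numeric(names(tab)[1])
}

#' Handle missing values
#'
#' Default policy: median imputation for numeric columns, mode for
#' categorical ones; `"drop"` removes every row containing a missing
#' value instead. Deterministic.
#'
#' @param ds data frame (heart schema or any numeric-coded table).
#' @param policy `"impute"` (default) or `"drop"`.
#' @param categorical names of columns imputed by mode.
#' @return data frame with no missing values.
#' @export
handle_missing <- function(ds, policy = c("impute", "drop"),
                           categorical = HEART_CATEGORICAL) {
  policy <- match.arg(policy)
  all_missing <- vapply(ds, function(v) all(is.na(v)), TRUE)
  if (any(all_missing)) {
    stop(sprintf("column '%s' is entirely missing",
                 names(ds)[all_missing][1]))
  }
  if (policy == "drop") {
    keep <- !apply(is.na(ds), 1, any)
    return(ds[keep, , drop = FALSE])
  }
  for (cn in names(ds)) {
    miss <- is.na(ds[[cn]])
    if (!any(miss)) next
    fill <- if (cn %in% categorical) col_mode(ds[[cn]][!miss]) else {
      median(ds[[cn]][!miss])
    }
    ds[[cn]][miss] <- fill
  }
  ds
}

#' One-hot encode categorical columns
#'
#' Each categorical column of cardinality `c` expands to `c` indicator
#' columns named `col_level`; exactly one indicator is 1 per row per
#' source column. Level sets are learned from the data unless given
#' (pass the training levels to transform a test split); an unseen level
#' at transform time is an error by default.
#'
#' @param ds data frame.
#' @param columns categorical column names present in `ds`.
#' @param levels optional named list of level vectors from a previous call.
#' @param unseen `"error"` (default) or `"zero"` (emit an all-zero row
#'   block for unseen levels).
#' @return encoded data frame with an `onehot_levels` attribute.
#' @export
one_hot_encode <- function(ds, columns = intersect(HEART_CATEGORICAL,
                                                   names(ds)),
                           levels = NULL, unseen = c("error", "zero")) {
  unseen <- match.arg(unseen)
  learned <- list()
  out <- ds
  for (cn in columns) {
    lv <- if (!is.null(levels)) levels[[cn]] else sort(unique(ds[[cn]]))
    learned[[cn]] <- lv
    extra <- setdiff(unique(ds[[cn]]), lv)
    if (length(extra) && unseen == "error") {
      stop(sprintf("unseen level %s in column '%s'", extra[1], cn))
    }
    block <- vapply(lv, function(l) as.integer(ds[[cn]] == l),
                    integer(nrow(ds)))
    block <- matrix(block, nrow = nrow(ds),
                    dimnames = list(NULL, paste(cn, lv, sep = "_")))
    out[[cn]] <- NULL
    out <- cbind(out, as.data.frame(block))
  }
  attr(out, "onehot_levels") <- learned
  out
}

#' Split a dataset 80:20
#'
#' `|train| = round(ratio * n)`, train and test disjoint with union the
#' full data; reproducible under `seed`; stratified on `target` by
#' default (per-class allocations balanced to the total by largest
#' fractional part).
#'
#' @param ds data frame.
#' @param ratio train fraction (default 0.8).
#' @param seed integer seed (default 0).
#' @param stratified stratify on the target column (default `TRUE`).
#' @param target label column name (default `"disease"`).
#' @return list with `train` and `test` data frames.
#' @export
split_dataset <- function(ds, ratio = 0.8, seed = 0, stratified = TRUE,
                          target = "disease") {
  n <- nrow(ds)
  if (n < 5) stop("need at least 5 rows to split")
  n_train <- round_half_up(ratio * n)
  if (stratified && !target %in% names(ds)) {
    warning("target column absent; falling back to a simple random split")
    stratified <- FALSE
  }
  idx <- with_seed(seed, {
    if (!stratified) {
      sample(n, n_train)
    } else {
      y <- ds[[target]]
      classes <- unique(y)
      want <- ratio * table(y)[as.character(classes)]
      base <- floor(want)
      rem <- n_train - sum(base)
      # distribute the remainder by largest fractional part
      frac_order <- order(want - base, decreasing = TRUE)
      take <- base
      if (rem > 0) take[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
      unlist(lapply(seq_along(classes), function(ci) {
        rows <- which(y == classes[ci])
        sample(rows, min(take[ci], length(rows)))
      }), use.names = FALSE)
    }
  })
  list(train = ds[sort(idx), , drop = FALSE],
       test = ds[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Min-max normalization by training statistics
#'
#' Training columns are rescaled to `[0, 1]` by their own min/max; the
#' test split is rescaled by the TRAIN min/max (an affine map fixed by
#' train statistics only) and may therefore fall outside `[0, 1]` — no
#' clipping. A constant training column maps to all zeros with a warning.
#'
#' @param train,test data frames with identical columns.
#' @param columns columns to normalize (default: all numeric columns
#'   except `disease` and `num`).
#' @return list with `train`, `test` and the `bounds` (per-column min and
#'   max) used.
#' @export
min_max_normalize <- function(train, test = NULL,
                              columns = setdiff(names(train),
                                                c("disease", "num"))) {
  bounds <- lapply(columns, function(cn) {
    c(min = min(train[[cn]]), max = max(train[[cn]]))
  })
  names(bounds) <- columns
  rescale <- function(df) {
    for (cn in columns) {
      b <- bounds[[cn]]
      if (b["max"] == b["min"]) {
        df[[cn]] <- rep(0, nrow(df))
      } else {
        df[[cn]] <- (df[[cn]] - b["min"]) / (b["max"] - b["min"])
      }
    }
    df
  }
  const <- vapply(bounds, function(b) b["max"] == b["min"], TRUE)
  if (any(const)) {
    warning(sprintf("constant training column '%s' normalized to zeros",
                    columns[const][1]))
  }
  out <- list(train = rescale(train),
              test = if (!is.null(test)) rescale(test),
              bounds = bounds)
  out
}

#' Balanced class weights
#'
#' `weight_c = n_samples / (n_classes * count_c)` — weights inversely
#' proportional to the class frequencies, so that
#' `sum_c weight_c * count_c = n_samples` holds exactly.
#'
#' @param labels binary 0/1 label vector with both classes present.
#' @return object of class `class_weights`: named numeric vector
#'   (`"0"`, `"1"`) with a `counts` attribute.
#' @export
#' @examples
#' compute_class_weights(rep(c(0, 1), c(33, 28)))  # 0.9242424 1.0892857
compute_class_weights <- function(labels) {
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0)) stop("both classes must be present")
  n <- sum(counts)
  w <- n / (2 * as.numeric(counts))
  names(w) <- names(counts)
  structure(w, counts = as.numeric(counts), class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf("class weights: (%.8f, %.8f) for counts (%d, %d)\n",
              x[1], x[2], attr(x, "counts")[1], attr(x, "counts")[2]))
  invisible(x)
}

# expand class weights to one weight per observation
observation_weights <- function(labels, cw) {
  as.numeric(cw[as.character(labels)])
}

#' Full preprocessing pipeline for a heart-disease table
#'
#' Missing-data handling, target binarization, 10-feature selection,
#' one-hot encoding of the categorical features (levels learned on the
#' full table so train and test share columns), stratified 80:20 split,
#' train-statistics min-max normalization and balanced class weights.
#'
#' @param ds raw heart-schema data frame.
#' @param features input features (default [default_features()]).
#' @param missing_policy see [handle_missing].
#' @param ratio,seed,stratified see [split_dataset].
#' @return list with `train`, `test` (feature matrix `x` + label `y`
#'   each), `weights` (a `class_weights`), `bounds`, `onehot_levels`,
#'   `features` (encoded column names).
#' @export
preprocess_heart <- function(ds, features = default_features(),
                             missing_policy = "impute", ratio = 0.8,
                             seed = 0, stratified = TRUE) {
  ds <- handle_missing(ds, missing_policy)
  ds <- binarize_target(ds)
  keep <- c(features, "disease")
  ds <- ds[, keep, drop = FALSE]
  cats <- intersect(HEART_CATEGORICAL, features)
  enc <- one_hot_encode(ds, columns = cats)
  lv <- attr(enc, "onehot_levels")
  sp <- split_dataset(enc, ratio = ratio, seed = seed,
                      stratified = stratified)
  cols <- setdiff(names(enc), "disease")
  nm <- min_max_normalize(sp$train, sp$test, columns = cols)
  weights <- compute_class_weights(nm$train$disease)
  list(
    train = list(x = as.matrix(nm$train[, cols, drop = FALSE]),
                 y = nm$train$disease),
    test = list(x = as.matrix(nm$test[, cols, drop = FALSE]),
                y = nm$test$disease),
    weights = weights, bounds = nm$bounds, onehot_levels = lv,
    features = cols
  )
}
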