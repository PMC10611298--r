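# The four plaintext classifiers (defaults as tuned for the federated
# prime servers) and the metric suite.

default_hyper <- function(kind) {
  switch(kind,
    logistic = list(max_iter = 1000),
    linear_svc = list(kernel = "linear", C = 1, max_iter = 1000,
                      probability = TRUE),
    decision_tree = list(max_depth = 10, min_samples_leaf = 10,
                         min_samples_split = 100, max_features = NULL),
    xgboost = list(n_estimators = 10, learning_rate = 0.1,
                   max_depth = 3, booster = "gbtree")
  )
}

resolve_kind <- function(kind) {
  aliases <- c(
    logistic = "logistic", "linear_regression" = "logistic",
    lr = "logistic",
    linear_svc = "linear_svc", svm = "linear_svc", svc = "linear_svc",
    decision_tree = "decision_tree", tree = "decision_tree",
    dt = "decision_tree",
    xgboost = "xgboost", gbt = "xgboost", xgb = "xgboost"
  )
  k <- aliases[tolower(kind)]
  if (is.na(k)) stop(sprintf("unknown classifier kind '%s'", kind))
  unname(k)
}

#' Fit one of the four supported classifiers
#'
#' All models are trained with balanced class weights on the
#' preprocessed, min-max-normalized feature matrix. Defaults:
#' logistic regression (weighted cross-entropy, iteration cap 1000;
#' `"linear_regression"` is accepted as an alias since the linear model
#' is evaluated as a thresholded classifier), linear SVC (libsvm, C = 1,
#' linear kernel), decision tree (weighted Gini, `max_depth` 10,
#' `min_samples_leaf` 10, `min_samples_split` 100) and gradient-boosted
#' trees (10 estimators, learning rate 0.1, depth 3).
#'
#' @param kind `"logistic"`, `"linear_svc"`, `"decision_tree"`,
#'   `"xgboost"` or an alias (`"linear_regression"`, `"svm"`, `"tree"`,
#'   `"gbt"`).
#' @param x numeric feature matrix.
#' @param y binary 0/1 labels (both classes required).
#' @param weights a `class_weights` object (default: computed from `y`).
#' @param hyper named list overriding the kind's default hyperparameters.
#' @param seed integer seed (default 0).
#' @return object of class `fhecare_classifier`.
#' @export
fit_classifier <- function(kind, x, y, weights = NULL, hyper = list(),
                           seed = 0) {
  kind <- resolve_kind(kind)
  x <- as.matrix(x)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (is.null(weights)) weights <- compute_class_weights(y)
  hp <- utils::modifyList(default_hyper(kind), hyper)
  ow <- observation_weights(y, weights)
  fit <- with_seed(seed, switch(kind,
    logistic = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      suppressWarnings(glm(.y ~ ., data = df, family = binomial(),
                           weights = ow,
                           control = glm.control(maxit = hp$max_iter)))
    },
    linear_svc = {
      cw <- c("0" = unname(weights["0"]), "1" = unname(weights["1"]))
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = hp$kernel,
                 cost = hp$C, class.weights = cw, scale = FALSE,
                 probability = hp$probability)
    },
    decision_tree = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = df, weights = ow, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(
                     maxdepth = hp$max_depth,
                     minbucket = hp$min_samples_leaf,
                     minsplit = hp$min_samples_split, cp = 0,
                     xval = 0))
    },
    xgboost = {
      xgboost::xgboost(x, factor(y, levels = c(0, 1)), weights = ow,
                       nrounds = hp$n_estimators,
                       learning_rate = hp$learning_rate,
                       max_depth = hp$max_depth, booster = hp$booster,
                       objective = "binary:logistic", nthreads = 1,
                       seed = seed, verbosity = 0)
    }
  ))
  structure(list(kind = kind, fit = fit, hyper = hp, weights = weights,
                 features = colnames(x), seed = seed),
            class = "fhecare_classifier")
}

#' @export
print.fhecare_classifier <- function(x, ...) {
  cat(sprintf("<fhecare_classifier %s, %d features>\n", x$kind,
              length(x$features)))
  invisible(x)
}

#' Predict scores or labels from a fitted classifier
#'
#' @param object an `fhecare_classifier`.
#' @param newdata numeric feature matrix.
#' @param type `"label"` (threshold 0.5 on the score, default) or
#'   `"score"` (class-1 probability).
#' @param ... unused.
#' @return integer labels or numeric scores.
#' @export
predict.fhecare_classifier <- function(object, newdata,
                                       type = c("label", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  score <- switch(object$kind,
    logistic = {
      df <- data.frame(newdata, check.names = FALSE)
      as.numeric(predict(object$fit, newdata = df, type = "response"))
    },
    linear_svc = {
      pr <- predict(object$fit, newdata, probability = TRUE)
      pm <- attr(pr, "probabilities")
      if (!is.null(pm) && "1" %in% colnames(pm)) {
        as.numeric(pm[, "1"])
      } else {
        # decision values fall back to a monotone score
        dv <- attr(predict(object$fit, newdata, decision.values = TRUE),
                   "decision.values")
        plogis(as.numeric(dv) * if (colnames(dv)[1] == "0/1") -1 else 1)
      }
    },
    decision_tree = {
      df <- data.frame(newdata, check.names = FALSE)
      as.numeric(predict(object$fit, newdata = df, type = "prob")[, "1"])
    },
    xgboost = as.numeric(predict(object$fit, newdata))
  )
  if (type == "score") score else as.integer(score >= 0.5)
}

#' Coefficients of the linear decision function
#'
#' For logistic models: the weight vector and intercept on the
#' preprocessed feature scale, the inputs to [quantize_linear_model].
#'
#' @param object a logistic `fhecare_classifier`.
#' @param ... unused.
#' @return list with `weights` and `bias`.
#' @export
coef.fhecare_classifier <- function(object, ...) {
  if (object$kind != "logistic") {
    stop("linear coefficients are only available for logistic models")
  }
  cf <- coef(object$fit)
  list(weights = unname(cf[-1]), bias = unname(cf[1]))
}

#' AUROC by the midrank statistic
#'
#' The concordant-pair fraction `P(score_pos > score_neg)` computed from
#' average ranks (ties counted half).
#'
#' @param y_true binary 0/1 labels.
#' @param y_score numeric scores.
#' @return AUROC in `[0, 1]`, or `NA` (with a warning) when only one
#'   class is present.
#' @export
auroc <- function(y_true, y_score) {
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(y_score, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metric suite
#'
#' Precision, recall, F1, accuracy, AUROC (midrank) and the confusion
#' counts, with positive class 1.
#'
#' @param y_true binary labels.
#' @param y_pred binary predictions.
#' @param y_score optional scores for AUROC.
#' @return object of class `metrics_report`.
#' @export
compute_metrics <- function(y_true, y_pred, y_score = NULL) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  auc <- if (!is.null(y_score)) auroc(y_true, y_score) else NA_real_
  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = (tp + tn) / length(y_true), auroc = auc,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%-10s %-7s %-8s %-9s %-6s\n", "Precision", "Recall",
              "F1-Score", "Accuracy", "AUROC"))
  cat(sprintf("%-10.3f %-7.3f %-8.3f %-9.3f %-6s\n", x$precision,
              x$recall, x$f1, x$accuracy,
              ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc))))
  invisible(x)
}
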