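# Affine per-feature quantization of clinical records onto the small
# integer message space that the encrypted evaluation works over.

#' Calibrate a quantization scheme on training features
#'
#' Per-feature affine quantization: value `x` maps to
#' `round((x - min) / scale)` with `scale = (max - min) / (2^bits - 1)`,
#' so the calibrated min maps to level 0 and the calibrated max to
#' `2^bits - 1`. Out-of-range values at transform time are clamped.
#' The headroom bound is the largest absolute integer score an encrypted
#' accumulator may reach: blind rotation resolves `2N` phase slots, so
#' scores must stay within `(-N, N)`.
#'
#' @param X numeric matrix or data frame of training features (one column
#'   per feature).
#' @param bits integer precision per value (default 3).
#' @param params [fhe_params] used for encrypted evaluation (sets the
#'   headroom `N - 1`).
#' @return object of class `quantization_scheme` with fields `bits`,
#'   `mins`, `scales`, `levels`, `headroom`, `slots`, `features`.
#' @export
quantization_scheme <- function(X, bits = 3, params = fhe_params("TOY")) {
  X <- as.matrix(X)
  stopifnot(bits >= 1)
  levels <- 2^bits - 1
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  scales <- (maxs - mins) / levels
  scales[scales == 0] <- 1 # constant feature: everything maps to level 0
  structure(list(bits = as.integer(bits), mins = mins, scales = scales,
                 levels = levels, headroom = params$N - 1L,
                 slots = 2L * params$N,
                 features = colnames(X)),
            class = "quantization_scheme")
}

#' Quantize a record onto integer levels
#'
#' @param record numeric vector (one value per calibrated feature).
#' @param scheme a [quantization_scheme].
#' @return integer vector of levels in `0 .. 2^bits - 1`; values outside
#'   the calibrated range are clamped (with a warning).
#' @export
quantize_record <- function(record, scheme) {
  if (length(record) != length(scheme$mins)) {
    stop("record arity does not match the quantization scheme")
  }
  q <- round_half_up((record - scheme$mins) / scheme$scales)
  out_of_range <- q < 0 | q > scheme$levels
  if (any(out_of_range)) {
    warning(sprintf("%d value(s) outside the calibrated range were clamped",
                    sum(out_of_range)))
  }
  as.integer(pmin(pmax(q, 0), scheme$levels))
}

#' Invert quantization
#'
#' @param q integer levels.
#' @param scheme a [quantization_scheme].
#' @return numeric values `min + q * scale`; the quantization error of
#'   `dequantize(quantize(x))` is at most `scale/2` for in-range `x`.
#' @export
dequantize <- function(q, scheme) scheme$mins + q * scheme$scales

# Jointly rescale float weights to integers so the accumulated integer
# score stays within the headroom for every representable input.
scale_weights_to_int <- function(alpha, beta, levels, headroom) {
  mass <- sum(abs(alpha)) * levels + abs(beta)
  if (mass == 0) {
    return(list(w = as.integer(numeric(length(alpha))), b = 0L, lambda = 0))
  }
  lambda <- headroom / mass
  repeat {
    w <- round_half_up(lambda * alpha)
    b <- round_half_up(lambda * beta)
    if (sum(abs(w)) * levels + abs(b) <= headroom) break
    lambda <- lambda * 0.95
  }
  list(w = as.integer(w), b = as.integer(b), lambda = lambda)
}

#' Quantize a linear/logistic classifier for encrypted evaluation
#'
#' Folds the float decision function `w . x + b` (on the preprocessed
#' feature scale; the 0.5 probability threshold of a logistic model
#' corresponds to `w . x + b >= 0`) into integer weights over quantization
#' levels, jointly scaled so that `|score| <= headroom` for every
#' representable input.
#'
#' @param weights float weight vector on the calibrated feature scale.
#' @param bias float intercept.
#' @param scheme a [quantization_scheme].
#' @param link `"logistic"` (score is a logit) or `"identity"`.
#' @return object of class `quantized_linear` with integer `weights`,
#'   `bias`, the scale factor `lambda`, and the scheme.
#' @export
quantize_linear_model <- function(weights, bias, scheme,
                                  link = c("logistic", "identity")) {
  link <- match.arg(link)
  stopifnot(length(weights) == length(scheme$mins))
  alpha <- weights * scheme$scales
  beta <- bias + sum(weights * scheme$mins)
  si <- scale_weights_to_int(alpha, beta, scheme$levels, scheme$headroom)
  structure(list(weights = si$w, bias = si$b, lambda = si$lambda,
                 link = link, scheme = scheme),
            class = "quantized_linear")
}

#' @export
print.quantized_linear <- function(x, ...) {
  cat(sprintf("<quantized_linear %d features, headroom %d>\n",
              length(x$weights), x$scheme$headroom))
  invisible(x)
}

#' Predict from a quantized linear model (plaintext reference path)
#'
#' @param object a `quantized_linear`.
#' @param newdata integer matrix of quantized records (rows) or a single
#'   integer vector.
#' @param type `"label"` (default) or `"score"` (the integer score).
#' @param ... unused.
#' @return integer labels (`score >= 0`) or integer scores.
#' @export
predict.quantized_linear <- function(object, newdata,
                                     type = c("label", "score"), ...) {
  type <- match.arg(type)
  Q <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  score <- as.vector(Q %*% object$weights) + object$bias
  if (type == "score") score else as.integer(score >= 0)
}

# ---- quantized decision trees (exhaustive weighted-Gini CART on integer
# features; depth-limited so the encrypted one-hot path evaluation stays
# desk-scale) ----

tree_leaf <- function(label, score = NULL) {
  list(leaf = TRUE, label = as.integer(label),
       score = if (is.null(score)) as.integer(label) else as.integer(score))
}

tree_node <- function(feature, theta, left, right) {
  list(leaf = FALSE, feature = as.integer(feature), theta = as.integer(theta),
       left = left, right = right)
}

weighted_gini <- function(y, w) {
  tw <- sum(w)
  if (tw == 0) return(0)
  p <- sum(w[y == 1]) / tw
  2 * p * (1 - p)
}

best_split <- function(Q, y, w) {
  n <- nrow(Q)
  base <- weighted_gini(y, w) * sum(w)
  best <- NULL
  for (f in seq_len(ncol(Q))) {
    vals <- sort(unique(Q[, f]))
    if (length(vals) < 2) next
    for (theta in vals[-length(vals)]) {
      left <- Q[, f] <= theta
      gain <- base - weighted_gini(y[left], w[left]) * sum(w[left]) -
        weighted_gini(y[!left], w[!left]) * sum(w[!left])
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(feature = f, theta = theta, gain = gain)
      }
    }
  }
  best
}

grow_tree <- function(Q, y, w, depth) {
  maj <- as.integer(sum(w[y == 1]) >= sum(w) / 2)
  if (depth == 0 || length(unique(y)) < 2) return(tree_leaf(maj))
  sp <- best_split(Q, y, w)
  if (is.null(sp) || sp$gain <= 1e-12) return(tree_leaf(maj))
  left <- Q[, sp$feature] <= sp$theta
  tree_node(sp$feature, sp$theta,
            grow_tree(Q[left, , drop = FALSE], y[left], w[left], depth - 1),
            grow_tree(Q[!left, , drop = FALSE], y[!left], w[!left], depth - 1))
}

#' Fit a depth-limited decision tree on quantized features
#'
#' Exhaustive weighted-Gini CART over integer thresholds (`x <= theta`
#' goes left). Integer thresholds make the plaintext reference prediction
#' and the encrypted comparison circuit agree exactly.
#'
#' @param Q integer matrix of quantized records.
#' @param y binary labels (0/1).
#' @param weights per-observation weights (e.g. expanded class weights);
#'   default 1.
#' @param depth maximum depth (default 3, the encrypted-evaluation limit).
#' @param scheme the [quantization_scheme] the features live on.
#' @return object of class `quantized_tree`.
#' @export
fit_quantized_tree <- function(Q, y, weights = NULL, depth = 3,
                               scheme = NULL) {
  Q <- as.matrix(Q)
  if (is.null(weights)) weights <- rep(1, nrow(Q))
  stopifnot(depth >= 0, nrow(Q) == length(y))
  root <- grow_tree(Q, as.integer(y), weights, depth)
  structure(list(root = root, depth = depth, n_features = ncol(Q),
                 scheme = scheme),
            class = "quantized_tree")
}

tree_depth <- function(node) {
  if (node$leaf) 0L else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' @export
print.quantized_tree <- function(x, ...) {
  cat(sprintf("<quantized_tree depth=%d features=%d>\n",
              tree_depth(x$root), x$n_features))
  invisible(x)
}

predict_tree_one <- function(node, q) {
  while (!node$leaf) {
    node <- if (q[node$feature] <= node$theta) node$left else node$right
  }
  node$label
}

#' Predict from a quantized tree (plaintext reference path)
#'
#' @param object a `quantized_tree`.
#' @param newdata integer matrix of quantized records or one vector.
#' @param ... unused.
#' @return integer labels.
#' @export
predict.quantized_tree <- function(object, newdata, ...) {
  Q <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  as.integer(apply(Q, 1, function(q) predict_tree_one(object$root, q)))
}

#' Construct a boosted stump ensemble with integer leaf scores
#'
#' A sum of depth-1 trees: each stump contributes `a_s + b_s * [x_f <= theta]`
#' to the integer score. The combined score must respect the scheme's
#' headroom.
#'
#' @param stumps list of `list(feature, theta, a, b)` with integer `a`, `b`.
#' @param scheme a [quantization_scheme].
#' @return object of class `quantized_stumps`.
#' @export
quantized_stump_ensemble <- function(stumps, scheme) {
  mass <- sum(vapply(stumps, function(s) abs(s$a) + abs(s$b), 0))
  if (mass > scheme$headroom) {
    stop("stump ensemble score can exceed the accumulator headroom")
  }
  structure(list(stumps = stumps, scheme = scheme),
            class = "quantized_stumps")
}

#' Predict from a quantized stump ensemble (plaintext reference path)
#'
#' @param object a `quantized_stumps`.
#' @param newdata integer matrix of quantized records or one vector.
#' @param type `"score"` (default: the integer ensemble score) or
#'   `"label"` (`score >= 0`).
#' @param ... unused.
#' @return integer scores or labels.
#' @export
predict.quantized_stumps <- function(object, newdata,
                                     type = c("score", "label"), ...) {
  type <- match.arg(type)
  Q <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  score <- apply(Q, 1, function(q) {
    sum(vapply(object$stumps, function(s) {
      s$a + s$b * (q[s$feature] <= s$theta)
    }, 0))
  })
  if (type == "score") as.integer(score) else as.integer(score >= 0)
}
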