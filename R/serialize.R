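# Versioned JSON serialization for keys, ciphertexts and quantized
# models: a small envelope (format tag, object type, parameter preset)
# with integer arrays base64-encoded over a deterministic decimal byte
# layout, so fixtures are stable across platforms.

FORMAT_TAG <- "fhecare/1"

b64_nums <- function(v) {
  jsonlite::base64_enc(charToRaw(paste(format(v, scientific = FALSE,
                                              trim = TRUE),
                                       collapse = " ")))
}

unb64_nums <- function(s) {
  as.numeric(strsplit(rawToChar(jsonlite::base64_dec(s)), " ",
                      fixed = TRUE)[[1]])
}

#' Serialize FHE objects or quantized models to JSON
#'
#' Supported: `lwe_sample`, `lwe_key`, `quantized_linear`,
#' `quantized_tree`, `quantized_stumps`, `quantization_scheme`.
#'
#' @param obj the object.
#' @param path optional file path; when `NULL` the JSON string is
#'   returned.
#' @param preset parameter preset name recorded in the envelope.
#' @return the JSON string (invisibly when written to `path`).
#' @export
fhe_serialize <- function(obj, path = NULL, preset = "TOY") {
  body <- if (inherits(obj, "lwe_sample")) {
    list(a = b64_nums(obj$a), b = b64_nums(obj$b), var = obj$var)
  } else if (inherits(obj, "lwe_key")) {
    list(s = b64_nums(obj$s))
  } else if (inherits(obj, "quantization_scheme")) {
    list(bits = obj$bits, mins = obj$mins, scales = obj$scales,
         levels = obj$levels, headroom = obj$headroom, slots = obj$slots)
  } else if (inherits(obj, "quantized_linear")) {
    list(weights = obj$weights, bias = obj$bias, lambda = obj$lambda,
         link = obj$link,
         scheme = jsonlite::fromJSON(fhe_serialize(obj$scheme)))
  } else if (inherits(obj, "quantized_stumps")) {
    list(stumps = obj$stumps,
         scheme = jsonlite::fromJSON(fhe_serialize(obj$scheme)))
  } else if (inherits(obj, "quantized_tree")) {
    list(root = obj$root, depth = obj$depth, n_features = obj$n_features,
         scheme = if (!is.null(obj$scheme)) {
           jsonlite::fromJSON(fhe_serialize(obj$scheme))
         })
  } else {
    stop(sprintf("cannot serialize class '%s'", class(obj)[1]))
  }
  env <- list(format = FORMAT_TAG, type = class(obj)[1], preset = preset,
              data = body)
  js <- jsonlite::toJSON(env, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

rebuild_scheme <- function(d) {
  structure(list(bits = as.integer(d$bits), mins = unlist(d$mins),
                 scales = unlist(d$scales), levels = d$levels,
                 headroom = as.integer(d$headroom),
                 slots = as.integer(d$slots), features = names(d$mins)),
            class = "quantization_scheme")
}

rebuild_node <- function(nd) {
  if (isTRUE(nd$leaf)) return(tree_leaf(nd$label, nd$score))
  tree_node(nd$feature, nd$theta, rebuild_node(nd$left),
            rebuild_node(nd$right))
}

#' Deserialize a [fhe_serialize] JSON envelope
#'
#' @param input JSON string or file path.
#' @return the reconstructed object.
#' @export
fhe_deserialize <- function(input) {
  js <- if (file.exists(input)) paste(readLines(input), collapse = "") else input
  env <- jsonlite::fromJSON(js, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(env$format, FORMAT_TAG)) {
    stop("unrecognized serialization format")
  }
  d <- env$data
  switch(env$type,
    lwe_sample = new_lwe_sample(unb64_nums(d$a), unb64_nums(d$b), d$var),
    lwe_key = structure(list(s = unb64_nums(d$s),
                             n = length(unb64_nums(d$s))),
                        class = "lwe_key"),
    quantization_scheme = rebuild_scheme(d),
    quantized_linear = structure(
      list(weights = as.integer(unlist(d$weights)),
           bias = as.integer(d$bias), lambda = d$lambda, link = d$link,
           scheme = rebuild_scheme(d$scheme$data)),
      class = "quantized_linear"),
    quantized_stumps = structure(
      list(stumps = lapply(d$stumps, function(s) {
        list(feature = as.integer(s$feature), theta = as.integer(s$theta),
             a = as.integer(s$a), b = as.integer(s$b))
      }), scheme = rebuild_scheme(d$scheme$data)),
      class = "quantized_stumps"),
    quantized_tree = structure(
      list(root = rebuild_node(d$root), depth = d$depth,
           n_features = d$n_features,
           scheme = if (!is.null(d$scheme)) rebuild_scheme(d$scheme$data)),
      class = "quantized_tree"),
    stop(sprintf("unknown serialized type '%s'", env$type))
  )
}
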