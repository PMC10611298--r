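# Encrypted evaluation of quantized classifiers over LWE-encrypted
# patient records.
#
# Integer feature levels are carried as phases on the 2N-slot grid
# (level q -> phase q/(2N)); homomorphic integer affine arithmetic then
# keeps scores on the same grid, and one programmable bootstrap per sign
# extraction / path bit does the non-linear part.  Fresh record masks are
# grid-aligned (see lwe_encrypt), which makes the rescaling step of blind
# rotation exact and gives the encrypted/plaintext agreement contract its
# exactness.

#' Generate a patient's FHE key material
#'
#' The patient holds the secret keys (LWE key and the extracted TLWE key);
#' the evaluation key set (bootstrapping key + key-switching key) is
#' public material handed to the servers, which lets them compute on the
#' patient's ciphertexts without being able to read them.
#'
#' @param params an [fhe_params] object.
#' @param key_id identifier string.
#' @param seed optional integer seed.
#' @return object of class `patient_keys` with fields `key_id`, `secret`
#'   (list `lwe`, `extracted`) and `eval` (a `bootstrap_keyset`).
#' @export
patient_keygen <- function(params, key_id = "patient", seed = NULL) {
  with_seed(seed, {
    lk <- lwe_keygen(params)
    tk <- tlwe_keygen(params)
    bk <- bootstrap_keygen(lk, tk, params)
    ksk <- keyswitch_keygen(extracted_key(tk), lk, params)
    keyset <- structure(list(bk = bk, ksk = ksk, params = params,
                             key_id = key_id),
                        class = "bootstrap_keyset")
    structure(list(key_id = key_id,
                   secret = list(lwe = lk, extracted = extracted_key(tk)),
                   eval = keyset, params = params),
              class = "patient_keys")
  })
}

#' @export
print.patient_keys <- function(x, ...) {
  cat(sprintf("<patient_keys id=%s preset=%s>\n", x$key_id,
              x$params$preset))
  invisible(x)
}

# phase step of one integer level
level_step <- function(params) TORUS_MOD / (2 * params$N)

#' Encrypt a quantized record
#'
#' Componentwise LWE encryption of the integer feature levels (phase
#' `q/(2N)` per feature), mask aligned to the rotation grid.
#'
#' @param keys a `patient_keys` object (uses the secret LWE key).
#' @param qrecord integer vector of quantized feature levels.
#' @param scheme the [quantization_scheme] the record was quantized with.
#' @param timestamp optional timestamp carried as provenance.
#' @param seed optional integer seed.
#' @return object of class `encrypted_record`.
#' @export
encrypted_record <- function(keys, qrecord, scheme, timestamp = 0,
                             seed = NULL) {
  params <- keys$params
  if (length(qrecord) != length(scheme$mins)) {
    stop("record arity does not match the model schema")
  }
  if (any(qrecord < 0) || any(qrecord > scheme$levels)) {
    stop("quantized values overflow the message space")
  }
  step <- level_step(params)
  with_seed(seed, {
    cts <- lapply(qrecord, function(q) {
      lwe_encrypt(keys$secret$lwe, tmod(q * step), params,
                  grid = 2 * params$N)
    })
    structure(list(cts = cts, key_id = keys$key_id, timestamp = timestamp,
                   arity = length(qrecord), params = params),
              class = "encrypted_record")
  })
}

#' @export
print.encrypted_record <- function(x, ...) {
  cat(sprintf("<encrypted_record key=%s arity=%d>\n", x$key_id, x$arity))
  invisible(x)
}

new_enc_prediction <- function(ct, key_id, key_form, space, kind,
                               server = NA_character_, model = NA_character_) {
  structure(list(ct = ct, key_id = key_id, key_form = key_form,
                 space = space, kind = kind,
                 server = server, model = model),
            class = "encrypted_prediction")
}

#' @export
print.encrypted_prediction <- function(x, ...) {
  cat(sprintf("<encrypted_prediction %s key=%s from=%s>\n", x$kind,
              x$key_id, x$server))
  invisible(x)
}

# the two-point encoding used for boolean path/label bits: phase 0 or 1/4
bit_encoding <- function() message_encoding(0, 1 / 4)

# sign bootstrap: mu1 when the phase is in the upper half-torus
enc_sign_bit <- function(eval_keys, ct, keyswitch = TRUE) {
  bootstrap(eval_keys, bit_encoding(), ct, keyswitch = keyswitch)
}

#' Homomorphic linear-classifier prediction
#'
#' Integer dot product of the encrypted levels with the model weights via
#' [lwe_affine_combine] plus the integer bias, then one bootstrap
#' extracting the score sign as the class label. The decrypted label
#' equals the plaintext quantized model's label on the same record.
#'
#' @param model a `quantized_linear`.
#' @param rec an `encrypted_record`.
#' @param eval_keys the patient's public `bootstrap_keyset`.
#' @param server,model_name provenance strings.
#' @return an `encrypted_prediction` (label bit under the extracted key).
#' @export
enc_linear_predict <- function(model, rec, eval_keys,
                               server = NA_character_,
                               model_name = "linear") {
  if (rec$arity != length(model$weights)) {
    stop("record arity does not match the model")
  }
  params <- rec$params
  step <- level_step(params)
  score <- lwe_affine_combine(
    c(rec$cts, list(lwe_trivial(tmod(model$bias * step), params$n))),
    c(model$weights, 1)
  )
  bit <- enc_sign_bit(eval_keys, score, keyswitch = FALSE)
  new_enc_prediction(bit, rec$key_id, "extracted", 4L, "label",
                     server, model_name)
}

# encrypted comparison  x_f <= theta  as a sign bit (keyswitched so it can
# feed further gates)
enc_compare_leq <- function(rec, feature, theta, eval_keys) {
  params <- rec$params
  step <- level_step(params)
  diff <- lwe_affine_combine(
    list(lwe_trivial(tmod(theta * step), params$n), rec$cts[[feature]]),
    c(1, -1)
  )
  enc_sign_bit(eval_keys, diff, keyswitch = TRUE)
}

# NOT over {0, 1/4}-encoded bits: 1/4 - b (linear, no bootstrap)
enc_bit_not <- function(bit, n) {
  lwe_affine_combine(list(lwe_trivial(to_torus(1 / 4), n), bit), c(1, -1))
}

# AND via one bootstrap: the bit sum is 0, 1/4 or 1/2, and subtracting
# 3/8 puts it in the upper half-torus iff both bits are set (margin 1/8
# on either side)
enc_bit_and <- function(b1, b2, eval_keys, keyswitch = TRUE) {
  n <- length(b1$a)
  s <- lwe_affine_combine(
    list(b1, b2, lwe_trivial(to_torus(3 / 8), n)),
    c(1, 1, -1)
  )
  enc_sign_bit(eval_keys, s, keyswitch = keyswitch)
}

# Recursively build the one-hot leaf indicators of a tree path product.
# `cond` is the encrypted indicator of the path so far (NULL at the root);
# returns list of list(label, ct) with ct under the extracted key.
enc_tree_leaves <- function(node, rec, eval_keys, cond) {
  params <- rec$params
  if (node$leaf) {
    ct <- if (is.null(cond)) {
      # single-leaf tree: constant indicator
      lwe_trivial(to_torus(1 / 4), params$k * params$N)
    } else {
      # re-threshold the path bit between its two phases (0 and 1/4) and
      # finalize without the key switch (terminal result)
      shifted <- lwe_affine_combine(
        list(cond, lwe_trivial(to_torus(1 / 8), params$n)), c(1, -1)
      )
      bootstrap(eval_keys, bit_encoding(), shifted, keyswitch = FALSE)
    }
    return(list(list(label = node$label, ct = ct)))
  }
  bit <- enc_compare_leq(rec, node$feature, node$theta, eval_keys)
  nbit <- enc_bit_not(bit, params$n)
  left_cond <- if (is.null(cond)) bit else {
    enc_bit_and(cond, bit, eval_keys, keyswitch = TRUE)
  }
  right_cond <- if (is.null(cond)) nbit else {
    enc_bit_and(cond, nbit, eval_keys, keyswitch = TRUE)
  }
  c(enc_tree_leaves(node$left, rec, eval_keys, left_cond),
    enc_tree_leaves(node$right, rec, eval_keys, right_cond))
}

#' Homomorphic decision-tree prediction
#'
#' Every comparison `x_f <= theta` is a bootstrapped sign of
#' `theta - x_f`; leaf selection is a one-hot product of path bits
#' (bootstrapped AND gates); the label ciphertext is the sum of the
#' label-1 leaf indicators (exactly one indicator is hot). The decrypted
#' label equals the plaintext quantized tree's label.
#'
#' @param model a `quantized_tree` of depth at most `max_depth`.
#' @param rec an `encrypted_record`.
#' @param eval_keys the patient's public `bootstrap_keyset`.
#' @param max_depth encrypted-evaluation depth limit (default 3); deeper
#'   trees are rejected with a pointer to the plaintext path.
#' @param server,model_name provenance strings.
#' @return an `encrypted_prediction` (label under the extracted key).
#' @export
enc_tree_predict <- function(model, rec, eval_keys, max_depth = 3,
                             server = NA_character_, model_name = "tree") {
  d <- tree_depth(model$root)
  if (d > max_depth) {
    stop(sprintf(
      "tree depth %d exceeds the encrypted-evaluation limit %d; use the plaintext quantized path",
      d, max_depth
    ))
  }
  params <- rec$params
  leaves <- enc_tree_leaves(model$root, rec, eval_keys, NULL)
  pos <- Filter(function(lf) lf$label == 1, leaves)
  ct <- if (length(pos) == 0) {
    lwe_trivial(0, params$k * params$N)
  } else {
    lwe_affine_combine(lapply(pos, `[[`, "ct"), rep(1, length(pos)))
  }
  new_enc_prediction(ct, rec$key_id, "extracted", 4L, "label",
                     server, model_name)
}

#' Homomorphic stump-ensemble prediction
#'
#' Each stump's comparison bit is bootstrapped directly onto the stump's
#' integer leaf increment (`b_s` levels), so the encrypted score is the
#' trivial constant part plus the sum of the bootstrapped contributions.
#' The decrypted integer score equals the plaintext quantized ensemble
#' score.
#'
#' @param model a `quantized_stumps`.
#' @param rec an `encrypted_record`.
#' @param eval_keys the patient's public `bootstrap_keyset`.
#' @param server,model_name provenance strings.
#' @return an `encrypted_prediction` (signed integer score on the `2N`
#'   grid, under the extracted key).
#' @export
enc_stumps_predict <- function(model, rec, eval_keys,
                               server = NA_character_,
                               model_name = "stumps") {
  params <- rec$params
  step <- level_step(params)
  const <- sum(vapply(model$stumps, `[[`, 0, "a"))
  parts <- list(lwe_trivial(tmod(const * step), params$k * params$N))
  for (s in model$stumps) {
    diff <- lwe_affine_combine(
      list(lwe_trivial(tmod(s$theta * step), params$n),
           rec$cts[[s$feature]]),
      c(1, -1)
    )
    enc_b <- message_encoding(0, s$b / (2 * params$N))
    parts <- c(parts, list(bootstrap(eval_keys, enc_b, diff,
                                     keyswitch = FALSE)))
  }
  ct <- lwe_affine_combine(parts, rep(1, length(parts)))
  new_enc_prediction(ct, rec$key_id, "extracted", 2L * params$N, "score",
                     server, model_name)
}

#' Decrypt an encrypted prediction
#'
#' @param keys the `patient_keys` whose `key_id` matches the prediction's.
#' @param pred an `encrypted_prediction`.
#' @return for `kind = "label"`, an integer 0/1 label; for
#'   `kind = "score"`, the signed integer score.
#' @export
decrypt_result <- function(keys, pred) {
  if (!identical(keys$key_id, pred$key_id)) {
    stop("prediction is not addressed to this patient key")
  }
  key <- switch(pred$key_form,
    lwe = keys$secret$lwe,
    extracted = keys$secret$extracted,
    stop("unknown key form")
  )
  m <- lwe_decrypt(key, pred$ct, pred$space)
  if (pred$kind == "label") {
    as.integer(m == 1)
  } else {
    # signed decode on the 2N grid
    as.integer(if (m >= pred$space / 2) m - pred$space else m)
  }
}
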