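test_that("encrypted records round-trip and validate their schema", {
  env <- toy_scheme_env()
  sch <- env$scheme
  keys <- toy_keys()
  p <- toy_params()
  step <- 2^32 / (2 * p$N)
  # all-zero record decrypts to zeros; random record recovers exactly
  for (q in list(rep(0L, 5), with_seed(33, sample(0:7, 5, TRUE)))) {
    rec <- encrypted_record(keys, q, sch, seed = 34)
    got <- vapply(rec$cts, function(ct) {
      lwe_decrypt(keys$secret$lwe, ct, 2 * p$N)
    }, 0)
    expect_identical(as.integer(got), as.integer(q))
  }
  expect_error(encrypted_record(keys, c(1L, 2L), sch), "arity")
  expect_error(encrypted_record(keys, c(0L, 0L, 0L, 0L, 99L), sch),
               "overflow")
})

test_that("encrypted linear predictions equal the plaintext quantized labels", {
  env <- toy_scheme_env()
  sch <- env$scheme
  keys <- toy_keys()
  # all-zero weights with positive bias: constant positive class
  const <- quantize_linear_model(numeric(5), 2, sch)
  rec0 <- encrypted_record(keys, rep(0L, 5), sch, seed = 35)
  expect_identical(decrypt_result(keys,
                                  enc_linear_predict(const, rec0,
                                                     keys$eval)), 1L)
  # single feature, weight 1, threshold mid-range: label is the sign of
  # the centered level
  single <- structure(list(weights = c(1L, 0L, 0L, 0L, 0L), bias = -4L,
                           lambda = 1, link = "identity", scheme = sch),
                      class = "quantized_linear")
  for (v in c(0L, 3L, 4L, 7L)) {
    r <- encrypted_record(keys, c(v, 0L, 0L, 0L, 0L), sch, seed = 90 + v)
    expect_identical(decrypt_result(keys,
                                    enc_linear_predict(single, r,
                                                       keys$eval)),
                     as.integer(v - 4L >= 0))
  }
  # 40 random records: labels identical to the plaintext quantized model
  qm <- with_seed(36, quantize_linear_model(rnorm(5), rnorm(1, 0, 0.5),
                                            sch))
  Q <- with_seed(37, matrix(sample(0:7, 40 * 5, TRUE), 40, 5))
  want <- predict(qm, Q)
  got <- vapply(1:40, function(i) {
    rec <- encrypted_record(keys, Q[i, ], sch, seed = 38 + i)
    decrypt_result(keys, enc_linear_predict(qm, rec, keys$eval))
  }, 0L)
  expect_identical(got, want)
})

test_that("encrypted tree predictions equal the plaintext quantized labels", {
  env <- toy_scheme_env()
  sch <- env$scheme
  keys <- toy_keys()
  # single leaf: constant prediction regardless of input
  leaf_only <- structure(list(root = fhecare:::tree_leaf(1),
                              depth = 0, n_features = 5, scheme = sch),
                         class = "quantized_tree")
  rec <- encrypted_record(keys, rep(3L, 5), sch, seed = 80)
  expect_identical(decrypt_result(keys,
                                  enc_tree_predict(leaf_only, rec,
                                                   keys$eval)), 1L)
  # depth-1 stump at theta = 3: matches the cleartext comparison on
  # records straddling the threshold
  stump <- structure(list(root = fhecare:::tree_node(
    2L, 3L, fhecare:::tree_leaf(1), fhecare:::tree_leaf(0)
  ), depth = 1, n_features = 5, scheme = sch), class = "quantized_tree")
  for (v in c(0L, 2L, 3L, 4L, 7L)) {
    q <- c(1L, v, 1L, 1L, 1L)
    r <- encrypted_record(keys, q, sch, seed = 81 + v)
    expect_identical(decrypt_result(keys,
                                    enc_tree_predict(stump, r, keys$eval)),
                     predict(stump, q))
  }
  # a fitted depth-3 tree on 25 random records
  Q <- t(apply(env$X, 1, quantize_record, scheme = sch))
  y <- as.integer(env$X[, 1] + 0.5 * env$X[, 2] - env$X[, 5] > 0.4)
  tr <- fit_quantized_tree(Q, y, depth = 3, scheme = sch)
  idx <- with_seed(39, sample(nrow(Q), 25))
  want <- predict(tr, Q[idx, ])
  got <- vapply(seq_along(idx), function(i) {
    r <- encrypted_record(keys, Q[idx[i], ], sch, seed = 400 + i)
    decrypt_result(keys, enc_tree_predict(tr, r, keys$eval))
  }, 0L)
  expect_identical(got, want)
  # depth limit is enforced with a pointer to the plaintext path
  deep <- fit_quantized_tree(Q, y, depth = 5, scheme = sch)
  if (fhecare:::tree_depth(deep$root) > 3) {
    expect_error(enc_tree_predict(deep, rec, keys$eval), "plaintext")
  }
})

test_that("encrypted stump-ensemble scores equal the plaintext scores", {
  env <- toy_scheme_env()
  sch <- env$scheme
  keys <- toy_keys()
  st <- quantized_stump_ensemble(list(
    list(feature = 1L, theta = 3L, a = 2L, b = -5L),
    list(feature = 5L, theta = 2L, a = -1L, b = 4L),
    list(feature = 2L, theta = 5L, a = 0L, b = 3L)
  ), sch)
  Q <- with_seed(40, matrix(sample(0:7, 12 * 5, TRUE), 12, 5))
  want <- predict(st, Q, type = "score")
  got <- vapply(1:12, function(i) {
    r <- encrypted_record(keys, Q[i, ], sch, seed = 500 + i)
    decrypt_result(keys, enc_stumps_predict(st, r, keys$eval))
  }, 0L)
  expect_identical(got, want)
})

test_that("results decrypt only under the addressed patient key", {
  env <- toy_scheme_env()
  keys <- toy_keys()
  other <- patient_keygen(toy_params(), "other-patient", seed = 41)
  qm <- quantize_linear_model(numeric(5), 1, env$scheme)
  rec <- encrypted_record(keys, rep(0L, 5), env$scheme, seed = 42)
  pred <- enc_linear_predict(qm, rec, keys$eval)
  expect_identical(decrypt_result(keys, pred), 1L)
  expect_error(decrypt_result(other, pred), "not addressed")
})
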