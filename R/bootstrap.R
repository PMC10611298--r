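# Key switching, blind rotation, sample extraction and bootstrapping.

#' Generate a key-switching key
#'
#' `ks[i, j]` encrypts `s_src[i] * 2^-j` (j = 1..t) under the target key, so
#' a ciphertext under the source key can be re-expressed under the target
#' key by binary-decomposing its (rounded) mask.
#'
#' @param src_key source `lwe_key` (dimension n').
#' @param dst_key target `lwe_key`.
#' @param params an [fhe_params] object (`t`, `stdev_ksk`, target `n`).
#' @param seed optional integer seed.
#' @return object of class `keyswitch_key`.
#' @export
keyswitch_keygen <- function(src_key, dst_key, params, seed = NULL) {
  n_src <- length(src_key$s)
  t <- params$t
  with_seed(seed, {
    n_dst <- length(dst_key$s)
    A <- matrix(0, nrow = n_src * t, ncol = n_dst)
    b <- numeric(n_src * t)
    for (i in seq_len(n_src)) {
      for (j in seq_len(t)) {
        mu <- tmod(src_key$s[i] * 2^(TORUS_Q - j))
        # grid-aligned masks: key-switched ciphertexts then re-enter blind
        # rotation without per-coefficient rounding drift
        ct <- lwe_encrypt(dst_key, mu, params, stdev = params$stdev_ksk,
                          grid = 2 * params$N)
        r <- (i - 1) * t + j
        A[r, ] <- ct$a
        b[r] <- ct$b
      }
    }
    structure(list(A = A, b = b, n_src = n_src, n_dst = n_dst, t = t,
                   source_key_id = attr(src_key, "key_id"),
                   target_key_id = attr(dst_key, "key_id"),
                   var = params$stdev_ksk^2),
              class = "keyswitch_key")
  })
}

#' Switch an LWE sample to a different key
#'
#' Each mask coefficient is rounded to the nearest multiple of `2^-t`
#' (so `|a_bar - a| < 2^-(t+1)`), expanded in binary digits, and the
#' output assembled as `(0, b) - sum_{i,j} digit_{i,j} * ks[i, j]`. The
#' message is preserved; the noise gains the key-switching-key noise plus
#' the rounding term.
#'
#' @param ksk a `keyswitch_key`.
#' @param ct an `lwe_sample` under the source key.
#' @return an `lwe_sample` under the target key.
#' @export
key_switch <- function(ksk, ct) {
  if (length(ct$a) != ksk$n_src) {
    stop("ciphertext is not under the key-switching source key")
  }
  t <- ksk$t
  # nearest multiple of 2^-t (torus integer grid step 2^(32-t)), half up
  abar <- round_half_up(ct$a / 2^(TORUS_Q - t)) %% 2^t
  # binary digits a_{i,j} in {0,1}, most significant first (weight 2^-j)
  bits <- matrix(0, nrow = ksk$n_src, ncol = t)
  r <- abar
  for (j in seq_len(t)) {
    w <- 2^(t - j)
    bits[, j] <- floor(r / w)
    r <- r - bits[, j] * w
  }
  bv <- as.vector(t(bits)) # row (i-1)*t + j ordering of ksk
  a_out <- tmod(-as.vector(bv %*% ksk$A))
  b_out <- tmod(ct$b - sum(bv * ksk$b))
  nbits <- sum(bv)
  new_lwe_sample(a_out, b_out,
                 var = ct$var + nbits * ksk$var +
                   ksk$n_src * (2^-(t + 1))^2 / 3)
}

#' Build the bootstrap test vector
#'
#' The staircase polynomial `mu_bar_prime * (1 + X + ... + X^(N-1))`: under
#' blind rotation by the ciphertext phase and constant-term extraction, its
#' sign flip across the half-torus realizes the two-point selection of the
#' bootstrap (negacyclic wrap: rotating by `X^N` negates all coefficients).
#'
#' @param enc a [message_encoding].
#' @param N polynomial degree (power of two).
#' @return length-`N` vector of torus integers, all equal `mu_bar_prime`.
#' @export
make_test_vector <- function(enc, N) {
  stopifnot(N >= 2, log2(N) == round(log2(N)))
  rep(tmod(enc$mu_bar_prime), N)
}

#' Generate a bootstrapping key
#'
#' `bk[i]` is a TGSW encryption of the i-th bit of the input LWE key under
#' the TLWE key.
#'
#' @param lwe_key the input-side `lwe_key`.
#' @param tlwe_key the accumulator-side `tlwe_key`.
#' @param params an [fhe_params] object.
#' @param seed optional integer seed.
#' @return object of class `bootstrap_key` (list of `n` TGSW samples).
#' @export
bootstrap_keygen <- function(lwe_key, tlwe_key, params, seed = NULL) {
  with_seed(seed, {
    bk <- lapply(seq_len(params$n), function(i) {
      tgsw_encrypt(tlwe_key, lwe_key$s[i], params)
    })
    structure(list(bk = bk, n = params$n, params = params),
              class = "bootstrap_key")
  })
}

# Extract the constant coefficient of a TLWE sample as an LWE sample of
# dimension k*N under the flattened (extracted) key.
sample_extract <- function(ct) {
  N <- ct$N
  k <- ct$k
  a <- numeric(k * N)
  for (i in seq_len(k)) {
    col <- ct$coefs[, i]
    # constant coeff of a_i(X) * S_i(X) mod X^N+1 pairs S_j with
    # a_0 (j = 0) and -a_{N-j} (j >= 1)
    a[(i - 1) * N + 1] <- col[1]
    if (N > 1) a[(i - 1) * N + 2:N] <- tmod(-col[N:2])
  }
  new_lwe_sample(a, ct$coefs[1, k + 1], var = ct$var)
}

# The LWE key the extraction decrypts under: the TLWE key coefficients
# flattened column-major.
extracted_key <- function(tlwe_key) {
  structure(list(s = as.vector(tlwe_key$S), n = length(tlwe_key$S)),
            class = "lwe_key")
}

#' Blind rotation and sample extraction
#'
#' Rescales the input ciphertext to `2N` slots (`b_bar = round(2N b)`,
#' `a_bar_i = round(2N a_i)`, half-up), initializes the accumulator
#' `ACC <- X^(-b_bar) * (0, testv)` and iterates the CMUX step
#' `ACC <- ACC + BK_i (x) (X^(a_bar_i) * ACC - ACC)` for `i = 1..n` —
#' the exact-identity realization of multiplying by
#' `h + (X^(a_bar_i) - 1) * BK_i` — then returns the constant-coefficient
#' LWE extraction of `ACC` (a sample under the extracted TLWE key).
#'
#' @param bk a `bootstrap_key`.
#' @param testv length-`N` torus polynomial (see [make_test_vector]).
#' @param ct an `lwe_sample` of dimension `n`.
#' @return an `lwe_sample` of dimension `k*N` under the extracted key.
#' @export
blind_rotate_and_extract <- function(bk, testv, ct) {
  params <- bk$params
  if (length(ct$a) != params$n) stop("ciphertext/bootstrap-key mismatch")
  N <- params$N
  two_N <- 2 * N
  bbar <- round_half_up(ct$b * two_N / TORUS_MOD) %% two_N
  abar <- round_half_up(ct$a * two_N / TORUS_MOD) %% two_N
  acc <- tlwe_rotate(tlwe_trivial(testv, params$k), -bbar)
  for (i in seq_len(params$n)) {
    if (abar[i] == 0) next
    diff <- tlwe_sub(tlwe_rotate(acc, abar[i]), acc)
    acc <- tlwe_add(acc, external_product(bk$bk[[i]], diff))
  }
  sample_extract(acc)
}

#' Evaluation key set for bootstrapping
#'
#' Bundles the public evaluation material: the bootstrapping key over a
#' fresh TLWE key and the key-switching key from the extracted key back to
#' the original LWE key. The secret keys themselves are not part of the
#' set; publishing it allows third parties to bootstrap ciphertexts they
#' cannot read.
#'
#' @param lwe_key the patient's `lwe_key`.
#' @param params an [fhe_params] object.
#' @param seed optional integer seed.
#' @return object of class `bootstrap_keyset` with fields `bk`, `ksk`,
#'   `params`.
#' @export
make_bootstrap_keyset <- function(lwe_key, params, seed = NULL) {
  with_seed(seed, {
    tk <- tlwe_keygen(params)
    bk <- bootstrap_keygen(lwe_key, tk, params)
    ksk <- keyswitch_keygen(extracted_key(tk), lwe_key, params)
    structure(list(bk = bk, ksk = ksk, params = params),
              class = "bootstrap_keyset")
  })
}

#' Bootstrap an LWE ciphertext onto a two-point message
#'
#' Refreshes the ciphertext noise and maps the phase onto one of the two
#' encoded messages: phases in the upper half-torus `[0, 1/2)` (a phase of
#' exactly 0 included) come out as `mu1`, phases in `[1/2, 1)` as `mu0`.
#' The output is `(0, mu_bar)` plus the blind-rotation extraction,
#' key-switched back to the original key; its noise is bounded by a
#' constant independent of the input noise.
#'
#' The sign selection needs the test vector negated relative to
#' [make_test_vector] (equivalently, offset by `X^N`); that offset is
#' applied here, keeping the staircase construction itself untouched.
#'
#' @param keyset a `bootstrap_keyset`.
#' @param enc a [message_encoding].
#' @param ct an `lwe_sample` whose noise is below the decryption-failure
#'   threshold for the rotation grid (`|noise| << 1/(4N)` in practice).
#' @param keyswitch if `FALSE`, skip the final key switch and return the
#'   sample under the extracted key (dimension `k*N`). Useful for terminal
#'   results that the key owner will decrypt directly: the key-switching
#'   noise (the dominant term in the output noise) is avoided, at the cost
#'   of the larger ciphertext dimension.
#' @return an `lwe_sample` under the original key (or the extracted key
#'   when `keyswitch = FALSE`), encrypting `mu0` or `mu1`.
#' @export
bootstrap <- function(keyset, enc, ct, keyswitch = TRUE) {
  params <- keyset$params
  testv <- tmod(-make_test_vector(enc, params$N)) # X^N offset: negation
  u <- blind_rotate_and_extract(keyset$bk, testv, ct)
  u$b <- tmod(u$b + enc$mu_bar)
  if (keyswitch) key_switch(keyset$ksk, u) else u
}
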