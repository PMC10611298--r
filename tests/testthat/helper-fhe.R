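# Shared fixtures: TOY-parameter key material is expensive to generate,
# so it is memoized for the whole test run.

.fixtures <- new.env(parent = emptyenv())

toy_params <- function() fhe_params("TOY")

toy_keys <- function() {
  if (is.null(.fixtures$keys)) {
    .fixtures$keys <- patient_keygen(toy_params(), "test-patient",
                                     seed = 20260920L)
  }
  .fixtures$keys
}

toy_lwe_key <- function() toy_keys()$secret$lwe

toy_keyset <- function() toy_keys()$eval

# a small calibrated feature table + quantization scheme shared by the
# encrypted-inference tests
toy_scheme_env <- function() {
  if (is.null(.fixtures$scheme)) {
    X <- with_seed(99, matrix(runif(200 * 5), 200, 5))
    .fixtures$scheme <- list(
      X = X,
      scheme = quantization_scheme(X, bits = 3, params = toy_params())
    )
  }
  .fixtures$scheme
}

# brute-force negacyclic product over torus integers (independent oracle,
# O(N^2) schoolbook with explicit sign handling)
oracle_negacyclic <- function(p_int, q_tor) {
  N <- length(p_int)
  out <- numeric(N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      k <- (i + j - 2) %% N + 1
      sgn <- if (i + j - 2 >= N) -1 else 1
      out[k] <- out[k] + sgn * p_int[i] * q_tor[j]
    }
  }
  out %% 2^32
}
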