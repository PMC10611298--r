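# LWE ciphertexts over the discretized torus.
#
# A sample is (a, b) with mask a in T^n and body b = a.s + mu + e.  The
# noise variance (torus^2 scale) is tracked alongside each ciphertext as
# test instrumentation; it composes additively under the linear operations.

new_lwe_sample <- function(a, b, var = 0) {
  structure(list(a = a, b = b, var = var), class = "lwe_sample")
}

#' @export
print.lwe_sample <- function(x, ...) {
  cat(sprintf("<lwe_sample n=%d var~2^%.1f>\n", length(x$a),
              if (x$var > 0) log2(sqrt(x$var)) else -Inf))
  invisible(x)
}

#' Generate a binary LWE secret key
#'
#' @param params an [fhe_params] object (uses `params$n`).
#' @param seed optional integer seed.
#' @return object of class `lwe_key`: a length-`n` 0/1 vector.
#' @export
lwe_keygen <- function(params, seed = NULL) {
  with_seed(seed, {
    structure(list(s = sample(c(0, 1), params$n, replace = TRUE),
                   n = params$n),
              class = "lwe_key")
  })
}

#' Encrypt a torus message under an LWE key
#'
#' `b = a.s + mu + e` with uniform mask `a` and rounded-Gaussian noise `e`
#' of standard deviation `stdev` on the torus scale. With `stdev = 0` the
#' phase equals `mu` exactly.
#'
#' @param key an `lwe_key`.
#' @param mu torus message: integer in `[0, 2^32)` (use [to_torus] for
#'   fractions).
#' @param params an [fhe_params] object.
#' @param stdev noise standard deviation; defaults to `params$stdev_lwe`.
#' @param grid optional slot count: when given, the mask is drawn from the
#'   sub-grid of multiples of `2^32/grid`. Aligning fresh encryptions to
#'   the `2N`-slot rotation grid makes the phase rescaling inside
#'   bootstrapping exact (no per-coefficient rounding drift), which the
#'   encrypted-inference layer relies on for its exact-agreement contract.
#' @param seed optional integer seed.
#' @return an `lwe_sample`.
#' @export
#' @examples
#' p <- fhe_params("TOY")
#' k <- lwe_keygen(p, seed = 1)
#' ct <- lwe_encrypt(k, to_torus(5 / 8), p, seed = 2)
#' lwe_decrypt(k, ct, 8)  # 5 (i.e. message 5/8 on an 8-point space)
lwe_encrypt <- function(key, mu, params, stdev = params$stdev_lwe,
                        grid = NULL, seed = NULL) {
  if (length(key$s) != params$n) {
    stop("key dimension does not match params$n")
  }
  with_seed(seed, {
    a <- if (is.null(grid)) {
      tmod(floor(runif(params$n) * TORUS_MOD))
    } else {
      floor(runif(params$n) * grid) * (TORUS_MOD / grid)
    }
    e <- torus_gaussian(1, stdev)
    b <- tmod(sum(a * key$s) + mu + e)
    new_lwe_sample(a, b, var = stdev^2)
  })
}

# Trivial (noiseless, keyless) sample encoding a public constant.
lwe_trivial <- function(mu, n) new_lwe_sample(numeric(n), tmod(mu), var = 0)

#' Phase of an LWE sample
#'
#' `phase = b - a.s`, the message plus noise, as a torus integer.
#'
#' @param key the `lwe_key` the sample was encrypted under.
#' @param ct an `lwe_sample`.
#' @return torus integer in `[0, 2^32)`.
#' @export
lwe_phase <- function(key, ct) {
  if (length(key$s) != length(ct$a)) stop("key/ciphertext dimension mismatch")
  # sum(a*s) <= n * 2^32 < 2^53 for all supported n: exact in doubles
  tmod(ct$b - sum(ct$a * key$s))
}

#' Decrypt an LWE sample onto a small message space
#'
#' Rounds the phase to the nearest of `message_space` equispaced torus
#' points (half-up tie rule) and returns the message index.
#'
#' @param key the matching `lwe_key`.
#' @param ct an `lwe_sample`.
#' @param message_space number of message points (`>= 2`).
#' @return integer message index in `0 .. message_space - 1`.
#' @export
lwe_decrypt <- function(key, ct, message_space) {
  stopifnot(message_space >= 2)
  ph <- lwe_phase(key, ct)
  as.integer(round_half_up(ph / TORUS_MOD * message_space) %% message_space)
}

#' Homomorphic integer-affine combination of LWE samples
#'
#' Computes `sum(coeffs[i] * ct[i])` componentwise; the phase of the output
#' is exactly the same combination of the input phases (modular torus
#' arithmetic), and the tracked noise variance composes as
#' `sum(coeffs^2 * var)`.
#'
#' @param samples non-empty list of `lwe_sample`s under one key.
#' @param coeffs integer coefficients, one per sample (kept small so the
#'   noise growth stays bounded).
#' @return an `lwe_sample`.
#' @export
lwe_affine_combine <- function(samples, coeffs) {
  if (length(samples) == 0) stop("empty sample list")
  if (length(samples) != length(coeffs)) {
    stop("one coefficient per sample required")
  }
  n <- length(samples[[1]]$a)
  a <- numeric(n)
  b <- 0
  v <- 0
  for (i in seq_along(samples)) {
    ct <- samples[[i]]
    if (length(ct$a) != n) stop("samples have mismatched dimensions")
    if (coeffs[i] == 0) next
    a <- tmod(a + coeffs[i] * ct$a)
    b <- tmod(b + coeffs[i] * ct$b)
    v <- v + coeffs[i]^2 * ct$var
  }
  new_lwe_sample(a, b, var = v)
}
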