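# TLWE ciphertexts: LWE over torus polynomials T_N[X] = T[X]/(X^N + 1).
# A sample is stored as an N x (k+1) matrix of torus integers: columns
# 1..k are the mask polynomials a_i, column k+1 is the body b.

new_tlwe_sample <- function(coefs, k, N, var = 0) {
  structure(list(coefs = coefs, k = k, N = N, var = var),
            class = "tlwe_sample")
}

#' @export
print.tlwe_sample <- function(x, ...) {
  cat(sprintf("<tlwe_sample k=%d N=%d>\n", x$k, x$N))
  invisible(x)
}

#' Generate a TLWE secret key
#'
#' @param params an [fhe_params] object (uses `N` and `k`); the key is a
#'   length-`k` vector of binary-coefficient polynomials.
#' @param seed optional integer seed.
#' @return object of class `tlwe_key` holding an `N x k` 0/1 matrix `S`.
#' @export
tlwe_keygen <- function(params, seed = NULL) {
  with_seed(seed, {
    S <- matrix(sample(c(0, 1), params$N * params$k, replace = TRUE),
                nrow = params$N, ncol = params$k)
    structure(list(S = S, k = params$k, N = params$N), class = "tlwe_key")
  })
}

#' Encrypt a torus polynomial under a TLWE key
#'
#' @param key a `tlwe_key`.
#' @param mu length-`N` vector of torus integers (the message polynomial).
#' @param params an [fhe_params] object.
#' @param stdev per-coefficient noise standard deviation (torus scale),
#'   default `params$stdev_tlwe`.
#' @param seed optional integer seed.
#' @return a `tlwe_sample`.
#' @export
tlwe_encrypt <- function(key, mu, params, stdev = params$stdev_tlwe,
                         seed = NULL) {
  N <- params$N
  k <- params$k
  stopifnot(length(mu) == N)
  with_seed(seed, {
    coefs <- matrix(0, nrow = N, ncol = k + 1)
    body <- tmod(mu + torus_gaussian(N, stdev))
    for (i in seq_len(k)) {
      a_i <- tmod(floor(runif(N) * TORUS_MOD))
      coefs[, i] <- a_i
      body <- tmod(body + poly_mul_negacyclic(key$S[, i], a_i))
    }
    coefs[, k + 1] <- body
    new_tlwe_sample(coefs, k, N, var = stdev^2)
  })
}

# Trivial noiseless sample of a public polynomial (mask zero).
tlwe_trivial <- function(mu, k) {
  N <- length(mu)
  coefs <- matrix(0, nrow = N, ncol = k + 1)
  coefs[, k + 1] <- tmod(mu)
  new_tlwe_sample(coefs, k, N)
}

#' Phase of a TLWE sample
#'
#' `phase = b - sum_i a_i * S_i` (negacyclic products), the message
#' polynomial plus noise.
#'
#' @param key the matching `tlwe_key`.
#' @param ct a `tlwe_sample`.
#' @return length-`N` vector of torus integers.
#' @export
tlwe_phase <- function(key, ct) {
  ph <- ct$coefs[, ct$k + 1]
  for (i in seq_len(ct$k)) {
    ph <- tmod(ph - poly_mul_negacyclic(key$S[, i], ct$coefs[, i]))
  }
  ph
}

tlwe_add <- function(x, y) {
  new_tlwe_sample(tmod(x$coefs + y$coefs), x$k, x$N, var = x$var + y$var)
}

tlwe_sub <- function(x, y) {
  new_tlwe_sample(tmod(x$coefs - y$coefs), x$k, x$N, var = x$var + y$var)
}

# Multiply a whole TLWE sample by X^m (exact, noise-preserving).
tlwe_rotate <- function(ct, m) {
  coefs <- apply(ct$coefs, 2, poly_rotate, m = m)
  new_tlwe_sample(coefs, ct$k, ct$N, var = ct$var)
}

#' Gadget decomposition of a TLWE sample
#'
#' Approximates every coefficient of the `k + 1` component polynomials by
#' its nearest multiple of `1/Bg^l` (ties round half up) and expands that
#' approximation in signed base-`Bg` digits, each in `(-Bg/2, Bg/2]`
#' (normalized by carry propagation). The reconstruction
#' `sum_p digit_p / Bg^p` differs from the input coefficient by at most
#' `epsilon = 1/(2*Bg^l)`, and the map is deterministic.
#'
#' @param ct a `tlwe_sample`.
#' @param g a [gadget_params] object.
#' @return object of class `decomposition_digits`: an integer matrix with
#'   `(k+1)*l` rows (row `(i-1)*l + p` is the level-`p` digit polynomial of
#'   component `i`) and `N` columns.
#' @export
gadget_decompose <- function(ct, g) {
  N <- ct$N
  k <- ct$k
  Bg <- g$Bg
  l <- g$l
  half <- Bg / 2
  scale <- Bg^l
  # nearest multiple of 1/Bg^l, half-up, as an integer in [0, Bg^l)
  vbar <- round_half_up(ct$coefs * (scale / TORUS_MOD)) %% scale
  digits <- matrix(0L, nrow = (k + 1) * l, ncol = N)
  # extract signed digits least-significant first; d = Bg/2 is kept (tie
  # side of the (-Bg/2, Bg/2] range), larger residues borrow upward
  for (p in l:1) {
    d <- vbar %% Bg
    d <- ifelse(d > half, d - Bg, d)
    vbar <- (vbar - d) / Bg
    for (i in seq_len(k + 1)) {
      digits[(i - 1) * l + p, ] <- as.integer(d[, i])
    }
  }
  structure(list(digits = digits, k = k, N = N, g = g),
            class = "decomposition_digits")
}

# Reconstruct the approximated sample from its digits (test support and
# the definition of the decomposition error).
gadget_reconstruct <- function(dd) {
  Bg <- dd$g$Bg
  l <- dd$g$l
  coefs <- matrix(0, nrow = dd$N, ncol = dd$k + 1)
  for (i in seq_len(dd$k + 1)) {
    acc <- numeric(dd$N)
    for (p in seq_len(l)) {
      acc <- acc + dd$digits[(i - 1) * l + p, ] * (TORUS_MOD / Bg^p)
    }
    coefs[, i] <- tmod(acc)
  }
  coefs
}

#' Encrypt a small integer polynomial as a TGSW sample
#'
#' A TGSW sample is `(k+1)*l` TLWE encryptions of zero plus `m` times the
#' gadget matrix `h` (row `(i, p)` carries `1/Bg^p` in component `i`).
#' Subtracting `m*h` from the rows therefore leaves TLWE encryptions of
#' zero, and the external product with a TLWE sample scales its phase
#' by `m`.
#'
#' @param key a `tlwe_key`.
#' @param m integer scalar or length-`N` integer polynomial with small
#'   coefficients (|coef| <= `plaintext_bound`).
#' @param params an [fhe_params] object (supplies the gadget parameters).
#' @param stdev row noise, default `params$stdev_tlwe`.
#' @param plaintext_bound validation bound on `max(abs(m))`, default `Bg/2`.
#' @param seed optional integer seed.
#' @return object of class `tgsw_sample`.
#' @export
tgsw_encrypt <- function(key, m, params, stdev = params$stdev_tlwe,
                         plaintext_bound = params$Bg / 2, seed = NULL) {
  N <- params$N
  k <- params$k
  g <- params$gadget
  l <- g$l
  if (length(m) == 1) m <- c(m, numeric(N - 1))
  stopifnot(length(m) == N)
  if (max(abs(m)) > plaintext_bound) {
    stop("TGSW plaintext exceeds the configured bound")
  }
  with_seed(seed, {
    nr <- (k + 1) * l
    rows <- vector("list", nr)
    for (i in seq_len(k + 1)) {
      for (p in seq_len(l)) {
        z <- tlwe_encrypt(key, numeric(N), params, stdev = stdev)
        # add m * h_{i,p}: the torus constant 2^32/Bg^p in component i,
        # as the polynomial m (exact modular add)
        h_val <- TORUS_MOD / g$Bg^p
        z$coefs[, i] <- tmod(z$coefs[, i] + m * h_val)
        rows[[(i - 1) * l + p]] <- z
      }
    }
    # flattened row matrix consumed by the C++ external-product kernel
    mat <- do.call(rbind, lapply(rows, function(r) as.vector(r$coefs)))
    structure(list(rows = rows, mat = mat, k = k, N = N, g = g,
                   var = stdev^2),
              class = "tgsw_sample")
  })
}

#' @export
print.tgsw_sample <- function(x, ...) {
  cat(sprintf("<tgsw_sample k=%d N=%d l=%d>\n", x$k, x$N, x$g$l))
  invisible(x)
}

#' External product TGSW (x) TLWE -> TLWE
#'
#' Decomposes the TLWE sample into gadget digits and contracts them with
#' the TGSW rows: `out = sum_{i,p} digit_{i,p} (*) row_{i,p}` (negacyclic
#' products). The phase of the output is `m * phase(ct)` up to the additive
#' noise composed from the decomposition error `epsilon` and the TGSW row
#' noise.
#'
#' @param C a `tgsw_sample`.
#' @param ct a `tlwe_sample` with matching `k` and `N`.
#' @param g gadget parameters; defaults to the ones stored in `C`.
#' @return a `tlwe_sample`.
#' @export
external_product <- function(C, ct, g = C$g) {
  if (C$k != ct$k || C$N != ct$N) stop("TGSW/TLWE parameter mismatch")
  dd <- gadget_decompose(ct, g)
  flat <- ext_prod_cpp(dd$digits, C$mat, C$k, C$N)
  coefs <- matrix(flat, nrow = C$N, ncol = C$k + 1)
  # worst-case composition: digit mass times row noise, plus the
  # decomposition error scaled by the (unknown) message bound ~1
  nvar <- (C$k + 1) * g$l * C$N * (g$Bg / 2)^2 * C$var +
    (1 + C$k * C$N) * g$epsilon^2
  new_tlwe_sample(coefs, C$k, C$N, var = ct$var + nvar)
}
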