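#' FHE parameter presets
#'
#' Bundles every dimension and noise parameter of the torus-FHE core.
#' Two presets are provided: `"TOY"` (n = 16, N = 64, k = 1, Bg = 64,
#' l = 3, t = 8) sized for fast tests, and `"DEMO"` (n = 64, N = 256)
#' for the network simulator. Neither preset claims any cryptographic
#' security level; this core is educational.
#'
#' @param preset `"TOY"` or `"DEMO"`.
#' @return an object of class `fhe_params`: a list with LWE dimension `n`,
#'   polynomial degree `N`, mask length `k`, gadget base `Bg` and depth `l`,
#'   key-switching precision `t`, and the three noise standard deviations
#'   (torus scale) `stdev_lwe` (fresh LWE encryptions), `stdev_tlwe`
#'   (TLWE/TGSW rows) and `stdev_ksk` (key-switching key).
#' @export
#' @examples
#' p <- fhe_params("TOY")
#' p$n
fhe_params <- function(preset = c("TOY", "DEMO")) {
  preset <- match.arg(preset)
  p <- switch(preset,
    TOY = list(
      n = 16L, N = 64L, k = 1L, Bg = 64L, l = 3L, t = 8L,
      stdev_lwe = 2^-20, stdev_tlwe = 2^-25, stdev_ksk = 2^-24
    ),
    DEMO = list(
      n = 64L, N = 256L, k = 1L, Bg = 64L, l = 3L, t = 10L,
      stdev_lwe = 2^-22, stdev_tlwe = 2^-27, stdev_ksk = 2^-26
    )
  )
  p$preset <- preset
  p$q <- TORUS_Q
  p$gadget <- gadget_params(p$Bg, p$l)
  class(p) <- "fhe_params"
  p
}

#' @export
print.fhe_params <- function(x, ...) {
  cat(sprintf(
    "<fhe_params %s> n=%d N=%d k=%d Bg=%d l=%d t=%d (educational parameters, no security claim)\n",
    x$preset, x$n, x$N, x$k, x$Bg, x$l, x$t
  ))
  invisible(x)
}

#' Gadget decomposition parameters
#'
#' Base-`Bg`, depth-`l` digit decomposition of torus values to the nearest
#' multiple of `1/Bg^l`; the worst-case reconstruction error is
#' `epsilon = 1/(2*Bg^l)`.
#'
#' @param Bg decomposition base, a power of two `>= 2`.
#' @param l number of levels, `>= 1`.
#' @return object of class `gadget_params` with fields `Bg`, `l`, `epsilon`.
#' @export
gadget_params <- function(Bg, l) {
  stopifnot(Bg >= 2, l >= 1)
  if (log2(Bg) != round(log2(Bg))) stop("Bg must be a power of two")
  if (log2(Bg) * l > TORUS_Q) stop("Bg^l exceeds the torus discretization")
  structure(list(Bg = as.integer(Bg), l = as.integer(l),
                 epsilon = 1 / (2 * Bg^l)),
            class = "gadget_params")
}

#' Two-point message encoding for bootstrapping
#'
#' The bootstrap maps any input ciphertext onto one of two fixed torus
#' messages: phases in the upper half-torus `[0, 1/2)` decrypt to `mu1`,
#' phases in `[1/2, 1)` to `mu0` (a phase of exactly 0 therefore resolves
#' to `mu1`). The derived constants are `mu_bar = (mu0 + mu1)/2` and
#' `mu_bar_prime = mu0 - mu_bar`, held exactly on the discretized torus.
#'
#' @param mu0,mu1 torus fractions (numeric in `[-1/2, 1)`), defaults 0 and
#'   1/8. These defaults are configuration, not fixed by the scheme.
#' @return object of class `message_encoding` with torus-integer fields
#'   `mu0`, `mu1`, `mu_bar`, `mu_bar_prime`.
#' @export
#' @examples
#' message_encoding(0, 1/8)
message_encoding <- function(mu0 = 0, mu1 = 1 / 8) {
  m0 <- to_torus(mu0)
  m1 <- to_torus(mu1)
  # exact halving on the grid: (m0 + m1)/2 rounded half up, then the two
  # defining identities hold exactly in the discretized torus
  mu_bar <- tmod(round_half_up((m0 + m1) / 2))
  mu_bar_prime <- tmod(m0 - mu_bar)
  structure(list(mu0 = m0, mu1 = m1, mu_bar = mu_bar,
                 mu_bar_prime = mu_bar_prime),
            class = "message_encoding")
}
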