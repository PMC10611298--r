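#' @useDynLib fhecare, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median quantile rbinom rgamma uniroot
#'   predict sd var aggregate binomial glm glm.control coef plogis
NULL

# The torus T = R/Z is discretized as integers modulo 2^32: an integer v
# represents the real v / 2^32.  All torus arithmetic is exact modular
# integer arithmetic carried in doubles (every intermediate stays well
# below 2^53, see the individual operations).
TORUS_Q <- 32
TORUS_MOD <- 2^32

#' Reduce values into the discretized torus
#'
#' @param x numeric vector of (possibly signed) integers.
#' @return values reduced modulo `2^32` into `[0, 2^32)`.
#' @keywords internal
tmod <- function(x) x %% TORUS_MOD

#' Convert a real fraction to a discretized torus value
#'
#' Rounds half up, so e.g. `to_torus(5/8)` is exact and ties between grid
#' points resolve deterministically upward.
#'
#' @param frac numeric vector of real numbers (interpreted modulo 1).
#' @return integers in `[0, 2^32)`.
#' @export
to_torus <- function(frac) tmod(floor(frac * TORUS_MOD + 0.5))

#' Convert a discretized torus value back to a real fraction
#'
#' @param v torus values (integers in `[0, 2^32)`).
#' @param signed if `TRUE`, return representatives in `[-1/2, 1/2)` instead
#'   of `[0, 1)`.
#' @return numeric fractions.
#' @export
torus_frac <- function(v, signed = FALSE) {
  f <- tmod(v) / TORUS_MOD
  if (signed) f <- ifelse(f >= 0.5, f - 1, f)
  f
}

# round-half-up, the package-wide tie convention (base round() is
# round-half-even, which would make decomposition ties platform-lore)
round_half_up <- function(x) floor(x + 0.5)

# Gaussian noise on the torus: continuous N(0, stdev) rounded to the grid.
torus_gaussian <- function(m, stdev) {
  if (stdev == 0) return(numeric(m) + 0)
  tmod(round_half_up(rnorm(m, mean = 0, sd = stdev * TORUS_MOD)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# --- negacyclic polynomial helpers (R side; the hot path lives in C++) ---

# Multiply a polynomial (coefficient vector over the torus or integers) by
# X^m in Z[X]/(X^N + 1).  m may be any integer; X^N = -1.
poly_rotate <- function(v, m) {
  N <- length(v)
  m <- m %% (2L * N)
  neg <- FALSE
  if (m >= N) {
    m <- m - N
    neg <- TRUE
  }
  out <- if (m == 0) v else c(-v[(N - m + 1):N], v[seq_len(N - m)])
  if (neg) out <- -out
  tmod(out)
}

# Reference negacyclic product, exact, O(N^2); used by internals only for
# small N (key material and phases) -- products of bits by torus values.
poly_mul_negacyclic <- function(p_int, q_tor) {
  N <- length(p_int)
  acc <- numeric(N)
  for (i in seq_len(N)) {
    d <- p_int[i]
    if (d == 0) next
    acc <- acc + d * poly_rotate(q_tor, i - 1L)
    acc <- tmod(acc)
  }
  tmod(acc)
}
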