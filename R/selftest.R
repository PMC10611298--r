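# The FHE-core property suite: shared by the self-test CLI command, the
# test suite and the acceptance script.

#' Run the FHE-core property suite
#'
#' Exercises the core invariants at the given preset and reports one
#' pass/fail (plus the measured statistic) per property:
#'
#' * `roundtrip`: noisy encrypt/decrypt on an 8-point message space
#'   succeeds in at least 999/1000 seeded trials.
#' * `phase_linearity`: integer-affine combinations compose phases
#'   exactly (modular arithmetic).
#' * `gadget_bound`: 1000 random torus values reconstruct within
#'   `epsilon = 1/(2*Bg^l)`, zero violations.
#' * `external_product`: phase of `TGSW(m) (x) TLWE(u)` matches the
#'   brute-force negacyclic oracle `m * u` at N = 8, k = 1 within the
#'   composed noise bound.
#' * `key_switch`: 500/500 random messages decrypt identically before
#'   and after switching keys.
#' * `bootstrap_refresh`: output-noise variance is flat across input
#'   noise levels spanning a 100-fold variance range.
#'
#' @param preset parameter preset (default `"TOY"`).
#' @param seed master seed.
#' @param trials named list overriding the per-property trial counts
#'   (fields `roundtrip`, `gadget`, `keyswitch`, `refresh`).
#' @param quiet suppress the per-property console report.
#' @return named list of property results (`pass` flag + statistics),
#'   with an overall `pass` attribute.
#' @export
fhe_selftest <- function(preset = "TOY", seed = 1, trials = list(),
                         quiet = FALSE) {
  tr <- utils::modifyList(list(roundtrip = 1000, gadget = 1000,
                               keyswitch = 500, refresh = 200), trials)
  params <- fhe_params(preset)
  out <- list()

  # --- roundtrip with noise ---
  out$roundtrip <- with_seed(seed, {
    key <- lwe_keygen(params)
    ok <- 0L
    for (i in seq_len(tr$roundtrip)) {
      m <- sample(0:7, 1)
      ct <- lwe_encrypt(key, to_torus(m / 8), params, stdev = 2^-10)
      ok <- ok + as.integer(lwe_decrypt(key, ct, 8) == m)
    }
    list(pass = ok >= ceiling(999 / 1000 * tr$roundtrip), successes = ok,
         trials = tr$roundtrip)
  })

  # --- phase linearity (exact) ---
  out$phase_linearity <- with_seed(seed + 1, {
    key <- lwe_keygen(params)
    ok <- TRUE
    for (i in 1:50) {
      k <- sample(2:5, 1)
      cts <- lapply(seq_len(k), function(j) {
        lwe_encrypt(key, to_torus(runif(1)), params)
      })
      cf <- sample(-4:4, k, replace = TRUE)
      lhs <- lwe_phase(key, lwe_affine_combine(cts, cf))
      rhs <- tmod(sum(cf * vapply(cts, function(ct) lwe_phase(key, ct), 0)))
      ok <- ok && (lhs == rhs)
    }
    list(pass = ok)
  })

  # --- gadget bound ---
  out$gadget_bound <- with_seed(seed + 2, {
    g <- params$gadget
    viol <- 0L
    worst <- 0
    for (i in seq_len(ceiling(tr$gadget / params$N))) {
      coefs <- matrix(tmod(floor(runif(params$N * (params$k + 1)) *
                                   TORUS_MOD)),
                      params$N, params$k + 1)
      ct <- new_tlwe_sample(coefs, params$k, params$N)
      dd <- gadget_decompose(ct, g)
      err <- abs(torus_frac(tmod(gadget_reconstruct(dd) - coefs),
                            signed = TRUE))
      worst <- max(worst, max(err))
      viol <- viol + sum(err > g$epsilon)
    }
    list(pass = viol == 0, violations = viol, worst = worst,
         epsilon = g$epsilon)
  })

  # --- external-product oracle equivalence at N = 8, k = 1 ---
  out$external_product <- with_seed(seed + 3, {
    sp <- fhe_params(preset)
    sp$N <- 8L
    key <- tlwe_keygen(sp)
    ok <- TRUE
    worst <- 0
    for (i in 1:20) {
      u <- to_torus(runif(sp$N))
      m <- sample(-2:2, sp$N, replace = TRUE)
      ct <- tlwe_encrypt(key, u, sp, stdev = 0)
      C <- tgsw_encrypt(key, m, sp, stdev = 0)
      got <- tlwe_phase(key, external_product(C, ct))
      want <- poly_mul_negacyclic(m, u) # independent brute-force oracle
      err <- max(abs(torus_frac(tmod(got - want), signed = TRUE)))
      # all noise here is decomposition error: |m|_1 * N * epsilon bound
      bound <- sum(abs(m)) * sp$gadget$epsilon * (1 + sp$k * sp$N)
      worst <- max(worst, err)
      ok <- ok && err <= bound
    }
    list(pass = ok, worst = worst)
  })

  # --- key switching preserves decryption ---
  out$key_switch <- with_seed(seed + 4, {
    src <- lwe_keygen(params)
    dst <- lwe_keygen(params)
    ksk <- keyswitch_keygen(src, dst, params)
    ok <- 0L
    for (i in seq_len(tr$keyswitch)) {
      m <- sample(0:7, 1)
      ct <- lwe_encrypt(src, to_torus(m / 8), params)
      ct2 <- key_switch(ksk, ct)
      ok <- ok + as.integer(lwe_decrypt(src, ct, 8) == m &&
                              lwe_decrypt(dst, ct2, 8) == m)
    }
    list(pass = ok == tr$keyswitch, successes = ok,
         trials = tr$keyswitch)
  })

  # --- bootstrap refresh: output noise independent of input noise ---
  out$bootstrap_refresh <- with_seed(seed + 5, {
    key <- lwe_keygen(params)
    keyset <- make_bootstrap_keyset(key, params)
    enc <- message_encoding(0, 1 / 8)
    stdevs <- c(2^-18, 2^-18 * sqrt(10), 2^-18 * 10) # 100x variance span
    vars <- vapply(stdevs, function(sd) {
      dev <- vapply(seq_len(tr$refresh), function(i) {
        m <- sample(c(-1, 1), 1) / 4
        ct <- lwe_encrypt(key, to_torus(m), params, stdev = sd)
        out_ct <- bootstrap(keyset, enc, ct)
        want <- if (m > 0) enc$mu1 else enc$mu0
        torus_frac(tmod(lwe_phase(key, out_ct) - want), signed = TRUE)
      }, 0)
      var(dev)
    }, 0)
    ratio <- max(vars) / min(vars)
    list(pass = ratio < 2, variances = vars, ratio = ratio)
  })

  for (nm in names(out)) {
    if (!quiet) {
      cat(sprintf("%-18s %s\n", nm,
                  if (isTRUE(out[[nm]]$pass)) "PASS" else "FAIL"))
    }
  }
  attr(out, "pass") <- all(vapply(out, function(p) isTRUE(p$pass), TRUE))
  invisible(out)
}
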