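test_that("noiseless LWE encryption round-trips every message exactly", {
  p <- toy_params()
  key <- with_seed(1, lwe_keygen(p))
  for (m in 0:7) {
    ct <- lwe_encrypt(key, to_torus(m / 8), p, stdev = 0, seed = m)
    expect_identical(lwe_decrypt(key, ct, 8), m)
    expect_equal(lwe_phase(key, ct), to_torus(m / 8))
  }
  # a phase exactly halfway between message points rounds half up
  half <- new_lwe_sample(numeric(p$n), to_torus(1 / 16))
  expect_identical(lwe_decrypt(key, half, 8), 1L)
})

test_that("noisy decryption succeeds at the Gaussian-tail rate", {
  # stdev 2^-10 on an 8-point space: failure needs |e| > 1/16, i.e. a
  # 64-sigma event; the analytic tail bound makes 1000/1000 all but sure
  p <- toy_params()
  key <- with_seed(2, lwe_keygen(p))
  ok <- with_seed(3, {
    sum(vapply(1:1000, function(i) {
      m <- sample(0:7, 1)
      ct <- lwe_encrypt(key, to_torus(m / 8), p, stdev = 2^-10)
      lwe_decrypt(key, ct, 8) == m
    }, TRUE))
  })
  expect_gte(ok, 999)
})

test_that("phases combine exactly under integer-affine arithmetic", {
  p <- toy_params()
  key <- with_seed(4, lwe_keygen(p))
  c1 <- lwe_encrypt(key, to_torus(1 / 8), p, seed = 5)
  c2 <- lwe_encrypt(key, to_torus(1 / 16), p, seed = 6)
  # (2, -1): phase 2/8 - 1/16 = 3/16 plus composed noise
  out <- lwe_affine_combine(list(c1, c2), c(2, -1))
  drift <- torus_frac(tmod(lwe_phase(key, out) - to_torus(3 / 16)),
                      signed = TRUE)
  expect_lt(abs(drift), 2^-15)
  # identity and all-zero coefficients
  expect_equal(lwe_phase(key, lwe_affine_combine(list(c1), 1)),
               lwe_phase(key, c1))
  expect_equal(lwe_phase(key, lwe_affine_combine(list(c1, c2), c(0, 0))), 0)
  expect_error(lwe_affine_combine(list(), numeric(0)), "empty")
  # property: exact modular composition over random cases
  with_seed(7, {
    for (i in 1:25) {
      k <- sample(2:6, 1)
      cts <- lapply(seq_len(k), function(j) {
        lwe_encrypt(key, to_torus(runif(1)), p)
      })
      cf <- sample(-7:7, k, replace = TRUE)
      lhs <- lwe_phase(key, lwe_affine_combine(cts, cf))
      rhs <- tmod(sum(cf * vapply(cts, function(ct) lwe_phase(key, ct), 0)))
      expect_identical(lhs, rhs)
    }
  })
})

test_that("gadget decomposition picks the nearest multiple with bounded error", {
  g <- gadget_params(4, 2)
  p <- toy_params()
  mk <- function(frac) {
    coefs <- matrix(0, p$N, p$k + 1)
    coefs[1, p$k + 1] <- to_torus(frac)
    new_tlwe_sample(coefs, p$k, p$N)
  }
  # zero sample -> zero digits
  dd0 <- gadget_decompose(mk(0), g)
  expect_true(all(dd0$digits == 0))
  body_rows <- p$k * g$l + 1:2 # body-block digit rows for k = 1, l = 2
  # 1/4 with Bg=4, l=2: digits (1, 0), exact
  dd1 <- gadget_decompose(mk(1 / 4), g)
  expect_equal(unname(dd1$digits[body_rows, 1]), c(1, 0))
  # 0.3 with Bg=4, l=2: digits (1, 1), reconstructing 5/16
  dd2 <- gadget_decompose(mk(0.3), g)
  expect_equal(unname(dd2$digits[body_rows, 1]), c(1, 1))
  rec <- 1 / 4 + 1 / 16
  expect_lte(abs(rec - 0.3), 1 / 32)
  # exhaustive check that (1,1) is the nearest valid 2-digit decomposition
  best <- Inf
  for (d1 in -1:2) for (d2 in -1:2) {
    best <- min(best, abs(d1 / 4 + d2 / 16 - 0.3))
  }
  expect_equal(abs(rec - 0.3), best)
})

test_that("gadget reconstruction error never exceeds epsilon", {
  p <- toy_params()
  g <- p$gadget
  with_seed(8, {
    for (i in 1:8) {
      coefs <- matrix(tmod(floor(runif(p$N * (p$k + 1)) * 2^32)),
                      p$N, p$k + 1)
      ct <- new_tlwe_sample(coefs, p$k, p$N)
      dd <- gadget_decompose(ct, g)
      expect_true(all(dd$digits > -g$Bg / 2 & dd$digits <= g$Bg / 2))
      err <- abs(torus_frac(tmod(gadget_reconstruct(dd) - coefs),
                            signed = TRUE))
      expect_lte(max(err), g$epsilon)
      # determinism
      expect_identical(dd$digits, gadget_decompose(ct, g)$digits)
    }
  })
})

test_that("TGSW rows are zero-encryptions shifted by m times the gadget", {
  p <- toy_params()
  key <- with_seed(9, tlwe_keygen(p))
  # m = 0: every row decrypts to ~0
  C0 <- tgsw_encrypt(key, 0, p, seed = 10)
  for (r in C0$rows) {
    expect_lt(max(abs(torus_frac(tlwe_phase(key, r), signed = TRUE))),
              2^-18)
  }
  # m = 1: row (i, p) has phase ~ h entry (visible in the body block)
  C1 <- tgsw_encrypt(key, 1, p, seed = 11)
  for (pp in seq_len(p$gadget$l)) {
    row <- C1$rows[[p$k * p$gadget$l + pp]]
    ph <- tlwe_phase(key, row)
    expect_lt(abs(torus_frac(tmod(ph[1] - 2^32 / p$Bg^pp),
                             signed = TRUE)), 2^-18)
  }
  expect_error(tgsw_encrypt(key, p$Bg, p), "bound")
})

test_that("the external product matches the brute-force negacyclic oracle", {
  sp <- toy_params()
  sp$N <- 8L
  key <- with_seed(12, tlwe_keygen(sp))
  with_seed(13, {
    for (i in 1:10) {
      u <- to_torus(runif(sp$N))
      m <- sample(-2:2, sp$N, replace = TRUE)
      ct <- tlwe_encrypt(key, u, sp, stdev = 0)
      C <- tgsw_encrypt(key, m, sp, stdev = 0)
      got <- tlwe_phase(key, external_product(C, ct))
      want <- oracle_negacyclic(m, u)
      err <- max(abs(torus_frac(tmod(got - want), signed = TRUE)))
      bound <- sum(abs(m)) * (1 + sp$k * sp$N) * sp$gadget$epsilon
      expect_lte(err, bound)
    }
  })
  # multiplication by one / by zero at full TOY size
  p <- toy_params()
  key <- with_seed(14, tlwe_keygen(p))
  mu <- to_torus(with_seed(15, runif(p$N)))
  ct <- tlwe_encrypt(key, mu, p, seed = 16)
  one <- external_product(tgsw_encrypt(key, 1, p, seed = 17), ct)
  expect_lt(max(abs(torus_frac(tmod(tlwe_phase(key, one) - mu),
                               signed = TRUE))), 2^-12)
  zero <- external_product(tgsw_encrypt(key, 0, p, seed = 18), ct)
  expect_lt(max(abs(torus_frac(tlwe_phase(key, zero), signed = TRUE))),
            2^-12)
  # X^2 rotates the message (negacyclic)
  m_x2 <- c(0, 0, 1, numeric(p$N - 3))
  rot <- external_product(tgsw_encrypt(key, m_x2, p, seed = 19), ct)
  expect_lt(max(abs(torus_frac(tmod(tlwe_phase(key, rot) -
                                      poly_rotate(mu, 2)),
                               signed = TRUE))), 2^-12)
})

test_that("key switching preserves every message", {
  p <- toy_params()
  src <- with_seed(20, lwe_keygen(p))
  dst <- with_seed(21, lwe_keygen(p))
  ksk <- keyswitch_keygen(src, dst, p, seed = 22)
  # noiseless zero-mask ciphertext
  triv <- new_lwe_sample(numeric(p$n), to_torus(3 / 8))
  expect_identical(lwe_decrypt(dst, key_switch(ksk, triv), 8), 3L)
  with_seed(23, {
    for (i in 1:60) {
      m <- sample(0:7, 1)
      ct <- lwe_encrypt(src, to_torus(m / 8), p)
      expect_identical(lwe_decrypt(dst, key_switch(ksk, ct), 8), m)
    }
  })
  expect_error(key_switch(ksk, new_lwe_sample(numeric(p$n + 1), 0)),
               "source")
})

test_that("the mask rounding step is the identity at full precision", {
  p <- toy_params()
  p$t <- TORUS_Q
  # with t = q the nearest multiple of 2^-t is the value itself
  a <- tmod(floor(with_seed(24, runif(10)) * 2^32))
  abar <- round_half_up(a / 2^(TORUS_Q - p$t)) %% 2^p$t
  expect_identical(abar, a)
})

test_that("the test vector is the staircase the sign selection needs", {
  enc <- message_encoding(0, 1 / 8)
  tv <- make_test_vector(enc, 4)
  expect_length(tv, 4)
  expect_true(all(tv == enc$mu_bar_prime))
  # mu_bar_prime = 0 gives the zero polynomial
  enc0 <- message_encoding(1 / 8, 1 / 8)
  expect_true(all(make_test_vector(enc0, 8) == 0))
  # rotating by X^N negates all coefficients (negacyclic wrap)
  tv8 <- make_test_vector(enc, 8)
  expect_equal(poly_rotate(tv8, 8), tmod(-tv8))
  expect_error(make_test_vector(enc, 3))
})

test_that("blind rotation matches a cleartext rotation oracle", {
  p <- toy_params()
  keys <- toy_keys()
  lk <- keys$secret$lwe
  xk <- keys$secret$extracted
  bk <- keys$eval$bk
  enc <- message_encoding(0, 1 / 8)
  testv <- make_test_vector(enc, p$N)
  # all-zero ciphertext: output phase is testv's constant coefficient
  z <- new_lwe_sample(numeric(p$n), 0)
  out <- blind_rotate_and_extract(bk, testv, z)
  expect_lt(abs(torus_frac(tmod(lwe_phase(xk, out) - testv[1]),
                           signed = TRUE)), 2^-12)
  # random inputs vs the cleartext oracle: rotate testv by the true
  # rescaled phase and read the constant coefficient
  with_seed(25, {
    for (i in 1:6) {
      ct <- lwe_encrypt(lk, to_torus(runif(1)), p, grid = 2 * p$N)
      phase_slots <- round_half_up(lwe_phase(lk, ct) * 2 * p$N / 2^32) %%
        (2 * p$N)
      want <- poly_rotate(testv, -phase_slots)[1]
      got <- lwe_phase(xk, blind_rotate_and_extract(bk, testv, ct))
      expect_lt(abs(torus_frac(tmod(got - want), signed = TRUE)), 2^-12)
    }
  })
})

test_that("bootstrapping selects the encoded message by phase sign", {
  p <- toy_params()
  keys <- toy_keys()
  lk <- keys$secret$lwe
  enc <- message_encoding(0, 1 / 8)
  up <- lwe_encrypt(lk, to_torus(1 / 4), p, seed = 26)
  down <- lwe_encrypt(lk, to_torus(-1 / 4), p, seed = 27)
  expect_identical(lwe_decrypt(lk, bootstrap(keys$eval, enc, up), 8), 1L)
  expect_identical(lwe_decrypt(lk, bootstrap(keys$eval, enc, down), 8), 0L)
  # phase exactly 0 is the documented mu1 side of the boundary
  zero <- lwe_encrypt(lk, 0, p, stdev = 0, grid = 2 * p$N, seed = 28)
  expect_identical(lwe_decrypt(lk, bootstrap(keys$eval, enc, zero), 8), 1L)
})

test_that("bootstrapping output noise does not depend on input noise", {
  p <- toy_params()
  keys <- toy_keys()
  lk <- keys$secret$lwe
  enc <- message_encoding(0, 1 / 8)
  vars <- with_seed(29, {
    vapply(c(2^-18, 2^-14), function(sd) {
      dev <- vapply(1:40, function(i) {
        m <- sample(c(-1, 1), 1) / 4
        ct <- lwe_encrypt(lk, to_torus(m), p, stdev = sd)
        out <- bootstrap(keys$eval, enc, ct)
        want <- if (m > 0) enc$mu1 else enc$mu0
        torus_frac(tmod(lwe_phase(lk, out) - want), signed = TRUE)
      }, 0)
      var(dev)
    }, 0)
  })
  # 256-fold input variance gap, output variances within a small factor
  expect_lt(max(vars) / min(vars), 3)
})
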