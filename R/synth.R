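# Seeded synthetic generators for the heart-disease schema and for
# patient sensor streams.  The default feature ranges are loosely modeled
# on published summary statistics of the UCI Cleveland table but the data
# are explicitly synthetic: no claim of distributional fidelity is made.

#' Generate a synthetic heart-disease dataset
#'
#' Draws the 14 schema attributes from fixed marginal distributions and
#' the disease label from a logistic model over standardized features
#' whose intercept is calibrated so the expected prevalence matches
#' `prevalence`; the multi-level `num` target expands label 1 into
#' severity levels 1-4. Deterministic under `seed`.
#'
#' @param n number of patients.
#' @param prevalence disease prevalence in `(0, 1)` (default 0.46, about
#'   the Cleveland rate).
#' @param missing_rate probability in `[0, 1)` that any non-target cell
#'   is replaced by a missing marker.
#' @param seed integer seed (default 0).
#' @param effects named numeric vector of logistic effect sizes on the
#'   standardized feature scale (defaults chosen to give an informative
#'   but noisy signal).
#' @return heart-schema data frame with attributes `source`
#'   (`"synthetic"`) and `effects`.
#' @export
generate_heart_data <- function(n, prevalence = 0.46, missing_rate = 0,
                                seed = 0, effects = NULL) {
  stopifnot(prevalence > 0, prevalence < 1, missing_rate >= 0,
            missing_rate < 1, n >= 1)
  if (is.null(effects)) {
    effects <- c(age = 0.4, sex = 0.6, cp = 0.8, trestbps = 0.25,
                 chol = 0.2, fbs = 0.1, restecg = 0.15, thalach = -0.7,
                 exang = 0.8, oldpeak = 0.9, slope = 0.4, ca = 0.9,
                 thal = 0.7)
  }
  ds <- with_seed(seed, {
    d <- data.frame(
      age = round(rnorm(n, 54, 9)),
      sex = rbinom(n, 1, 0.68),
      cp = sample(1:4, n, replace = TRUE, prob = c(0.08, 0.17, 0.28, 0.47)),
      trestbps = round(rnorm(n, 131, 17)),
      chol = round(rnorm(n, 246, 51)),
      fbs = rbinom(n, 1, 0.15),
      restecg = sample(0:2, n, replace = TRUE, prob = c(0.49, 0.01, 0.5)),
      thalach = round(rnorm(n, 150, 23)),
      exang = rbinom(n, 1, 0.33),
      oldpeak = round(rgamma(n, shape = 1.2, scale = 0.9), 1),
      slope = sample(1:3, n, replace = TRUE, prob = c(0.47, 0.46, 0.07)),
      ca = sample(0:3, n, replace = TRUE, prob = c(0.58, 0.22, 0.13, 0.07)),
      thal = sample(c(3, 6, 7), n, replace = TRUE,
                    prob = c(0.55, 0.06, 0.39))
    )
    z <- scale(as.matrix(d))
    z[is.nan(z)] <- 0
    lp <- as.vector(z %*% effects[colnames(d)])
    # calibrate the intercept so mean(plogis(lp + c)) == prevalence
    cal <- uniroot(function(c0) mean(plogis(lp + c0)) - prevalence,
                   interval = c(-30, 30))$root
    disease <- rbinom(n, 1, plogis(lp + cal))
    d$num <- ifelse(disease == 1,
                    sample(1:4, n, replace = TRUE,
                           prob = c(0.4, 0.26, 0.26, 0.08)),
                    0L)
    d
  })
  if (missing_rate > 0) {
    ds <- inject_missing(ds, missing_rate, seed = seed + 1L)
  }
  attr(ds, "source") <- "synthetic"
  attr(ds, "effects") <- effects
  validate_heart(ds)
  ds
}

#' Inject missing values
#'
#' Independently replaces each non-target cell by `NA` with probability
#' `rate`; the target column `num` is never masked.
#'
#' @param ds heart-schema data frame.
#' @param rate probability in `[0, 1)`.
#' @param seed integer seed.
#' @return the data frame with missing markers.
#' @export
inject_missing <- function(ds, rate, seed = 0) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(ds)
  cols <- setdiff(names(ds), "num")
  with_seed(seed, {
    for (cn in cols) {
      mask <- runif(nrow(ds)) < rate
      ds[[cn]][mask] <- NA
    }
  })
  ds
}

#' Generate a linearly separable two-class fixture
#'
#' Gaussian features labelled by the sign of a known linear score, with
#' points closer than `margin/2` to the boundary pushed out, so the
#' classes are separable with margin `margin`. The generating weights are
#' recorded in the `weights` attribute (training-sanity and
#' parameter-recovery oracles). Both classes are always present, even at
#' tiny `n`.
#'
#' @param n number of rows.
#' @param margin separation margin (> 0, default 1).
#' @param seed integer seed.
#' @param d number of features (default 2).
#' @param noise standard deviation of label-independent feature noise
#'   added after labelling (default 0: perfectly separable).
#' @return data frame `x1..xd` plus binary `label`, with attribute
#'   `weights` (the unit generating vector).
#' @export
make_separable_fixture <- function(n, margin = 1, seed = 0, d = 2,
                                   noise = 0) {
  stopifnot(margin > 0, n >= 2)
  with_seed(seed, {
    w <- rnorm(d)
    w <- w / sqrt(sum(w^2))
    X <- matrix(rnorm(n * d), n, d)
    s <- as.vector(X %*% w)
    lab <- as.integer(s >= 0)
    # guarantee both classes
    if (all(lab == 1)) lab[which.min(s)] <- 0L
    if (all(lab == 0)) lab[which.max(s)] <- 1L
    # push points outside the margin band
    shift <- (margin / 2 - s) * (lab == 1 & s < margin / 2) -
      (s + margin / 2) * (lab == 0 & s > -margin / 2)
    X <- X + outer(shift, w)
    if (noise > 0) X <- X + matrix(rnorm(n * d, sd = noise), n, d)
    out <- as.data.frame(X)
    names(out) <- paste0("x", seq_len(d))
    out$label <- lab
    attr(out, "weights") <- w
    out
  })
}

#' Generate per-patient heart-rate sensor streams
#'
#' Each patient gets a time series whose maximum heart rate lands in the
#' requested severity band for their age (severe / moderate / slight,
#' matching the scheduler's three modes). Optionally corrupts whole
#' records (missing vitals) to exercise the consistency-check
#' termination path.
#'
#' @param patients data frame with columns `id` and `age`.
#' @param severity character vector (one of `"severe"`, `"moderate"`,
#'   `"slight"` per patient).
#' @param ticks samples per stream (default 12).
#' @param corruption_rate probability a stream is corrupted (default 0).
#' @param seed integer seed.
#' @param thresholds severity thresholds, see [mode_select].
#' @return list of data frames (`tick`, `heart_rate`, `age`, `id`), one
#'   per patient, with a `corrupted` attribute each.
#' @export
generate_sensor_stream <- function(patients, severity, ticks = 12,
                                   corruption_rate = 0, seed = 0,
                                   thresholds = severity_thresholds()) {
  stopifnot(nrow(patients) == length(severity))
  with_seed(seed, {
    lapply(seq_len(nrow(patients)), function(i) {
      age <- patients$age[i]
      hr_max <- 220 - age
      sev <- severity[i]
      # target peak inside the requested band
      peak <- switch(sev,
        severe = max(thresholds$severe_frac * hr_max,
                     thresholds$severe_abs) + 8,
        moderate = (max(thresholds$moderate_frac * hr_max,
                        thresholds$moderate_abs) +
                    max(thresholds$severe_frac * hr_max,
                        thresholds$severe_abs)) / 2,
        slight = min(thresholds$moderate_frac * hr_max,
                     thresholds$moderate_abs) - 15,
        stop("unknown severity")
      )
      base <- pmin(peak - 5, 70 + 20 * runif(ticks))
      hr <- round(c(base[-ticks], peak) + rnorm(ticks, 0, 2))
      hr[ticks] <- round(peak) # the max lands the band deterministically
      df <- data.frame(tick = seq_len(ticks), heart_rate = hr,
                       age = age, id = patients$id[i])
      corrupted <- runif(1) < corruption_rate
      if (corrupted) df$heart_rate[sample(ticks, 1)] <- NA
      attr(df, "corrupted") <- corrupted
      df
    })
  })
}
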