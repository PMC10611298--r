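test_that("missing values are imputed or dropped deterministically", {
  df <- data.frame(a = c(1, 2, 3, NA), b = c(0, 0, 1, 1))
  out <- handle_missing(df, "impute", categorical = "b")
  expect_identical(out$a[4], 2) # median of 1,2,3
  df2 <- data.frame(a = c(1, NA, 3), b = c(1, 2, 3))
  expect_identical(nrow(handle_missing(df2, "drop")), 2L)
  # identity when nothing is missing
  expect_identical(handle_missing(df2[c(1, 3), ], "impute"),
                   df2[c(1, 3), ])
  # mode imputation for categoricals
  dfc <- data.frame(cat = c(7, 7, 3, NA))
  expect_identical(handle_missing(dfc, "impute", categorical = "cat")$cat[4],
                   7)
  expect_error(handle_missing(data.frame(x = c(NA, NA))), "entirely")
})

test_that("one-hot encoding emits exactly one indicator per row", {
  df <- data.frame(cp = c(1, 2, 3, 4, 2), sex = c(0, 1, 0, 1, 1))
  out <- one_hot_encode(df, columns = c("cp", "sex"))
  cp_cols <- grep("^cp_", names(out), value = TRUE)
  expect_length(cp_cols, 4)
  expect_true(all(rowSums(out[, cp_cols]) == 1))
  sex_cols <- grep("^sex_", names(out), value = TRUE)
  expect_length(sex_cols, 2)
  expect_true(all(out$sex_0 + out$sex_1 == 1))
  # transform with the learned levels; unseen level errors by default
  lv <- attr(out, "onehot_levels")
  df_new <- data.frame(cp = c(2, 5), sex = c(0, 1))
  expect_error(one_hot_encode(df_new, c("cp", "sex"), levels = lv),
               "unseen")
  ok <- one_hot_encode(df_new[1, ], c("cp", "sex"), levels = lv)
  expect_identical(ok$cp_2, 1L)
})

test_that("the 80:20 split is a seeded stratified partition", {
  ds <- data.frame(x = seq_len(100), disease = rep(c(0, 1), c(54, 46)))
  sp <- split_dataset(ds, seed = 0)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$test), 20L)
  # partition: disjoint with union the full data
  expect_identical(sort(c(sp$train$x, sp$test$x)), ds$x)
  # reproducibility
  sp2 <- split_dataset(ds, seed = 0)
  expect_identical(sp$train$x, sp2$train$x)
  # stratification: train prevalence within one record of 46%
  expect_lte(abs(sum(sp$train$disease) - 0.8 * 46), 1)
  # property over random sizes and seeds
  with_seed(43, {
    for (i in 1:10) {
      n <- sample(20:200, 1)
      d <- data.frame(x = seq_len(n),
                      disease = rbinom(n, 1, runif(1, 0.2, 0.8)))
      if (length(unique(d$disease)) < 2) next
      s <- split_dataset(d, seed = i)
      expect_identical(nrow(s$train), as.integer(round_half_up(0.8 * n)))
      expect_identical(sort(c(s$train$x, s$test$x)), d$x)
    }
  })
})

test_that("min-max normalization uses train statistics only", {
  train <- data.frame(a = c(2, 4, 6), b = c(1, 1, 1))
  test <- data.frame(a = c(8, 2), b = c(5, 1))
  expect_warning(nm <- min_max_normalize(train, test), "constant")
  expect_equal(nm$train$a, c(0, 0.5, 1))
  # test rescaled by TRAIN bounds, unclipped
  expect_equal(nm$test$a, c(1.5, 0))
  expect_equal(nm$train$b, c(0, 0, 0))
  # no test leakage: the map is an affine function of train bounds alone
  b <- nm$bounds$a
  expect_equal(nm$test$a, (test$a - b["min"]) / (b["max"] - b["min"]),
               ignore_attr = TRUE)
})

test_that("balanced class weights reproduce their defining identity", {
  # the three documented prime-server weight pairs
  w1 <- compute_class_weights(rep(c(0, 1), c(33, 28)))
  expect_equal(round(as.numeric(w1), 8), c(0.92424242, 1.08928571))
  w2 <- compute_class_weights(rep(c(0, 1), c(130, 79)))
  expect_equal(round(as.numeric(w2), 8), c(0.80384615, 1.32278481))
  w3 <- compute_class_weights(rep(c(0, 1), c(16, 54)))
  expect_equal(round(as.numeric(w3), 8), c(2.1875, 0.64814815))
  expect_equal(as.numeric(compute_class_weights(rep(c(0, 1), c(50, 50)))),
               c(1, 1))
  expect_error(compute_class_weights(rep(1, 10)), "both classes")
  # identity sum_c w_c * count_c == n holds exactly, property-tested
  with_seed(44, {
    for (i in 1:25) {
      y <- rbinom(sample(10:500, 1), 1, runif(1, 0.1, 0.9))
      if (length(unique(y)) < 2) next
      w <- compute_class_weights(y)
      counts <- attr(w, "counts")
      expect_identical(sum(unclass(w) * counts), as.numeric(length(y)))
    }
  })
})

test_that("the full preprocessing pipeline emits a trainable design", {
  ds <- generate_heart_data(250, seed = 45, missing_rate = 0.04)
  prep <- preprocess_heart(ds, seed = 1)
  expect_identical(nrow(prep$train$x) + nrow(prep$test$x), 250L)
  expect_identical(nrow(prep$train$x), 200L)
  # all normalized train columns within [0, 1]
  expect_true(all(prep$train$x >= 0 & prep$train$x <= 1))
  expect_false(anyNA(prep$train$x))
  # one-hot blocks sum to one per source column
  cp_cols <- grep("^cp_", colnames(prep$train$x))
  expect_true(all(rowSums(prep$train$x[, cp_cols]) == 1))
})
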