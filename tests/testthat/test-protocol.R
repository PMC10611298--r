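test_that("mode selection applies age-adjusted thresholds with severe ties", {
  rec <- function(hr, age) data.frame(heart_rate = hr, age = age)
  expect_identical(as.integer(mode_select(rec(180, 40))), 1L)
  expect_identical(as.integer(mode_select(rec(c(80, 85, 90), 40))), 3L)
  expect_identical(as.integer(mode_select(rec(140, 40))), 2L)
  # absolute cutoffs apply at any age
  expect_identical(as.integer(mode_select(rec(151, 20))), 1L)
  # a value exactly at a threshold takes the more severe mode
  expect_identical(as.integer(mode_select(rec(0.9 * (220 - 40), 40))), 1L)
  expect_identical(as.integer(mode_select(rec(110, 20))), 2L)
  expect_error(mode_select(rec(NA, 40)), "missing vitals")
  expect_error(mode_select(data.frame(heart_rate = numeric(),
                                      age = numeric())), "no sensor")
})

test_that("training events retrain exactly the unsignalled primes", {
  cloud <- federated_topology(3, 1)
  calls <- character()
  r1 <- training_event(cloud, 0, retrain = function(id) {
    calls <<- c(calls, id)
  })
  expect_identical(calls, c("PS1", "PS2", "PS3"))
  expect_true(r1$ready)
  expect_match(r1$message, "still under training")
  # all signals set: ready, no retraining
  r2 <- training_event(cloud, 0, retrain = function(id) stop("no"))
  expect_true(r2$ready)
  expect_identical(r2$retrained, character(0))
  expect_match(r2$message, "ready state")
  # a non-event date is a no-op
  r3 <- training_event(cloud, 1, is_event_date = FALSE)
  expect_match(r3$message, "no action")
})

test_that("the federated queue bounds occupancy and drains FIFO", {
  cloud <- federated_topology(2, 1, queue_capacity = 2)
  cloud$signals[] <- TRUE
  mk <- function(id, origin = "LS1") test_set(list(), origin, 3, id)
  expect_identical(submit_job(cloud, mk("a")), "accepted")
  expect_identical(submit_job(cloud, mk("b")), "accepted")
  expect_identical(submit_job(cloud, mk("c")), "waiting")
  expect_identical(submit_job(cloud, mk("d")), "waiting")
  expect_length(cloud$queues$LS1, 2)
  # completion frees a slot and admits the oldest waiter first
  fhecare:::complete_job(cloud, mk("a"))
  expect_identical(vapply(cloud$queues$LS1, `[[`, "", "batch_id"),
                   c("b", "c"))
  expect_error(submit_job(cloud, mk("x", origin = "EVIL")),
               "not authorized")
  # conservation: accepted + waiting + completed == submitted
  cnt <- cloud$counters
  expect_identical(cnt$accepted + cnt$waiting, cnt$submitted)
})

test_that("dispatch plans realize the three scheduler disciplines", {
  cloud <- federated_topology(3, 1)
  cloud$signals[] <- TRUE
  recs <- replicate(25, structure(list(arity = 1), class = "x"),
                    simplify = FALSE)
  # Mode 1: parallel fan-out to every prime in the same tick
  p1 <- dispatch_testset(cloud, test_set(recs[1], "LS1", 1))
  expect_length(p1$steps, 3)
  expect_setequal(vapply(p1$steps, `[[`, "", "server"), cloud$primes)
  expect_identical(unique(vapply(p1$steps, `[[`, 0L, "tick")), cloud$tick)
  expect_true(all(vapply(p1$steps, `[[`, TRUE, "parallel")))
  # Mode 2: relay chain, each prime exactly once in roster order
  p2 <- dispatch_testset(cloud, test_set(recs[1], "PS1", 2))
  expect_identical(vapply(p2$steps, `[[`, "", "server"),
                   c("PS1", "PS2", "PS3"))
  expect_identical(diff(vapply(p2$steps, `[[`, 0L, "tick")), c(1L, 1L))
  # Mode 3: 25 patients split into batches of 10, 10, 5
  p3 <- dispatch_testset(cloud, test_set(recs, "LS1", 3))
  batches <- unique(lapply(p3$steps, `[[`, "batch"))
  expect_length(batches, ceiling(25 / 10))
  expect_identical(vapply(batches, length, 0L), c(10L, 10L, 5L))
  expect_true(all(vapply(batches, length, 0L) <= 10))
  expect_error(dispatch_testset(cloud, test_set(recs[1], "LS1", 9)),
               "Invalid Request")
})

test_that("aggregation follows the exclude-origin branches", {
  cloud <- federated_topology(3, 1)
  preds <- list(PS1 = "r1", PS2 = "r2", PS3 = "r3")
  # local origin: all three entries arrive via the cloud
  rs_local <- aggregate_results(cloud, test_set(list(), "LS1", 1), preds)
  expect_length(rs_local$entries, 3)
  expect_setequal(rs_local$via_cloud, cloud$primes)
  expect_false(rs_local$origin_own_added)
  expect_true(rs_local$complete)
  # prime origin: two entries via the cloud plus the origin's own result
  rs_prime <- aggregate_results(cloud, test_set(list(), "PS2", 1), preds)
  expect_setequal(rs_prime$via_cloud, c("PS1", "PS3"))
  expect_true(rs_prime$origin_own_added)
  expect_length(rs_prime$entries, 3)
  expect_true(rs_prime$complete)
  # one prime offline: flagged incomplete
  rs_off <- aggregate_results(cloud, test_set(list(), "LS1", 1),
                              preds[c("PS1", "PS3")])
  expect_false(rs_off$complete)
})

test_that("consistency checks terminate corrupted submissions", {
  env <- toy_scheme_env()
  keys <- toy_keys()
  rec <- encrypted_record(keys, rep(1L, 5), env$scheme, seed = 50)
  ok <- test_set(list(rec), "PS1", 1)
  expect_identical(as.character(check_consistency(ok)), "ok")
  # truncated ciphertext
  broken <- rec
  broken$cts[[2]]$a <- c(NA, broken$cts[[2]]$a[-1])
  bad <- check_consistency(test_set(list(broken), "PS1", 1))
  expect_identical(as.character(bad), "corrupted")
  # batch of 11 in Mode 3 violates the size bound
  eleven <- test_set(rep(list(rec), 11), "PS1", 3)
  expect_identical(as.character(check_consistency(eleven)), "corrupted")
  expect_match(attr(check_consistency(eleven), "reason"), "10")
})

test_that("reminders fire once per pending patient at week boundaries", {
  expect_length(reminder_tick(character(), TRUE), 0)
  r <- reminder_tick(c("p1", "p2"), TRUE)
  expect_identical(unname(r),
                   rep("Your results evaluation is pending.", 2))
  expect_identical(names(r), c("p1", "p2"))
  expect_length(reminder_tick(c("p1", "p2"), FALSE), 0)
})

test_that("the examiner averages sealed results and reseals for the patient", {
  env <- seal_envelope("p1", "examiner", list(PS1 = 0.2, PS2 = 0.4,
                                              PS3 = 0.9))
  rep_env <- examiner_review("p1", env)
  expect_identical(rep_env$recipient, "p1")
  report <- unseal(rep_env, "p1")
  expect_equal(report$score, 0.5)
  # identical scores average to themselves
  env2 <- seal_envelope("p1", "examiner", list(a = 0.7, b = 0.7, c = 0.7))
  expect_equal(unseal(examiner_review("p1", env2), "p1")$score, 0.7)
  # a report sealed to the wrong patient is rejected on the patient side
  expect_error(unseal(rep_env, "p2"), "sealed for")
  expect_error(examiner_review("p1", env, examiner_id = "impostor"),
               "sealed for")
})
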