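# Discrete-event simulation of the federated hospital network: mode-based
# job scheduling, bounded per-server cloud queues, training events,
# exclude-origin result aggregation, reminders and the examiner loop.
#
# The cloud and server state lives in an environment (reference
# semantics) so queue operations mutate in place, as the discrete-event
# loop expects.

#' Severity thresholds for the scheduler
#'
#' A patient is `severe` when the maximum observed heart rate is at least
#' `severe_frac * (220 - age)` or at least `severe_abs` bpm; `moderate`
#' analogously with the moderate cutoffs; otherwise `slight`. A value
#' exactly at a threshold takes the more severe mode.
#'
#' @param severe_frac,severe_abs,moderate_frac,moderate_abs cutoffs
#'   (defaults 0.9/150 and 0.75/110).
#' @return list of thresholds.
#' @export
severity_thresholds <- function(severe_frac = 0.9, severe_abs = 150,
                                moderate_frac = 0.75, moderate_abs = 110) {
  list(severe_frac = severe_frac, severe_abs = severe_abs,
       moderate_frac = moderate_frac, moderate_abs = moderate_abs)
}

#' Select the scheduler mode from recent sensor records
#'
#' Takes the maximum heart rate over the submitted records and applies
#' the age-adjusted thresholds: severe maps to Mode 1 (parallel fan-out),
#' moderate to Mode 2 (relay chain), slight to Mode 3 (buffered batches).
#'
#' @param records data frame with `heart_rate` and `age` columns (one
#'   patient's recent stream).
#' @param thresholds see [severity_thresholds].
#' @return object of class `scheduler_mode`: integer 1, 2 or 3 with a
#'   `severity` attribute.
#' @export
mode_select <- function(records, thresholds = severity_thresholds()) {
  if (nrow(records) == 0) stop("no sensor records")
  if (any(is.na(records$heart_rate)) || any(is.na(records$age))) {
    stop("missing vitals in the sensor records")
  }
  hr <- max(records$heart_rate)
  age <- records$age[1]
  hr_max <- 220 - age
  sev <- if (hr >= thresholds$severe_frac * hr_max ||
             hr >= thresholds$severe_abs) {
    "severe"
  } else if (hr >= thresholds$moderate_frac * hr_max ||
             hr >= thresholds$moderate_abs) {
    "moderate"
  } else {
    "slight"
  }
  mode <- c(severe = 1L, moderate = 2L, slight = 3L)[[sev]]
  structure(mode, severity = sev, class = "scheduler_mode")
}

#' @export
print.scheduler_mode <- function(x, ...) {
  cat(sprintf("Mode %d (%s)\n", unclass(x), attr(x, "severity")))
  invisible(x)
}

#' Build a federated network topology
#'
#' Prime servers hold trained models and compute; local servers may only
#' submit encrypted test sets. The cloud keeps one bounded job queue per
#' authorized server plus a FIFO wait queue.
#'
#' @param n_prime number of prime servers (>= 1).
#' @param n_local number of local servers.
#' @param queue_capacity per-server federated-queue capacity (default 10).
#' @return an environment of class `federated_cloud` with the roster,
#'   queues, training signals, model registry and event log.
#' @export
federated_topology <- function(n_prime = 3, n_local = 1,
                               queue_capacity = 10) {
  stopifnot(n_prime >= 1, n_local >= 0, queue_capacity >= 1)
  cloud <- new.env(parent = emptyenv())
  cloud$primes <- paste0("PS", seq_len(n_prime))
  cloud$locals <- if (n_local > 0) paste0("LS", seq_len(n_local)) else character()
  cloud$authorized <- c(cloud$primes, cloud$locals)
  cloud$capacity <- queue_capacity
  cloud$queues <- setNames(vector("list", length(cloud$authorized)),
                           cloud$authorized)
  cloud$wait_queue <- list()
  cloud$signals <- setNames(rep(FALSE, n_prime), cloud$primes)
  cloud$models <- list()
  cloud$log <- list()
  cloud$tick <- 0L
  cloud$counters <- list(submitted = 0L, accepted = 0L, waiting = 0L,
                         completed = 0L)
  class(cloud) <- c("federated_cloud", "environment")
  cloud
}

#' @export
print.federated_cloud <- function(x, ...) {
  cat(sprintf("<federated_cloud %d prime / %d local, queue capacity %d>\n",
              length(x$primes), length(x$locals), x$capacity))
  invisible(x)
}

# structured event log; server-side payloads are recorded only as digests
log_event <- function(cloud, actor, kind, detail = "") {
  cloud$log[[length(cloud$log) + 1L]] <- list(
    tick = cloud$tick, actor = actor, kind = kind, detail = detail
  )
  invisible(NULL)
}

# tiny stable content digest for payload provenance (not cryptographic)
payload_digest <- function(x) {
  s <- paste(utils::capture.output(str(x, give.attr = FALSE)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 2^31)
}

#' Run a training event on the cloud
#'
#' Event 0 is the start-of-week retraining, event 1 the start-of-month
#' one. Every prime server whose training signal is unset is retrained
#' (the `retrain` callback is invoked and its signal set); when all
#' signals are set the cloud is ready.
#'
#' @param cloud a `federated_cloud`.
#' @param event 0 (weekly) or 1 (monthly).
#' @param is_event_date does the current date match the event (default
#'   `TRUE`; pass `FALSE` for a non-event tick, which is a no-op).
#' @param retrain callback `function(prime_id)` performing the training;
#'   default records the event only.
#' @return list with `ready` (all signals set), `retrained` (ids), and
#'   the printed status `message`.
#' @export
training_event <- function(cloud, event, is_event_date = TRUE,
                           retrain = function(id) NULL) {
  stopifnot(event %in% c(0, 1))
  if (!is_event_date) {
    return(list(ready = all(cloud$signals), retrained = character(),
                message = "no action (not the event date)"))
  }
  retrained <- character()
  if (all(cloud$signals)) {
    msg <- "All prime servers are in ready state"
  } else {
    msg <- "Prime server is still under training"
    for (id in cloud$primes[!cloud$signals]) {
      retrain(id)
      cloud$signals[id] <- TRUE
      retrained <- c(retrained, id)
      log_event(cloud, id, "retrain",
                sprintf("event=%d", event))
    }
  }
  log_event(cloud, "cloud", "training_event", msg)
  list(ready = all(cloud$signals), retrained = retrained, message = msg)
}

#' Build an encrypted test set
#'
#' @param records list of `encrypted_record`s.
#' @param origin submitting server id.
#' @param mode a [mode_select] result (or integer 1-3).
#' @param batch_id identifier.
#' @return object of class `test_set`.
#' @export
test_set <- function(records, origin, mode, batch_id = "b1") {
  structure(list(records = records, origin = origin,
                 mode = as.integer(mode), batch_id = batch_id),
            class = "test_set")
}

#' Consistency check on a submitted test set
#'
#' Validates the schema arity of every ciphertext vector, the ciphertext
#' well-formedness, and the Mode-3 batch bound (at most 10 patients). A
#' corrupted set terminates that job, it does not crash the cloud.
#'
#' @param ts a `test_set`.
#' @param arity expected feature count (default: taken from the first
#'   record).
#' @return `"ok"` or `"corrupted"` (with a `reason` attribute).
#' @export
check_consistency <- function(ts, arity = NULL) {
  bad <- function(reason) structure("corrupted", reason = reason)
  if (!length(ts$records)) return(bad("empty test set"))
  if (ts$mode == 3 && length(ts$records) > 10) {
    return(bad("Mode-3 batch exceeds 10 patients"))
  }
  if (is.null(arity)) arity <- ts$records[[1]]$arity
  for (r in ts$records) {
    if (!inherits(r, "encrypted_record")) return(bad("not a ciphertext"))
    if (r$arity != arity) return(bad("schema arity mismatch"))
    for (ct in r$cts) {
      if (!inherits(ct, "lwe_sample") || anyNA(ct$a) || anyNA(ct$b)) {
        return(bad("malformed ciphertext"))
      }
    }
  }
  "ok"
}

#' Submit a test set to the federated cloud
#'
#' Enqueued when the origin's federated queue has a free slot, otherwise
#' placed in the cloud's FIFO wait queue.
#'
#' @param cloud a `federated_cloud`.
#' @param ts a `test_set` whose `origin` must be an authorized server.
#' @return `"accepted"` or `"waiting"`.
#' @export
submit_job <- function(cloud, ts) {
  if (!ts$origin %in% cloud$authorized) {
    stop(sprintf("server '%s' is not authorized", ts$origin))
  }
  cloud$counters$submitted <- cloud$counters$submitted + 1L
  if (length(cloud$queues[[ts$origin]]) < cloud$capacity) {
    cloud$queues[[ts$origin]] <- c(cloud$queues[[ts$origin]], list(ts))
    cloud$counters$accepted <- cloud$counters$accepted + 1L
    log_event(cloud, "cloud", "job_accepted",
              sprintf("origin=%s batch=%s payload=%s", ts$origin,
                      ts$batch_id, payload_digest(ts)))
    "accepted"
  } else {
    cloud$wait_queue <- c(cloud$wait_queue, list(ts))
    cloud$counters$waiting <- cloud$counters$waiting + 1L
    log_event(cloud, "cloud", "job_waiting",
              "Request in wait queue of the cloud server")
    "waiting"
  }
}

# pop a finished job from the origin queue and drain the wait queue FIFO
complete_job <- function(cloud, ts) {
  q <- cloud$queues[[ts$origin]]
  keep <- !vapply(q, function(j) identical(j$batch_id, ts$batch_id), TRUE)
  cloud$queues[[ts$origin]] <- q[keep]
  cloud$counters$completed <- cloud$counters$completed + 1L
  if (length(cloud$wait_queue)) {
    nxt <- cloud$wait_queue[[1]]
    if (length(cloud$queues[[nxt$origin]]) < cloud$capacity) {
      cloud$wait_queue <- cloud$wait_queue[-1]
      cloud$queues[[nxt$origin]] <- c(cloud$queues[[nxt$origin]], list(nxt))
      cloud$counters$waiting <- cloud$counters$waiting - 1L
      cloud$counters$accepted <- cloud$counters$accepted + 1L
      log_event(cloud, "cloud", "job_dequeued_from_wait",
                sprintf("origin=%s", nxt$origin))
    }
  }
  invisible(NULL)
}

#' Plan the dispatch of a test set across the prime servers
#'
#' Mode 1 (severe): simultaneous fan-out, one parallel job per prime in
#' the same tick. Mode 2 (moderate): a relay chain in roster order, each
#' prime visited exactly once, appending its result. Mode 3 (slight):
#' batches of at most 10 patients forwarded at the configured flush
#' interval (1-5 simulated minutes), results gathered back to the
#' initiating server. Any other mode value is rejected ("Invalid
#' Request").
#'
#' @param cloud a `federated_cloud`.
#' @param ts a `test_set`.
#' @param flush_interval Mode-3 flush interval in simulated seconds
#'   (default 60, must lie in `[60, 300]`).
#' @return object of class `job_plan`: list of steps with `server`,
#'   `tick`, `batch` (record indices) and `parallel` fields.
#' @export
dispatch_testset <- function(cloud, ts, flush_interval = 60) {
  if (!ts$mode %in% 1:3) stop("Invalid Request")
  if (!all(cloud$signals)) stop("prime servers are not all trained")
  primes <- cloud$primes
  steps <- switch(as.character(ts$mode),
    "1" = lapply(primes, function(p) {
      list(server = p, tick = cloud$tick, batch = seq_along(ts$records),
           parallel = TRUE)
    }),
    "2" = lapply(seq_along(primes), function(i) {
      list(server = primes[i], tick = cloud$tick + i - 1L,
           batch = seq_along(ts$records), parallel = FALSE)
    }),
    "3" = {
      stopifnot(flush_interval >= 60, flush_interval <= 300)
      nb <- ceiling(length(ts$records) / 10)
      unlist(lapply(seq_len(nb), function(b) {
        idx <- ((b - 1) * 10 + 1):min(b * 10, length(ts$records))
        lapply(primes, function(p) {
          list(server = p,
               tick = cloud$tick + as.integer((b - 1) * flush_interval),
               batch = idx, parallel = FALSE)
        })
      }), recursive = FALSE)
    }
  )
  log_event(cloud, "cloud", "dispatch",
            sprintf("mode=%d steps=%d origin=%s", ts$mode, length(steps),
                    ts$origin))
  structure(list(steps = steps, mode = ts$mode, origin = ts$origin,
                 batch_id = ts$batch_id),
            class = "job_plan")
}

#' Aggregate per-prime-server predictions into a result set
#'
#' When the origin is itself a prime server, the cloud collects the other
#' N-1 primes' results and the origin's own result is appended
#' separately; for a local-server origin all N results flow through the
#' cloud. The result set is complete when every roster prime contributed.
#'
#' @param cloud a `federated_cloud`.
#' @param ts the originating `test_set`.
#' @param predictions named list (by prime id) of prediction payloads
#'   (e.g. `encrypted_prediction`s); missing entries mark offline primes.
#' @return object of class `result_set` with `entries`, `via_cloud`,
#'   `origin_own`, and `complete`.
#' @export
aggregate_results <- function(cloud, ts, predictions) {
  primes <- cloud$primes
  origin_is_prime <- ts$origin %in% primes
  via <- if (origin_is_prime) setdiff(primes, ts$origin) else primes
  entries <- predictions[names(predictions) %in% via]
  origin_own <- if (origin_is_prime) predictions[[ts$origin]] else NULL
  if (origin_is_prime && !is.null(origin_own)) {
    entries[[ts$origin]] <- origin_own
  }
  complete <- all(primes %in% names(entries))
  log_event(cloud, "cloud", "aggregate",
            sprintf("origin=%s via_cloud=%d own=%d complete=%s",
                    ts$origin, length(via), as.integer(origin_is_prime),
                    complete))
  structure(list(entries = entries, via_cloud = via,
                 origin_own_added = origin_is_prime,
                 complete = complete, batch_id = ts$batch_id),
            class = "result_set")
}

#' Sealed envelope (abstract public-key sealing)
#'
#' Models the PK1/PK2 sealed-message contract of the patient-examiner
#' exchange: the payload is readable only through [unseal] by the named
#' recipient. This is an access-control simulation, not real public-key
#' cryptography.
#'
#' @param sender,recipient identity strings.
#' @param payload any R object.
#' @param kind message kind label.
#' @return object of class `sealed_envelope`.
#' @export
seal_envelope <- function(sender, recipient, payload, kind = "message") {
  structure(list(sender = sender, recipient = recipient, kind = kind,
                 .payload = payload),
            class = "sealed_envelope")
}

#' Open a sealed envelope
#'
#' @param env a `sealed_envelope`.
#' @param identity the opener; must equal the envelope's recipient.
#' @return the payload.
#' @export
unseal <- function(env, identity) {
  if (!inherits(env, "sealed_envelope")) stop("not a sealed envelope")
  if (!identical(env$recipient, identity)) {
    stop(sprintf("envelope sealed for '%s', not '%s'", env$recipient,
                 identity))
  }
  env$.payload
}

#' Weekly reminder tick
#'
#' At a week boundary every pending patient (results delivered but not
#' yet forwarded for review) receives exactly one reminder with the text
#' "Your results evaluation is pending."; mid-week ticks send nothing.
#'
#' @param pending character vector of pending patient ids.
#' @param is_week_start is the current date a week boundary.
#' @return named character vector of reminder texts (one per patient).
#' @export
reminder_tick <- function(pending, is_week_start) {
  if (!is_week_start || length(pending) == 0) {
    return(setNames(character(0), character(0)))
  }
  setNames(rep("Your results evaluation is pending.", length(pending)),
           pending)
}

#' Examiner review of a patient's results
#'
#' The examiner unseals the forwarded results (sealed under the hospital
#' key PK2), averages the per-prime scores, attaches a disposition and
#' returns the report sealed under the patient key PK1.
#'
#' @param patient_id patient identity (PK1 holder).
#' @param envelope results sealed to `examiner_id`.
#' @param examiner_id examiner identity (PK2 holder).
#' @param aggregate `"mean"` (default) or `"majority"`.
#' @return a `sealed_envelope` for the patient containing `score`,
#'   `disposition` and the per-server values.
#' @export
examiner_review <- function(patient_id, envelope,
                            examiner_id = "examiner",
                            aggregate = c("mean", "majority")) {
  aggregate <- match.arg(aggregate)
  results <- unseal(envelope, examiner_id)
  vals <- as.numeric(unlist(results))
  score <- if (aggregate == "mean") mean(vals) else {
    as.numeric(mean(vals) >= 0.5)
  }
  disposition <- if (score >= 0.5) "follow-up recommended" else "routine"
  seal_envelope(examiner_id, patient_id,
                list(score = score, disposition = disposition,
                     per_server = results),
                kind = "evaluation_report")
}
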