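# End-to-end discrete-event simulation: sensor stream -> consistency
# check -> encryption -> hospital -> cloud queue -> mode dispatch ->
# encrypted inference on every prime server -> exclude-origin
# aggregation -> patient decryption -> consent -> examiner review ->
# sealed report; with reminders at week boundaries and a privacy audit
# over everything the servers ever see.

# wire-format view of a payload as the servers see it: sealed envelopes
# are opaque (kind + digest), everything else is serialized in full
serialize_for_wire <- function(x) {
  if (inherits(x, "sealed_envelope")) {
    return(sprintf("sealed[%s->%s:%s:%s]", x$sender, x$recipient, x$kind,
                   payload_digest(x$.payload)))
  }
  paste(utils::capture.output(str(x, give.attr = FALSE, vec.len = 1e6,
                                  digits.d = 12)),
        collapse = "\n")
}

record_server_message <- function(cloud, from, to, kind, payload) {
  cloud$server_messages[[length(cloud$server_messages) + 1L]] <- list(
    from = from, to = to, kind = kind, wire = serialize_for_wire(payload)
  )
  log_event(cloud, to, kind,
            sprintf("from=%s payload=%s", from,
                    if (inherits(payload, "sealed_envelope")) {
                      "sealed"
                    } else payload_digest(payload)))
  invisible(NULL)
}

#' Simulation scenario configuration
#'
#' @param n_prime,n_local topology (defaults 3 prime, 1 local).
#' @param n_patients number of simulated patients (default 5).
#' @param preset FHE parameter preset for the patient keys (default
#'   `"TOY"`).
#' @param queue_capacity per-server federated queue size (default 10).
#' @param corruption_rate probability a patient's sensor stream is
#'   corrupted (default 0).
#' @param severities severity labels recycled over patients (default
#'   cycles severe/moderate/slight so all three modes are exercised).
#' @param n_train per-prime synthetic training set size (default 160).
#' @param seed master seed.
#' @return config list of class `sim_config`.
#' @export
sim_config <- function(n_prime = 3, n_local = 1, n_patients = 5,
                       preset = "TOY", queue_capacity = 10,
                       corruption_rate = 0,
                       severities = c("severe", "moderate", "slight"),
                       n_train = 160, seed = 0) {
  structure(list(n_prime = n_prime, n_local = n_local,
                 n_patients = n_patients, preset = preset,
                 queue_capacity = queue_capacity,
                 corruption_rate = corruption_rate,
                 severities = severities, n_train = n_train, seed = seed),
            class = "sim_config")
}

#' Run the full federated-network simulation
#'
#' Embodies the end-to-end flow under a seeded discrete-event clock: each
#' prime server trains a (quantized, logistic) classifier on its own
#' synthetic cohort; each patient's sensor stream selects a scheduler
#' mode; records are quantized, encrypted under the patient's key and
#' submitted through the patient's hospital; the cloud queues and
#' dispatches jobs per mode; every prime evaluates its model
#' homomorphically; results are aggregated (exclude-origin when the
#' origin is a prime), returned, decrypted by the patient, forwarded with
#' consent to the examiner and averaged into a sealed report.
#'
#' @param config a [sim_config].
#' @return object of class `sim_run`: list with `reports` (per patient),
#'   `log` (event list), `cloud` (final state), `patients` (harness-side
#'   ground truth for auditing), and `counters`.
#' @export
simulate_run <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), config$n_prime >= 1)
  params <- fhe_params(config$preset)
  features <- default_features()
  cloud <- federated_topology(config$n_prime, config$n_local,
                              config$queue_capacity)
  cloud$server_messages <- list()

  # --- shared quantization scheme from a public reference cohort ---
  ref <- generate_heart_data(200, seed = config$seed)
  ref <- handle_missing(ref)
  scheme <- quantization_scheme(ref[, features], bits = 3, params = params)

  # --- weekly training event: every prime fits its private model ---
  models <- list()
  training_event(cloud, 0, retrain = function(id) {
    i <- match(id, cloud$primes)
    d <- generate_heart_data(config$n_train, seed = config$seed + 100 + i)
    d <- binarize_target(handle_missing(d))
    cw <- compute_class_weights(d$disease)
    fit <- fit_classifier("logistic", as.matrix(d[, features]),
                          d$disease, weights = cw,
                          seed = config$seed + i)
    cf <- coef(fit)
    models[[id]] <<- quantize_linear_model(cf$weights, cf$bias, scheme)
  })
  cloud$models <- models

  # --- patients: identity, hospital, keys, stream, clinical record ---
  pts <- generate_heart_data(config$n_patients,
                             seed = config$seed + 500)
  pts <- handle_missing(pts)
  hospitals <- rep(cloud$authorized, length.out = config$n_patients)
  severities <- rep(config$severities, length.out = config$n_patients)
  patient_tbl <- data.frame(id = paste0("pat", seq_len(config$n_patients)),
                            age = pts$age)
  streams <- generate_sensor_stream(patient_tbl, severities,
                                    corruption_rate = config$corruption_rate,
                                    seed = config$seed + 900)
  patients <- lapply(seq_len(config$n_patients), function(i) {
    keys <- patient_keygen(params, patient_tbl$id[i],
                           seed = config$seed + 1000 + i)
    raw <- as.numeric(pts[i, features])
    # out-of-calibration values clamp (already surfaced in the event log
    # via the consistency check, not as a console warning)
    q <- withCallingHandlers(
      quantize_record(raw, scheme),
      warning = function(w) invokeRestart("muffleWarning")
    )
    list(id = patient_tbl$id[i], hospital = hospitals[i], keys = keys,
         raw = raw, q = q,
         stream = streams[[i]], severity = severities[i])
  })

  # --- per-patient pipeline ---
  reports <- list()
  pending <- character()
  for (p in patients) {
    cloud$tick <- cloud$tick + 1L
    if (isTRUE(attr(p$stream, "corrupted"))) {
      log_event(cloud, p$hospital, "job_terminated",
                sprintf("%s: sensor data corrupted, process terminated",
                        p$id))
      reports[[p$id]] <- list(id = p$id, status = "terminated")
      next
    }
    mode <- mode_select(p$stream)
    rec <- encrypted_record(p$keys, p$q, scheme,
                            seed = config$seed + 2000 +
                              match(p$id, patient_tbl$id))
    record_server_message(cloud, p$id, p$hospital, "encrypted_upload",
                          rec)
    ts <- test_set(list(rec), p$hospital, mode,
                   batch_id = paste0("job_", p$id))
    stat <- check_consistency(ts, arity = length(features))
    if (!identical(as.character(stat), "ok")) {
      log_event(cloud, p$hospital, "job_terminated",
                "The patient's test set is corrupted")
      reports[[p$id]] <- list(id = p$id, status = "corrupted")
      next
    }
    log_event(cloud, p$hospital, "consistency",
              "The patient's test set is consistent and ready to be processed")
    record_server_message(cloud, p$hospital, "cloud", "job_submit", ts)
    status <- submit_job(cloud, ts)
    plan <- dispatch_testset(cloud, ts)
    preds <- list()
    for (step in plan$steps) {
      srv <- step$server
      record_server_message(cloud, "cloud", srv, "fhe_eval_request", ts)
      pred <- enc_linear_predict(cloud$models[[srv]], rec,
                                 p$keys$eval, server = srv,
                                 model_name = "logistic")
      preds[[srv]] <- pred
      record_server_message(cloud, srv, "cloud", "fhe_eval_result", pred)
      if (!step$parallel) cloud$tick <- cloud$tick + 1L
    }
    rs <- aggregate_results(cloud, ts, preds)
    complete_job(cloud, ts)
    record_server_message(cloud, "cloud", p$hospital, "result_set", rs)
    # patient side: decrypt each prime's encrypted label
    labels <- lapply(rs$entries, function(pr) decrypt_result(p$keys, pr))
    reports[[p$id]] <- list(id = p$id, status = "delivered", mode = mode,
                            labels = labels, result_set = rs)
    pending <- c(pending, p$id)
  }

  # --- week boundary: reminders for everyone still pending ---
  cloud$tick <- cloud$tick + 1L
  reminders <- reminder_tick(pending, is_week_start = TRUE)
  for (id in names(reminders)) {
    log_event(cloud, "hospital", "reminder", reminders[[id]])
  }

  # --- consent, examiner review, sealed report ---
  for (p in patients) {
    rep_i <- reports[[p$id]]
    if (!identical(rep_i$status, "delivered")) next
    env <- seal_envelope(p$id, "examiner", rep_i$labels,
                         kind = "consented_results")
    record_server_message(cloud, p$id, p$hospital, "forward_results", env)
    record_server_message(cloud, p$hospital, "examiner", "forward_results",
                          env)
    report_env <- examiner_review(p$id, env)
    record_server_message(cloud, "examiner", p$hospital, "report", report_env)
    report <- unseal(report_env, p$id)
    # harness-side oracle: what each prime's plaintext quantized model says
    oracle <- vapply(cloud$primes, function(srv) {
      as.numeric(predict(cloud$models[[srv]], p$q))
    }, 0)
    reports[[p$id]] <- c(rep_i[setdiff(names(rep_i), "result_set")],
                         list(score = report$score,
                              disposition = report$disposition,
                              oracle_mean = mean(oracle)))
  }

  structure(list(reports = reports, log = cloud$log, cloud = cloud,
                 patients = patients, counters = cloud$counters,
                 config = config),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  done <- sum(vapply(x$reports, function(r) identical(r$status, "delivered"),
                     TRUE))
  cat(sprintf("<sim_run %d patients, %d completed reports, %d events>\n",
              length(x$reports), done, length(x$log)))
  invisible(x)
}

#' Privacy audit of a simulation run
#'
#' Taint-tracking over every server-side message: scans the wire
#' serialization of everything the hospital, cloud and prime servers ever
#' received for each patient's raw feature signature, quantized feature
#' signature, and decrypted per-server label sequence. The only
#' legitimate plaintext sites are the patient and the examiner.
#'
#' @param run a `sim_run`.
#' @return list with `leaks` (total count), and `details` per patient.
#' @export
audit_privacy <- function(run) {
  wires <- vapply(run$cloud$server_messages, function(m) {
    if (m$to %in% c("examiner")) "" else m$wire
  }, "")
  blob <- paste(wires, collapse = "\n")
  details <- lapply(run$patients, function(p) {
    sig_raw <- paste(sprintf("%g", p$raw), collapse = ", ")
    sig_q <- paste(p$q, collapse = ", ")
    hits <- c(raw = grepl(sig_raw, blob, fixed = TRUE),
              quantized = grepl(sig_q, blob, fixed = TRUE))
    lab <- run$reports[[p$id]]$labels
    if (!is.null(lab)) {
      sig_lab <- paste(unlist(lab), collapse = ", ")
      # labels are short signatures; only flag them in combination with
      # the patient id to avoid false positives on unrelated integers
      hits <- c(hits, labels = grepl(paste0(p$id, ".*", sig_lab), blob))
    }
    hits
  })
  names(details) <- vapply(run$patients, `[[`, "", "id")
  list(leaks = sum(unlist(details)), details = details)
}
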