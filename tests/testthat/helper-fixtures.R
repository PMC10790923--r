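# Shared fixtures built in code at test time.

tiny_recording <- function(seed = 1, n_s = 2, condition = "baseline",
                           with_ecg = FALSE, hr = NULL) {
  set.seed(seed)
  n <- n_s * 10
  od <- array(rnorm(8 * 2 * n), dim = c(8, 2, n))
  accel <- matrix(rnorm(3 * n_s * 512), 3)
  if (is.null(hr)) hr <- 60 + rnorm(n)
  events <- data.frame(label = "rest", start_s = 0, end_s = n_s)
  session_recording(sprintf("p%02d", seed), condition, od, accel,
                    ecg = if (with_ecg) rnorm(n_s * 250) else NULL,
                    hr = hr, events = events)
}

# one fully preprocessed game session (cached per seed/condition)
.proc_cache <- new.env()
cached_processed <- function(participant, condition, cfg = NULL) {
  key <- paste(participant, condition, sep = "_")
  if (is.null(.proc_cache[[key]])) {
    if (is.null(cfg)) cfg <- sim_config()
    s <- simulate_session(cfg, participant, condition)
    .proc_cache[[key]] <- list(rec = s$recording, truth = s$truth,
                               proc = preprocess_session(s$recording))
  }
  .proc_cache[[key]]
}
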