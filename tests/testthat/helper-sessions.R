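# Shared fixtures: small synthetic sessions built once per test run.

fixture_env <- new.env(parent = emptyenv())

# memoised small session so several test files can share one render
test_session <- function(key = "default", ...) {
  if (!exists(key, fixture_env)) {
    args <- list(...)
    if (is.null(args$block_duration)) args$block_duration <- 120
    if (is.null(args$seed)) args$seed <- 42
    cfg <- do.call(synth_config, args)
    assign(key, synth_session(cfg), fixture_env)
  }
  get(key, fixture_env)
}

# session -> detected & labeled events plus preprocessed EEG
detect_and_preprocess <- function(s, detector = onset_detector_config(),
                                  preproc = preproc_config()) {
  thr <- estimate_noise_threshold(s$imu, detector, s$imu_rate)
  ev <- detect_onsets(s$imu, thr, detector, s$imu_rate)
  lf <- label_and_filter(ev, s$imu, detector, s$imu_rate)
  pre <- preprocess_session(s, preproc)
  list(session = pre, threshold = thr, events = lf$events,
       scored = lf$scored_events, labels = lf$labels)
}

# hold out a fraction of epochs for testing, keeping all jittered windows of
# one rotation on the same side (epoch-level splits leak: overlapping windows
# of a rotation share noise, letting the net recognize them)
group_holdout <- function(ds, frac = 0.25, seed = 1) {
  grp <- ifelse(is.na(ds$event_id), paste0("n", seq_along(ds$event_id)),
                paste0("e", ds$event_id))
  groups <- unique(grp)
  set.seed(seed)
  te_groups <- sample(groups, round(frac * length(groups)))
  te_idx <- which(grp %in% te_groups)
  list(train = headbci:::subset_epochs(ds, setdiff(seq_along(grp), te_idx)),
       test = headbci:::subset_epochs(ds, te_idx))
}

# a tiny end-to-end experiment configuration used by model-level tests
mini_experiment <- function(seed, rp_amplitude, lateralization_fraction = 0.7,
                            block_duration = 100, epochs = 15,
                            do_streaming = FALSE) {
  experiment_config(
    n_participants = 1,
    synth = synth_config(block_duration = block_duration,
                         rp_amplitude = rp_amplitude,
                         lateralization_fraction = lateralization_fraction,
                         artifact_rate = 0, seed = seed),
    split = split_spec(n_repetitions = 1),
    model = model_config(epochs = epochs, seed = seed),
    do_streaming = do_streaming, do_erp = FALSE,
    seed = seed)
}
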