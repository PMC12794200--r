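# Shared fixtures, built once per test run and memoised across files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# high-SNR encoding used for parameter-recovery runs: the angle-locked
# components dominate the background so the feasibility claim is testable at
# desk scale
high_snr_encoding <- function(seed = 101) {
  encoding_config(angle_gain = 50, background_scale = 4, alpha_amplitude = 4,
                  beta_amplitude = 2, mrcp_amplitude = 4, blink_rate_hz = 0.05,
                  line_noise_uv = 1, seed = seed)
}

# 40-trial high-SNR subject: windowed dataset with 4 test trials and 3 folds
recovery_dataset <- function() {
  fixture("recovery_dataset", function() {
    proto <- protocol_config(n_sessions = 4, trials_per_session = 10)
    trials <- simulate_subject(proto, high_snr_encoding())
    ang <- compute_angle_epochs(trials)
    prep <- preprocess_subject(sessions_from_trials(trials), seed = 5)
    build_window_dataset(prep$epochs, ang, shuffle_seed = 1,
                         n_test = 4, n_folds = 3)
  })
}

# 30-trial subject split into 10 folds of 2 trials for chance calibration
chance_dataset <- function() {
  fixture("chance_dataset", function() {
    proto <- protocol_config(n_sessions = 3, trials_per_session = 10)
    trials <- simulate_subject(proto, high_snr_encoding(seed = 202))
    ang <- compute_angle_epochs(trials)
    prep <- preprocess_subject(sessions_from_trials(trials), seed = 6)
    build_window_dataset(prep$epochs, ang, shuffle_seed = 2,
                         n_test = 10, n_folds = 10)
  })
}

# small cleaned subject for preprocessing/signature checks
small_clean_subject <- function() {
  fixture("small_clean_subject", function() {
    proto <- protocol_config(n_sessions = 2, trials_per_session = 5)
    enc <- encoding_config(angle_gain = 25, background_scale = 5, seed = 11)
    trials <- simulate_subject(proto, enc)
    list(trials = trials,
         angle_epochs = compute_angle_epochs(trials),
         prep = preprocess_subject(sessions_from_trials(trials), seed = 5))
  })
}

# fabricate a window_dataset with a planted linear mapping from one channel's
# mean to the label; tiny and fast for training-loop tests
toy_dataset <- function(n_trials = 12, n_test = 2, n_folds = 2, seed = 3) {
  withr::with_seed(seed, {
    wpt <- 121
    n <- n_trials * wpt
    windows <- array(rnorm(32 * 100 * n, sd = 0.5), c(32, 100, n))
    labels <- runif(n, 0, 2 * pi)
    for (i in seq_len(n)) {
      windows[1, , i] <- windows[1, , i] + cos(labels[i])
      windows[2, , i] <- windows[2, , i] + sin(labels[i])
    }
    trial_ids <- rep(seq_len(n_trials), each = wpt)
    structure(list(
      windows = windows, labels = labels, trial_ids = trial_ids,
      split = split_dataset(seq_len(n_trials), shuffle_seed = seed,
                            n_test = n_test, n_folds = n_folds),
      channel_stats = NULL, windows_per_trial = wpt
    ), class = "window_dataset")
  })
}

# build synthetic clean_epoch lists directly (for signature tests)
make_epochs <- function(n_trials, builder, rate = 100, n = 700, seed = 1) {
  labs <- montage_1010_32()$channel
  withr::with_seed(seed, lapply(seq_len(n_trials), function(i) {
    eeg <- builder(i)
    rownames(eeg) <- labs
    structure(list(eeg = eeg, rate = rate, trial_id = i),
              class = "clean_epoch")
  }))
}

tiny_specs_for_gradients <- function() {
  list(
    shallow = decoder_spec("shallow", use_lstm = TRUE, n_channels = 5,
                           n_samples = 60, dropout = 0,
                           first_layer_filters = 3, lstm_units = 4),
    deep = decoder_spec("deep", use_lstm = TRUE, n_channels = 5,
                        n_samples = 100, dropout = 0,
                        first_layer_filters = 2, lstm_units = 4),
    eegnet = decoder_spec("eegnet", use_lstm = TRUE, n_channels = 6,
                          n_samples = 80, dropout = 0,
                          first_layer_filters = 2, lstm_units = 5)
  )
}
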