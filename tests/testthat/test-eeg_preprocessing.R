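test_that("notch filter suppresses 50 Hz and passes 10 Hz", {
  fs <- 256
  tt <- (0:(fs * 8 - 1)) / fs
  s50 <- sin(2 * pi * 50 * tt)
  s10 <- sin(2 * pi * 10 * tt)
  rms <- function(v) sqrt(mean(v^2))
  keep <- (fs):(length(tt) - fs) # ignore edge transients
  expect_lt(rms(notch_filter(s50, fs)[keep]) / rms(s50[keep]), 0.03)
  expect_equal(rms(notch_filter(s10, fs)[keep]) / rms(s10[keep]), 1,
               tolerance = 0.01)
  expect_equal(notch_filter(rep(0, fs * 4), fs), rep(0, fs * 4))
  expect_error(notch_filter(s50, rate = 80), "twice")
})

test_that("band-pass is zero-phase in the passband and steep outside it", {
  fs <- 256
  # the 0.1 Hz edge implies a ~33 s kernel, so test on 90 s of signal (a
  # session's length) and judge the response away from the edges
  tt <- (0:(fs * 90 - 1)) / fs
  keep <- (20 * fs):(length(tt) - 20 * fs)
  s15 <- sin(2 * pi * 15 * tt)
  y15 <- bandpass_zero_phase(s15, fs)
  expect_equal(sqrt(mean(y15[keep]^2)) / sqrt(mean(s15[keep]^2)), 1,
               tolerance = 0.02)
  # no phase shift: cross-correlation peak at zero lag
  cc <- ccf(y15[keep], s15[keep], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  s45 <- sin(2 * pi * 45 * tt)
  y45 <- bandpass_zero_phase(s45, fs)
  expect_lt(20 * log10(sqrt(mean(y45[keep]^2)) / sqrt(mean(s45[keep]^2))), -40)
  dc <- rep(3, length(tt))
  expect_lt(max(abs(bandpass_zero_phase(dc, fs)[keep])), 3 * 0.01)
  expect_error(bandpass_zero_phase(s15, fs, band = c(0.1, 200)), "Nyquist")
})

test_that("bad-channel detection flags broken channels and spares clean data", {
  for (seed in 1:3) {
    sub <- withr::with_seed(seed, matrix(rnorm(32 * 2000), 32))
    # give channels realistic shared structure
    sub <- sub + matrix(rep(rnorm(2000), each = 32), 32) * 0.8
    expect_length(detect_bad_channels(sub), 0)
    noisy <- sub
    noisy[5, ] <- rnorm(2000, sd = 100)
    expect_true(5 %in% detect_bad_channels(noisy))
    flat <- sub
    flat[9, ] <- 0
    expect_true(9 %in% detect_bad_channels(flat))
  }
})

test_that("spherical-spline interpolation reconstructs a smooth field", {
  m <- montage_1010_32()
  pos <- as.matrix(m[, c("x", "y", "z")])
  # smooth spatial field: low-order polynomial of the positions over time
  tt <- seq_len(200)
  field <- outer(0.8 * pos[, 1] + 0.5 * pos[, 2] - 0.3 * pos[, 3] +
                   0.4 * pos[, 1] * pos[, 3], sin(tt / 10))
  out <- interpolate_channels(field, bad = 15L)
  err <- sqrt(mean((out[15, ] - field[15, ])^2))
  expect_lt(err / sqrt(mean(field^2)), 0.10)
  expect_identical(interpolate_channels(field, integer(0)), field)
  expect_error(interpolate_channels(field, 1:10), "25%")
})

test_that("common average reference zeroes the channel mean at every sample", {
  withr::with_seed(4, {
    x <- matrix(rnorm(32 * 500), 32) + 5
    y <- common_average_reference(x)
    expect_lt(max(abs(colMeans(y))), 1e-10)
    expect_equal(common_average_reference(y), y, tolerance = 1e-12)
  })
  expect_error(common_average_reference(matrix(1, 1, 10)), "2 channels")
})

test_that("ICA with no removed components is an exact round trip", {
  sub <- small_clean_subject()
  sess <- sessions_from_trials(sub$trials)[[1]]
  x <- common_average_reference(bandpass_zero_phase(sess$eeg, sess$rate))
  cfg <- preprocess_config(ocular_score_threshold = 1.01) # nothing passes
  res <- ica_remove_ocular(x, sess$rate, cfg, seed = 3)
  expect_length(res$removed, 0)
  expect_lt(max(abs(res$eeg - x)) / max(abs(x)), 1e-8)
})

test_that("ICA removes an injected blink source while sparing the angle code", {
  proto <- protocol_config(n_sessions = 1, trials_per_session = 5,
                           camera_dropout_rate = 0)
  enc <- encoding_config(angle_gain = 20, background_scale = 6,
                         blink_rate_hz = 0.5, blink_amplitude_uv = 120,
                         line_noise_uv = 0, seed = 31)
  enc0 <- encoding_config(angle_gain = 20, background_scale = 6,
                          blink_rate_hz = 0, line_noise_uv = 0, seed = 31)
  trials <- simulate_subject(proto, enc)
  sess <- sessions_from_trials(trials)[[1]]
  sess0 <- sessions_from_trials(simulate_subject(proto, enc0))[[1]]
  cfg <- preprocess_config()
  x <- common_average_reference(bandpass_zero_phase(sess$eeg, sess$rate))
  res <- ica_remove_ocular(x, sess$rate, cfg, seed = 4)
  expect_gte(length(res$removed), 1)
  # blink power (what was added on top of the blink-free session) must drop
  fr <- which(rownames(sess$eeg) %in% c("Fp1", "Fp2"))
  blink_part <- (sess$eeg - sess0$eeg)[fr, ]
  clean0 <- common_average_reference(
    bandpass_zero_phase(sess0$eeg, sess$rate))
  before <- mean((x[fr, ] - clean0[fr, ])^2)
  after <- mean((res$eeg[fr, ] - clean0[fr, ])^2)
  expect_gt(mean(blink_part^2), 0)
  expect_lt(after, 0.2 * before)
  # the angle-locked code survives: regress cos/sin of the hand angle on the
  # motor channels and compare the fitted amplitude before vs. after. (The
  # blink unmixing direction, estimated on high-passed data, projects a
  # little of the sub-1 Hz angle component when applied broadband, so exact
  # preservation is structurally impossible; most of the code must survive.)
  fs <- sess$rate
  regs <- NULL
  for (tr in trials) {
    tt <- (seq_len(ncol(tr$eeg)) - 1) / fs
    hx <- approx(tr$kinematics$time, tr$kinematics$x, xout = tt, rule = 2)$y
    hy <- approx(tr$kinematics$time, tr$kinematics$y, xout = tt, rule = 2)$y
    th <- to_polar(hx, hy)
    mv <- tt >= proto$prep_s & tt < proto$prep_s + proto$move_s
    regs <- rbind(regs, cbind(cos(th) * mv, sin(th) * mv))
  }
  mot <- which(rownames(sess$eeg) %in% c("C3", "C4"))
  amp <- function(m) sqrt(sum(vapply(mot, function(ch) {
    sum(lm.fit(regs, m[ch, ])$coefficients^2)
  }, numeric(1))))
  expect_gt(amp(res$eeg) / amp(x), 0.9)
  # CAR is preserved through the reconstruction
  expect_lt(max(abs(colMeans(res$eeg))), 1e-6)
})

test_that("at most the configured number of components is removed", {
  scores <- c(0.9, 0.99, 0.86, 0.95, 0.87, 0.3)
  sel <- select_ocular_components(scores, threshold = 0.85, max_removed = 3)
  expect_length(sel, 3)
  expect_equal(sel, c(2, 4, 1)) # descending score order
  expect_equal(select_ocular_components(scores, 0.85, 0), integer(0))
})

test_that("epoching subtracts the pre-movement baseline and yields 32 x 700", {
  sub <- small_clean_subject()
  expect_length(sub$prep$epochs, 10)
  expect_equal(dim(sub$prep$epochs[[1]]$eeg), c(32, 700))
  # constant offset is removed exactly
  fs <- 256
  x <- matrix(7, nrow = 3, ncol = fs * 10)
  rownames(x) <- c("C3", "Cz", "C4")
  trig <- tibble::tibble(trial_id = 1L, move_onset = fs * 2L)
  cfg <- preprocess_config()
  ep <- epoch_and_baseline(x, fs, trig, cfg)[[1]]
  expect_lt(max(abs(ep$eeg)), 1e-9)
  expect_equal(ncol(ep$eeg), 700)
  # insufficient pre-trial data errors with the trial id
  trig_bad <- tibble::tibble(trial_id = 99L, move_onset = 10L)
  expect_error(epoch_and_baseline(x, fs, trig_bad, cfg), "trial 99")
})
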