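test_that("noiseless trajectory lies exactly on the circle, starting at angle 0", {
  proto <- protocol_config(camera_dropout_rate = 0)
  tr <- simulate_trajectory(proto, motor_noise_sd = 0, lag_s = 0, seed = 1)
  r <- sqrt(tr$x^2 + tr$y^2)
  expect_lt(max(abs(r - proto$radius_cm)), 1e-9)
  i_move <- which(tr$time >= proto$prep_s)[1]
  th0 <- to_polar(tr$x[i_move], tr$y[i_move])
  # angle 0 modulo the wrap, within one camera frame of rotation
  expect_lt(min(th0, 2 * pi - th0), 2 * pi / proto$rotation_period_s / 300)
  # timestamps strictly increasing with instantaneous rate in the camera range
  dt <- diff(tr$time)
  expect_true(all(dt > 0))
  expect_true(all(1 / dt >= proto$camera_rate_range_hz[1] - 1e-6))
  expect_true(all(1 / dt <= proto$camera_rate_range_hz[2] + 1e-6))
})

test_that("target sweeps one full rotation (2*pi) over the movement period", {
  proto <- protocol_config(camera_dropout_rate = 0)
  tr <- simulate_trajectory(proto, motor_noise_sd = 0, lag_s = 0, seed = 2)
  mv <- tr$time >= proto$prep_s & tr$time < proto$prep_s + proto$move_s
  th <- to_polar(tr$x[mv], tr$y[mv])
  # clockwise in [0, 2pi): theta decreases from 2pi to 0; unwrap the sweep
  sweep <- sum(((diff(th) + pi) %% (2 * pi)) - pi)
  expect_equal(sweep, -2 * pi, tolerance = 0.01)
})

test_that("trajectories and EEG are bit-identical under a fixed seed", {
  proto <- protocol_config()
  a <- simulate_trajectory(proto, seed = 42)
  b <- simulate_trajectory(proto, seed = 42)
  expect_identical(a, b)
  enc <- encoding_config(seed = 9)
  e1 <- simulate_eeg(a, proto, enc, seed = 7)
  e2 <- simulate_eeg(b, proto, enc, seed = 7)
  expect_identical(e1$eeg, e2$eeg)
})

test_that("camera dropouts inject repairable far-off outliers", {
  proto <- protocol_config(camera_dropout_rate = 5)
  tr <- simulate_trajectory(proto, motor_noise_sd = 0, lag_s = 0, seed = 3)
  r <- sqrt(tr$x^2 + tr$y^2)
  expect_gt(max(abs(r - proto$radius_cm)), 10) # far off the circle
})

test_that("null encoding yields pure pink noise uncorrelated with the angle", {
  proto <- protocol_config(camera_dropout_rate = 0)
  enc <- encoding_config(angle_gain = 0, erd_depth = 0, mrcp_amplitude = 0,
                         blink_rate_hz = 0, line_noise_uv = 0,
                         alpha_amplitude = 0, beta_amplitude = 0,
                         background_scale = 20, seed = 5)
  # pink noise has few effective degrees of freedom within one 6-s rotation,
  # so pool many trials before judging the correlation with the angle
  X <- NULL; TH <- NULL
  for (s in 1:18) {
    tr <- simulate_trajectory(proto, seed = 100 + s)
    rec <- simulate_eeg(tr, proto, enc, seed = 200 + s)
    tt <- (seq_len(ncol(rec$eeg)) - 1) / rec$rate
    mv <- tt >= proto$prep_s & tt < proto$prep_s + proto$move_s
    hx <- approx(tr$time, tr$x, xout = tt[mv], rule = 2)$y
    hy <- approx(tr$time, tr$y, xout = tt[mv], rule = 2)$y
    X <- cbind(X, rec$eeg[, mv])
    TH <- c(TH, to_polar(hx, hy))
  }
  rs <- apply(X, 1, function(v) max(abs(cor(v, cos(TH))),
                                    abs(cor(v, sin(TH)))))
  expect_lt(max(rs), 0.25)
})

test_that("angle-locked component energy is zero outside the movement window", {
  proto <- protocol_config(camera_dropout_rate = 0)
  enc <- encoding_config(angle_gain = 10, erd_depth = 0, mrcp_amplitude = 0,
                         blink_rate_hz = 0, line_noise_uv = 0,
                         alpha_amplitude = 0, beta_amplitude = 0,
                         background_scale = 0, seed = 5)
  tr <- simulate_trajectory(proto, seed = 5)
  rec <- simulate_eeg(tr, proto, enc, seed = 6)
  tt <- (seq_len(ncol(rec$eeg)) - 1) / rec$rate
  outside <- tt < proto$prep_s | tt >= proto$prep_s + proto$move_s
  expect_equal(max(abs(rec$eeg[, outside])), 0)
  expect_gt(max(abs(rec$eeg[, !outside])), 1)
})

test_that("a linear readout recovers the angle encoding from clean channels", {
  # closed-loop check: regressing cos/sin of the hand angle on low-passed
  # motor channels must succeed when the angle gain dominates
  proto <- protocol_config(camera_dropout_rate = 0)
  enc <- encoding_config(angle_gain = 30, background_scale = 3,
                         blink_rate_hz = 0, seed = 21)
  X <- NULL; TH <- NULL
  for (s in 1:3) {
    tr <- simulate_trajectory(proto, seed = 30 + s)
    rec <- simulate_eeg(tr, proto, enc, seed = 60 + s)
    tt <- (seq_len(ncol(rec$eeg)) - 1) / rec$rate
    mv <- tt >= proto$prep_s + 0.3 & tt < proto$prep_s + proto$move_s - 0.3
    hx <- approx(tr$time, tr$x, xout = tt[mv], rule = 2)$y
    hy <- approx(tr$time, tr$y, xout = tt[mv], rule = 2)$y
    X <- cbind(X, rec$eeg[, mv])
    TH <- c(TH, to_polar(hx, hy))
  }
  bf <- signal::butter(4, 2 / (proto$eeg_rate_hz / 2))
  Xl <- t(apply(X, 1, function(v) signal::filtfilt(bf, v)))
  fit_c <- lm.fit(t(Xl), cos(TH))
  fit_s <- lm.fit(t(Xl), sin(TH))
  expect_gt(cor(fit_c$fitted.values, cos(TH)), 0.9)
  expect_gt(cor(fit_s$fitted.values, sin(TH)), 0.9)
})

test_that("alpha power drops during movement when ERD is configured", {
  proto <- protocol_config(camera_dropout_rate = 0)
  enc <- encoding_config(angle_gain = 0, erd_depth = 0.6, mrcp_amplitude = 0,
                         blink_rate_hz = 0, line_noise_uv = 0,
                         alpha_amplitude = 10, beta_amplitude = 0,
                         background_scale = 2, seed = 8)
  tr <- simulate_trajectory(proto, seed = 8)
  rec <- simulate_eeg(tr, proto, enc, seed = 9)
  tt <- (seq_len(ncol(rec$eeg)) - 1) / rec$rate
  c3 <- which(rownames(rec$eeg) == "C3")
  bandpower <- function(v, fs) {
    p <- Mod(fft(v - mean(v)))^2
    f <- seq(0, fs, length.out = length(v) + 1)[seq_along(v)]
    sum(p[f >= 8 & f <= 12])
  }
  prep_idx <- tt < proto$prep_s
  mv_idx <- tt >= proto$prep_s + 1 & tt < proto$prep_s + proto$move_s - 1
  n <- sum(prep_idx)
  p_prep <- bandpower(rec$eeg[c3, prep_idx], rec$rate) / n
  p_mv <- bandpower(rec$eeg[c3, head(which(mv_idx), n)], rec$rate) / n
  expect_lt(p_mv, p_prep)
})

test_that("simulate_subject yields the configured trial count, deterministically", {
  proto <- protocol_config(n_sessions = 2, trials_per_session = 3)
  enc <- encoding_config(seed = 13)
  trials <- simulate_subject(proto, enc)
  expect_length(trials, 6)
  expect_equal(vapply(trials, function(x) x$session_id, integer(1)),
               rep(1:2, each = 3))
  # movement duration between triggers equals move_s to within one sample
  durs <- vapply(trials, function(x) {
    (x$triggers$move_offset - x$triggers$move_onset) / x$rate
  }, numeric(1))
  expect_true(all(abs(durs - proto$move_s) <= 1 / proto$eeg_rate_hz))
  trials2 <- simulate_subject(proto, enc)
  expect_identical(trials[[4]]$eeg, trials2[[4]]$eeg)
  expect_identical(trials[[4]]$kinematics, trials2[[4]]$kinematics)
})

test_that("default protocol generates 200 trials", {
  proto <- protocol_config()
  expect_equal(proto$n_sessions * proto$trials_per_session, 200L)
})

test_that("subject datasets round-trip through the plain-text writer", {
  sub <- small_clean_subject()
  dir <- withr::local_tempdir()
  write_subject_dataset(sub$trials, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  kin <- read.csv(file.path(dir, "trial001_kinematics.csv"))
  expect_equal(kin$x, sub$trials[[1]]$kinematics$x, tolerance = 1e-12)
  eeg <- as.matrix(read.csv(file.path(dir, "session01_eeg.csv")))
  expect_equal(unname(eeg[1, ]), unname(sub$trials[[1]]$eeg[, 1]),
               tolerance = 1e-12)
})
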