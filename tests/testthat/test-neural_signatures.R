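test_that("identical epochs give a zero-width MRCP confidence band", {
  base <- matrix(rnorm(32 * 700, sd = 2), 32)
  eps <- make_epochs(4, function(i) base, seed = 1)
  mr <- compute_mrcp(eps, channels = "Cz")
  expect_lt(max(mr$ci_hi - mr$ci_lo), 1e-9)
  expect_true(all(mr$ci_lo <= mr$mean & mr$mean <= mr$ci_hi))
  expect_error(compute_mrcp(eps, channels = "XX"), "not present")
})

test_that("an injected pre-movement negativity is detected at Cz", {
  # longer epochs spanning [-3, 6) s so the pre-movement second is visible
  tt <- -3 + (0:899) / 100
  ramp <- pmin(pmax(tt + 1, 0), 1) * (tt < 6) # negativity builds from -1 s
  eps <- make_epochs(40, function(i) {
    x <- matrix(rnorm(32 * 900, sd = 1.5), 32)
    x[16, ] <- x[16, ] - 6 * ramp # row 16 = Cz
    x
  }, seed = 2, n = 900)
  mr <- compute_mrcp(eps, channels = "Cz", epoch_start_s = -3)
  base_sd <- sd(mr$mean[mr$time < -1.2])
  pre <- mr$mean[mr$time >= -1 & mr$time < 0]
  expect_lt(min(pre), -2 * base_sd)
})

test_that("a null MRCP stays within its calibration bound", {
  eps <- make_epochs(40, function(i) matrix(rnorm(32 * 900, sd = 1.5), 32),
                     seed = 3, n = 900)
  mr <- compute_mrcp(eps, channels = "Cz", epoch_start_s = -3)
  base_sd <- sd(mr$mean[mr$time < -1.2])
  pre <- mr$mean[mr$time >= -1 & mr$time < 0]
  expect_gt(min(pre), -3 * base_sd)
})

test_that("MRCP of the trial average equals the average of per-trial MRCPs", {
  eps <- make_epochs(6, function(i) matrix(rnorm(32 * 700), 32), seed = 4)
  mr <- compute_mrcp(eps, channels = "C3")
  avg <- Reduce(`+`, lapply(eps, function(e) e$eeg)) / length(eps)
  eps_avg <- make_epochs(2, function(i) avg, seed = 5)
  mr_avg <- compute_mrcp(eps_avg, channels = "C3")
  # linear up to the IIR recursion's numerical noise at the 0.1 Hz edge
  expect_equal(mr$mean, mr_avg$mean, tolerance = 1e-3)
})

test_that("white-noise ERSP is flat near 0 dB", {
  eps <- make_epochs(60, function(i) matrix(rnorm(32 * 700), 32), seed = 6)
  er <- compute_ersp(eps, channels = "Cz")
  move <- er$time >= 0.5 & er$time < 5.5
  expect_lt(max(abs(tapply(er$power_db[move],
                           er$freq[move], mean))), 1)
})

test_that("injected alpha-band ERD shows up below -2 dB during movement", {
  tt <- -0.5 + (0:699) / 100
  depth <- ifelse(tt >= 0 & tt < 6, 0.5, 1) # amplitude halves during movement
  mot <- match(c("C3", "Cz", "C4"), montage_1010_32()$channel)
  eps <- make_epochs(30, function(i) {
    x <- matrix(rnorm(32 * 700, sd = 0.3), 32)
    osc <- 3 * depth * sin(2 * pi * 10 * tt + i)
    x[mot, ] <- x[mot, ] + rep(osc, each = 3)
    x
  }, seed = 7)
  er <- compute_ersp(eps, channels = c("C3", "Cz", "C4"))
  alpha_mv <- er$power_db[er$freq >= 8 & er$freq <= 12 &
                            er$time >= 1 & er$time < 5]
  expect_lt(mean(alpha_mv), -2)
  expect_gt(mean(alpha_mv), 10 * log10(0.25) - 2) # bounded by the 0.5 depth
})

test_that("ERSP baseline normalization is exact", {
  eps <- make_epochs(8, function(i) matrix(rnorm(32 * 700), 32), seed = 8)
  er <- compute_ersp(eps, channels = "C3", baseline = c(-0.5, 6.5))
  # whole-epoch baseline: mean power over the epoch is 0 dB per frequency
  by_freq <- tapply(10^(er$power_db / 10), er$freq, mean)
  expect_lt(max(abs(10 * log10(by_freq))), 1e-6)
  expect_error(compute_ersp(eps, channels = "C3", baseline = c(-2, 0)),
               "outside")
})

test_that("channel voltage summaries return the across-trial mean per channel", {
  eps <- make_epochs(1, function(i) matrix(seq_len(32 * 700) / 1000, 32),
                     seed = 9)
  cv <- channel_voltage_summary(eps, timepoints = c(0, 1))
  expect_equal(nrow(cv), 64)
  i0 <- round(0.5 * 100) + 1
  expect_equal(cv$mean_uv[cv$time == 0], unname(eps[[1]]$eeg[, i0]))
  expect_error(channel_voltage_summary(eps, timepoints = 10), "outside")
  # zero-mean noise: grand means shrink with the trial count (CLT)
  eps2 <- make_epochs(60, function(i) matrix(rnorm(32 * 700), 32), seed = 10)
  cv2 <- channel_voltage_summary(eps2, timepoints = c(1, 3))
  expect_lt(max(abs(cv2$mean_uv)), 4 / sqrt(60))
})
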