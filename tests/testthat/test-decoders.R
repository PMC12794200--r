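test_that("all six architectures map a 32 x 100 window to one finite scalar", {
  zeros <- array(0, c(32, 100, 2))
  withr::with_seed(1, rnd <- array(rnorm(32 * 100 * 2), c(32, 100, 2)))
  for (fam in c("shallow", "deep", "eegnet")) {
    for (lstm in c(FALSE, TRUE)) {
      dec <- build_decoder(decoder_spec(fam, use_lstm = lstm), seed = 2)
      p0 <- predict(dec, zeros)
      expect_length(p0, 2)
      expect_true(all(is.finite(p0)))
      p1 <- predict(dec, rnd)
      expect_false(isTRUE(all.equal(p1[1], p1[2]))) # model is not constant
      expect_gte(dec$seq_len, 2)
    }
  }
})

test_that("first-layer filter counts follow the family defaults", {
  expect_equal(decoder_spec("eegnet")$first_layer_filters, 8L)
  expect_equal(decoder_spec("deep")$first_layer_filters, 25L)
  expect_equal(decoder_spec("shallow")$first_layer_filters, 40L)
  lay <- eegpolar:::decoder_layers(decoder_spec("eegnet"))$layers
  expect_equal(lay[[1]]$maps_out, 8L)
})

test_that("LSTM hybrids strictly add parameters over their base CNN", {
  for (fam in c("shallow", "deep", "eegnet")) {
    base <- build_decoder(decoder_spec(fam), seed = 1)
    hyb <- attach_lstm(base, seed = 1)
    expect_true(hyb$spec$use_lstm)
    expect_gt(n_parameters(hyb), n_parameters(base))
  }
})

test_that("a collapsed temporal axis before the LSTM stage is refused", {
  expect_error(
    build_decoder(decoder_spec("eegnet", use_lstm = TRUE, n_samples = 40)),
    "pooling")
})

test_that("initialization is deterministic under a fixed seed", {
  a <- build_decoder(decoder_spec("eegnet", use_lstm = TRUE), seed = 7)
  b <- build_decoder(decoder_spec("eegnet", use_lstm = TRUE), seed = 7)
  expect_identical(eegpolar:::nn_get_params(a$ptr),
                   eegpolar:::nn_get_params(b$ptr))
  c <- build_decoder(decoder_spec("eegnet", use_lstm = TRUE), seed = 8)
  expect_false(identical(eegpolar:::nn_get_params(a$ptr),
                         eegpolar:::nn_get_params(c$ptr)))
})

test_that("gradient flows to the first convolutional layer in all six models", {
  withr::with_seed(3, {
    x <- array(rnorm(32 * 100 * 4), c(32, 100, 4))
    y <- runif(4, 0, 2 * pi)
  })
  for (fam in c("shallow", "deep", "eegnet")) {
    for (lstm in c(FALSE, TRUE)) {
      dec <- build_decoder(decoder_spec(fam, use_lstm = lstm), seed = 4)
      lg <- eegpolar:::nn_loss_grad(dec$ptr, x, y)
      # the first parameter block is the first conv's kernel
      n_w1 <- dec$spec$first_layer_filters *
        eegpolar:::decoder_layers(dec$spec)$layers[[1]]$k
      expect_gt(sqrt(sum(lg$grad[seq_len(n_w1)]^2)), 0)
      expect_true(all(is.finite(lg$grad)))
    }
  }
})

test_that("analytic gradients match finite differences for every family", {
  specs <- tiny_specs_for_gradients()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    dec <- build_decoder(spec, seed = 3)
    withr::with_seed(10 + match(nm, names(specs)), {
      x <- array(rnorm(spec$n_channels * spec$n_samples * 4),
                 c(spec$n_channels, spec$n_samples, 4))
      y <- rnorm(4)
    })
    lg <- eegpolar:::nn_loss_grad(dec$ptr, x, y)
    p0 <- eegpolar:::nn_get_params(dec$ptr)
    np <- length(p0)
    idx <- withr::with_seed(20, sample(np, 30))
    h <- 1e-3
    num <- vapply(idx, function(k) {
      eegpolar:::nn_poke_param(dec$ptr, k - 1L, p0[k] + h)
      lp <- eegpolar:::nn_train_loss(dec$ptr, x, y)
      eegpolar:::nn_poke_param(dec$ptr, k - 1L, p0[k] - h)
      lm_ <- eegpolar:::nn_train_loss(dec$ptr, x, y)
      eegpolar:::nn_poke_param(dec$ptr, k - 1L, p0[k])
      (lp - lm_) / (2 * h)
    }, numeric(1))
    rel <- abs(num - lg$grad[idx]) / pmax(1e-3, abs(num) + abs(lg$grad[idx]))
    expect_lt(max(rel), 0.02)
  }
})

test_that("model summaries and JSON serialization round-trip the architecture config", {
  spec <- decoder_spec("eegnet", use_lstm = TRUE)
  dec <- build_decoder(spec, seed = 1)
  lines <- capture.output(model_summary(dec))
  expect_true(any(grepl("lstm_head", lines)))
  js <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$family, "eegnet")
  expect_true(back$use_lstm)
})
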