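test_that("evaluation metrics behave on known prediction patterns", {
  m <- eegpolar:::metrics_from_predictions
  lab <- runif(500, 0, 2 * pi)
  perfect <- m(lab, lab)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$cc, 1)
  expect_equal(perfect$r2, 1)
  shifted <- m(lab + 0.5, lab)
  expect_equal(shifted$mae, 0.5)
  expect_equal(shifted$mse, 0.25)
  expect_equal(shifted$cc, 1)
  const <- m(rep(1, 500), lab)
  expect_equal(const$cc, 0)
  expect_true(const$degenerate)
})

test_that("independent uniform predictions give cc near 0 and mse near 2*var", {
  withr::with_seed(5, {
    lab <- runif(1e5, 0, 2 * pi)
    pred <- runif(1e5, 0, 2 * pi)
  })
  m <- eegpolar:::metrics_from_predictions(pred, lab)
  expect_lt(abs(m$cc), 0.02)
  expect_equal(m$mse, 2 * (2 * pi)^2 / 12, tolerance = 0.03)
  # Jensen: mae^2 <= mse, here and in general
  expect_lte(m$mae^2, m$mse)
  for (s in 1:5) {
    withr::with_seed(s, {
      p <- rnorm(100)
      l <- rnorm(100)
    })
    mm <- eegpolar:::metrics_from_predictions(p, l)
    expect_lte(mm$mae^2, mm$mse + 1e-12)
  }
})

test_that("a learnable toy mapping is decoded above chance by a small model", {
  ds <- toy_dataset()
  spec <- decoder_spec("eegnet", use_lstm = FALSE)
  cfg <- train_config(batch_trials = 2, max_epochs = 12, patience = 12,
                      seed = 11)
  tr <- train_fold(spec, ds, 1, cfg)
  ev <- evaluate(tr, ds)
  expect_gt(ev$metrics$cc, 0.5)
  expect_equal(sort(unique(ev$predictions$trial_id)),
               sort(ds$split$trial_id[ds$split$assignment == "test"]))
})

test_that("training is deterministic and early stopping obeys its patience", {
  ds <- toy_dataset(n_trials = 8, n_test = 2, n_folds = 2)
  spec <- decoder_spec("eegnet", use_lstm = FALSE)
  cfg <- train_config(batch_trials = 2, max_epochs = 6, patience = 6, seed = 2)
  t1 <- train_fold(spec, ds, 1, cfg)
  t2 <- train_fold(spec, ds, 1, cfg)
  expect_identical(t1$history$val_loss, t2$history$val_loss)
  expect_equal(nrow(t1$history), t1$stopped_epoch)
  # early stopping contract: training runs exactly `patience` epochs past the
  # best validation epoch, unless the epoch cap intervenes
  cfg0 <- train_config(batch_trials = 2, max_epochs = 40, patience = 3,
                       seed = 2)
  t0 <- train_fold(spec, ds, 1, cfg0)
  expect_lte(t0$stopped_epoch - t0$best_epoch, 3L)
  expect_true(t0$stopped_epoch == 40L ||
                t0$stopped_epoch == t0$best_epoch + 3L)
})

test_that("cross-validation aggregates per-fold metrics and trial traces", {
  ds <- toy_dataset()
  spec <- decoder_spec("eegnet", use_lstm = FALSE)
  cfg <- train_config(batch_trials = 2, max_epochs = 4, patience = 4, seed = 3)
  cv <- cross_validate(spec, ds, cfg)
  expect_equal(nrow(cv$per_fold), 2)
  agg_cc <- cv$aggregate$mean[cv$aggregate$metric == "cc"]
  expect_gte(agg_cc, min(cv$per_fold$cc))
  expect_lte(agg_cc, max(cv$per_fold$cc))
  expect_true(all(c("pred_mean", "ci_lo", "ci_hi") %in% names(cv$trial_traces)))
  td <- tidy(cv)
  expect_setequal(unique(td$metric), c("mse", "mae", "cc", "r2"))
  gl <- glance(cv)
  expect_equal(gl$n_folds, 2)
  expect_equal(gl$cc_mean, agg_cc)
})

test_that("label permutation shuffles training labels but never the test set", {
  ds <- toy_dataset()
  spec <- decoder_spec("eegnet", use_lstm = FALSE)
  cfg <- train_config(batch_trials = 2, max_epochs = 2, patience = 2, seed = 4)
  ch <- chance_level(spec, ds, cfg)
  expect_true(ch$chance)
  # the evaluation labels are the intact dataset labels
  test_ids <- ds$split$trial_id[ds$split$assignment == "test"]
  idx <- which(ds$trial_ids %in% test_ids)
  lab_eval <- ch$trial_traces$label[order(ch$trial_traces$trial_id,
                                          ch$trial_traces$window)]
  lab_true <- ds$labels[idx][order(ds$trial_ids[idx])]
  expect_equal(sort(lab_eval), sort(ds$labels[idx]))
})

test_that("the chance comparison reports F, df and p for each metric", {
  mk_cv <- function(cc, mse, mae) {
    structure(list(per_fold = tibble::tibble(
      fold = seq_along(cc), mse = mse, mae = mae, cc = cc, r2 = cc^2),
      model = "x", chance = FALSE), class = "cv_result")
  }
  withr::with_seed(6, {
    dec <- mk_cv(rnorm(10, 0.9, 0.05), rnorm(10, 0.3, 0.05),
                 rnorm(10, 0.4, 0.05))
    cha <- mk_cv(rnorm(10, 0, 0.1), rnorm(10, 6.5, 0.5), rnorm(10, 2, 0.2))
  })
  cmp <- compare_to_chance(dec, cha)
  expect_equal(cmp$metric, c("mse", "mae", "cc"))
  expect_true(all(c("f", "df1", "df2", "p_anova", "p_perm") %in% names(cmp)))
  expect_lt(cmp$p_anova[cmp$metric == "cc"], 0.001)
  expect_lt(cmp$p_perm[cmp$metric == "cc"], 0.01)
  same <- compare_to_chance(dec, dec)
  expect_true(all(same$p_anova > 0.99 | is.nan(same$p_anova)))
  expect_error(compare_to_chance(dec, mk_cv(0.1, 1, 1)), "fold counts")
})
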