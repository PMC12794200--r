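#' Training configuration
#'
#' The study protocol trains with mean squared error, Adam at learning rate
#' 0.002 without decay, mini-batches of 9 whole trials (1089 windows under
#' default windowing), up to 1000 epochs, stopping early when validation
#' loss has not improved for 50 epochs (best-validation weights restored).
#' Scaled-down runs shrink `batch_trials`, `max_epochs` and `patience`, not
#' the loss/optimizer choices.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_trials whole trials per mini-batch.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed master seed for weight init, batch shuffling and permutation
#'   streams.
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 0.002, batch_trials = 9,
                         max_epochs = 1000, patience = 50, seed = 1L) {
  structure(list(
    loss = "mse", optimizer = "adam",
    learning_rate = learning_rate,
    batch_trials = as.integer(batch_trials),
    max_epochs = as.integer(max_epochs),
    patience = as.integer(patience),
    seed = as.integer(seed)
  ), class = "train_config")
}

# window indices of the given trials, in the given trial order
windows_of_trials <- function(dataset, trials) {
  unlist(lapply(trials, function(tid) which(dataset$trial_ids == tid)))
}

fold_names <- function(split) {
  sort(unique(split$assignment[split$assignment != "test"]))
}

#' Train one cross-validation fold
#'
#' Trains a decoder on all folds except `fold` (which serves as validation),
#' never touching the test trials. Mini-batches are whole trials
#' (`batch_trials` of them, shuffled each epoch); early stopping restores
#' the best-validation weights.
#'
#' @param spec a [decoder_spec()].
#' @param dataset a `window_dataset` from [build_window_dataset()].
#' @param fold integer fold index (1-based) used for validation.
#' @param config a [train_config()].
#' @param permute_labels internal: permute training+validation labels before
#'   training (used by [chance_level()]).
#' @return a `trained_decoder`: the fitted `eeg_decoder` plus `history`
#'   (tibble of per-epoch train/validation loss), `stopped_epoch`,
#'   `best_epoch`, `fold`.
#' @export
train_fold <- function(spec, dataset, fold, config = train_config(),
                       permute_labels = FALSE) {
  split <- dataset$split
  folds <- fold_names(split)
  if (fold < 1 || fold > length(folds)) {
    stop(sprintf("fold must be in 1..%d", length(folds)), call. = FALSE)
  }
  val_name <- sprintf("fold %d", fold)
  val_trials <- split$trial_id[split$assignment == val_name]
  train_trials <- split$trial_id[!(split$assignment %in% c("test", val_name))]
  if (length(val_trials) == 0 || length(train_trials) == 0) {
    stop("empty training or validation fold", call. = FALSE)
  }
  # leakage guard: no test trial may reach training or validation
  test_trials <- split$trial_id[split$assignment == "test"]
  stopifnot(length(intersect(test_trials, c(train_trials, val_trials))) == 0)

  labels <- dataset$labels
  if (permute_labels) {
    tv_idx <- windows_of_trials(dataset, c(train_trials, val_trials))
    perm_seed <- derive_seed(config$seed, 5000 + fold)
    perm <- withr::with_seed(perm_seed, sample(length(tv_idx)))
    if (length(tv_idx) > 1 && all(perm == seq_along(perm))) {
      perm <- rev(perm) # reject the identity permutation
    }
    labels[tv_idx] <- labels[tv_idx][perm]
  }

  decoder <- build_decoder(spec, seed = derive_seed(config$seed, 100 + fold))
  val_idx <- windows_of_trials(dataset, val_trials)
  val_x <- dataset$windows[, , val_idx, drop = FALSE]
  val_y <- labels[val_idx]

  best_loss <- Inf
  best_state <- NULL
  best_epoch <- 0L
  hist_train <- numeric(0)
  hist_val <- numeric(0)
  epoch <- 0L
  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    ord <- withr::with_seed(derive_seed(config$seed, 10000L + epoch),
                            sample(train_trials))
    n_b <- ceiling(length(ord) / config$batch_trials)
    ep_loss <- 0
    for (b in seq_len(n_b)) {
      bt <- ord[((b - 1) * config$batch_trials + 1):
                  min(b * config$batch_trials, length(ord))]
      idx <- windows_of_trials(dataset, bt)
      ep_loss <- ep_loss + nn_train_batch(
        decoder$ptr, dataset$windows[, , idx, drop = FALSE], labels[idx],
        config$learning_rate)
    }
    v_loss <- mean((predict(decoder, val_x) - val_y)^2)
    hist_train <- c(hist_train, ep_loss / n_b)
    hist_val <- c(hist_val, v_loss)
    if (v_loss < best_loss) {
      best_loss <- v_loss
      best_state <- nn_get_state(decoder$ptr)
      best_epoch <- epoch
    }
    if (epoch - best_epoch >= config$patience) break
  }
  if (!is.null(best_state)) nn_set_state(decoder$ptr, best_state)

  structure(list(
    decoder = decoder,
    history = tibble::tibble(epoch = seq_len(epoch),
                             train_loss = hist_train, val_loss = hist_val),
    stopped_epoch = epoch,
    best_epoch = best_epoch,
    fold = as.integer(fold),
    permuted = isTRUE(permute_labels)
  ), class = "trained_decoder")
}

# prediction metrics; constant predictions get cc = 0 with a flag because
# permuted-label models can collapse to the mean
metrics_from_predictions <- function(pred, label) {
  err <- pred - label
  degenerate <- sd(pred) < 1e-8 || sd(label) < 1e-8
  cc <- if (degenerate) 0 else cor(pred, label)
  ss_tot <- sum((label - mean(label))^2)
  tibble::tibble(
    mse = mean(err^2),
    mae = mean(abs(err)),
    cc = cc,
    r2 = 1 - sum(err^2) / ss_tot,
    degenerate = degenerate
  )
}

#' Evaluate a trained decoder on held-out windows
#'
#' Computes MSE (rad^2), MAE (rad), Pearson correlation and R^2 over the
#' pooled windows, plus per-trial prediction traces.
#'
#' @param trained a `trained_decoder` (or `eeg_decoder`).
#' @param dataset a `window_dataset`.
#' @param trials trial ids to evaluate on; default the test set.
#' @return an `eval_result`: `metrics` (one-row tibble), `predictions`
#'   (tibble: `trial_id`, `window`, `label`, `pred`).
#' @export
evaluate <- function(trained, dataset,
                     trials = dataset$split$trial_id[
                       dataset$split$assignment == "test"]) {
  dec <- if (inherits(trained, "trained_decoder")) trained$decoder else trained
  idx <- windows_of_trials(dataset, trials)
  pred <- predict(dec, dataset$windows[, , idx, drop = FALSE])
  label <- dataset$labels[idx]
  preds <- tibble::tibble(
    trial_id = dataset$trial_ids[idx],
    label = label,
    pred = pred
  )
  preds <- dplyr::mutate(dplyr::group_by(preds, .data$trial_id),
                         window = dplyr::row_number())
  preds <- dplyr::ungroup(preds)
  structure(list(
    metrics = metrics_from_predictions(pred, label),
    predictions = preds
  ), class = "eval_result")
}

#' Cross-validated decoding run
#'
#' Trains one decoder per fold (each fold serving once as validation),
#' evaluates every fold's model on the same held-out test set, and
#' aggregates the metrics as mean +/- SD across folds. Per-trial traces of
#' the fold-averaged prediction with a 95% CI are retained.
#'
#' @param spec a [decoder_spec()].
#' @param dataset a `window_dataset`.
#' @param config a [train_config()].
#' @param permute_labels permute training/validation labels per fold
#'   (chance-level estimation).
#' @param keep_models keep the fitted decoders in the result.
#' @return a `cv_result`: `per_fold` (tibble of fold metrics), `aggregate`
#'   (mean/sd per metric), `trial_traces` (fold-averaged predictions with
#'   CI), `history` (per-fold training curves), `model` label.
#' @export
cross_validate <- function(spec, dataset, config = train_config(),
                           permute_labels = FALSE, keep_models = FALSE) {
  folds <- fold_names(dataset$split)
  per_fold <- list()
  preds_all <- list()
  hist_all <- list()
  models <- list()
  for (k in seq_along(folds)) {
    tr <- train_fold(spec, dataset, k, config, permute_labels = permute_labels)
    ev <- evaluate(tr, dataset)
    per_fold[[k]] <- dplyr::mutate(ev$metrics, fold = k,
                                   stopped_epoch = tr$stopped_epoch,
                                   best_epoch = tr$best_epoch)
    preds_all[[k]] <- dplyr::mutate(ev$predictions, fold = k)
    hist_all[[k]] <- dplyr::mutate(tr$history, fold = k)
    if (keep_models) models[[k]] <- tr
  }
  per_fold <- dplyr::bind_rows(per_fold)
  preds <- dplyr::bind_rows(preds_all)
  traces <- dplyr::summarise(
    dplyr::group_by(preds, .data$trial_id, .data$window),
    label = .data$label[1],
    pred_mean = mean(.data$pred),
    pred_sd = sd(.data$pred),
    ci_lo = .data$pred_mean - qt(0.975, max(1, dplyr::n() - 1)) *
      .data$pred_sd / sqrt(dplyr::n()),
    ci_hi = .data$pred_mean + qt(0.975, max(1, dplyr::n() - 1)) *
      .data$pred_sd / sqrt(dplyr::n()),
    .groups = "drop")
  agg <- tidyr::pivot_longer(
    per_fold[, c("fold", "mse", "mae", "cc", "r2")],
    cols = c("mse", "mae", "cc", "r2"),
    names_to = "metric", values_to = "value")
  agg <- dplyr::summarise(dplyr::group_by(agg, .data$metric),
                          mean = mean(.data$value), sd = sd(.data$value),
                          .groups = "drop")
  structure(list(
    per_fold = per_fold,
    aggregate = agg,
    trial_traces = traces,
    history = dplyr::bind_rows(hist_all),
    model = spec_label(spec),
    chance = isTRUE(permute_labels),
    models = models
  ), class = "cv_result")
}

#' Permuted-label chance level
#'
#' Repeats the cross-validation with the labels of the training and
#' validation windows randomly permuted before each fold's training (one
#' fresh permutation per fold, window level); test labels stay intact. The
#' resulting metrics estimate the no-information baseline under the
#' identical training protocol.
#'
#' @inheritParams cross_validate
#' @param permutation_seed seed stream for the per-fold permutations (offsets
#'   the training config seed).
#' @return a `cv_result` with `chance = TRUE`.
#' @export
chance_level <- function(spec, dataset, config = train_config(),
                         permutation_seed = NULL) {
  if (!is.null(permutation_seed)) {
    config$seed <- derive_seed(config$seed, 9e6 + permutation_seed)
  }
  cross_validate(spec, dataset, config, permute_labels = TRUE)
}

#' Compare decoded performance against its chance level
#'
#' For each metric (MSE, MAE, CC), a one-way fixed-effects ANOVA with fold
#' results as observations (decoded vs. chance), plus a paired sign-flip
#' permutation p-value as a distribution-free companion (exact enumeration
#' up to 12 folds).
#'
#' @param decoded,chance `cv_result` objects with equal fold counts.
#' @return tibble: `metric`, `f`, `df1`, `df2`, `p_anova`, `p_perm`,
#'   `mean_decoded`, `mean_chance`.
#' @export
compare_to_chance <- function(decoded, chance) {
  stopifnot(inherits(decoded, "cv_result"), inherits(chance, "cv_result"))
  if (nrow(decoded$per_fold) != nrow(chance$per_fold)) {
    stop("fold counts differ between decoded and chance results",
         call. = FALSE)
  }
  if (nrow(decoded$per_fold) < 2) {
    stop("need at least 2 folds for the comparison", call. = FALSE)
  }
  purrr::map_dfr(c("mse", "mae", "cc"), function(metric) {
    a <- decoded$per_fold[[metric]]
    b <- chance$per_fold[[metric]]
    grp <- factor(rep(c("decoded", "chance"), c(length(a), length(b))))
    fit <- stats::aov(c(a, b) ~ grp)
    s <- summary(fit)[[1]]
    d <- a - b
    obs <- mean(d)
    n <- length(d)
    p_perm <- if (all(d == 0)) {
      1
    } else if (n <= 12) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      mean(abs(signs %*% d) / n >= abs(obs) - 1e-12)
    } else {
      signs <- matrix(sample(c(-1, 1), 2000 * n, replace = TRUE), ncol = n)
      mean(abs(signs %*% d) / n >= abs(obs) - 1e-12)
    }
    tibble::tibble(
      metric = metric,
      f = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
      p_anova = s$`Pr(>F)`[1], p_perm = p_perm,
      mean_decoded = mean(a), mean_chance = mean(b)
    )
  })
}
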