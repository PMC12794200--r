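#' Per-channel standardization
#'
#' Standardizes each EEG channel to zero mean and unit standard deviation,
#' `s[t] = (v[t] - mean(v)) / sd(v)`, using the population (divide-by-n)
#' standard deviation. By default the statistics are pooled over all epochs
#' of a subject jointly, replicating a standardize-before-split workflow;
#' note this lets test-set samples contribute to the statistics, so a
#' stricter `"train"` scope (statistics supplied from training trials only)
#' is also available through the `stats` argument.
#'
#' @param epochs list of `clean_epoch` objects (or a single channels x
#'   samples matrix).
#' @param stats optional precomputed list with `mean` and `sd` per channel;
#'   when supplied, it is applied instead of estimated.
#' @return list with `epochs` (standardized, same shape as input) and
#'   `stats` (`mean`, `sd` per channel).
#' @export
#' @examples
#' standardize(matrix(c(1, 2, 3), 1))$epochs # -1.2247, 0, 1.2247
standardize <- function(epochs, stats = NULL) {
  single <- is.matrix(epochs)
  mats <- if (single) list(epochs) else lapply(epochs, function(e) {
    if (is.matrix(e)) e else e$eeg
  })
  if (is.null(stats)) {
    all_x <- do.call(cbind, mats)
    mu <- rowMeans(all_x)
    sdv <- apply(all_x, 1, pop_sd)
    if (any(sdv <= 0)) {
      stop("zero-variance channel(s): ",
           paste(which(sdv <= 0), collapse = ", "), call. = FALSE)
    }
    stats <- list(mean = mu, sd = sdv)
  }
  std <- lapply(mats, function(m) (m - stats$mean) / stats$sd)
  if (single) {
    list(epochs = std[[1]], stats = stats)
  } else {
    out <- epochs
    for (i in seq_along(out)) {
      if (is.matrix(out[[i]])) out[[i]] <- std[[i]] else out[[i]]$eeg <- std[[i]]
    }
    list(epochs = out, stats = stats)
  }
}

#' Cut sliding windows with center-point angle labels
#'
#' Slides a 1 s window (100 samples at 100 Hz) in 0.05 s (5 sample) steps
#' over an epoch; incomplete terminal segments are discarded, giving
#' `floor((N - win)/step) + 1` windows (121 for the 700-sample default
#' epoch). Each window's label is the polar angle at its center: the 50th
#' sample (index 49 zero-based, configurable).
#'
#' @param epoch channels x N standardized EEG matrix.
#' @param theta numeric angle series of length N, aligned with the epoch.
#' @param win_samples,step_samples window geometry in samples.
#' @param label_index 1-based index of the label sample within the window
#'   (default 50, i.e. the 50th sample).
#' @return list with `windows` (channels x win x n_windows array) and
#'   `labels` (radians).
#' @export
slide_windows <- function(epoch, theta, win_samples = 100, step_samples = 5,
                          label_index = 50) {
  n <- ncol(epoch)
  if (length(theta) != n) {
    stop("epoch and angle series lengths differ", call. = FALSE)
  }
  if (n < win_samples) {
    stop("epoch shorter than one window", call. = FALSE)
  }
  n_win <- (n - win_samples) %/% step_samples + 1
  starts <- (seq_len(n_win) - 1) * step_samples + 1
  windows <- array(0, c(nrow(epoch), win_samples, n_win))
  for (w in seq_len(n_win)) {
    windows[, , w] <- epoch[, starts[w]:(starts[w] + win_samples - 1)]
  }
  labels <- theta[starts + label_index - 1]
  list(windows = windows, labels = labels)
}

#' Trial-level test / cross-validation split
#'
#' Shuffles the trials with a seeded permutation, selects every k-th trial of
#' the shuffled order (k = trials / n_test, starting at the first) as the
#' test set by systematic sampling, and partitions the remaining trials into
#' `n_folds` equal, disjoint folds in shuffled order. The assignment is at
#' trial level: every window of a trial inherits it, so no trial straddles
#' splits.
#'
#' @param trial_ids vector of trial identifiers.
#' @param shuffle_seed integer seed for the permutation.
#' @param n_test number of test trials.
#' @param n_folds number of cross-validation folds.
#' @return tibble with `trial_id` and `assignment` (`"test"` or `"fold k"`).
#' @export
#' @examples
#' split_dataset(1:200, shuffle_seed = 1)
split_dataset <- function(trial_ids, shuffle_seed = 1L, n_test = 20,
                          n_folds = 10) {
  n <- length(trial_ids)
  if (n < n_test + n_folds) {
    stop("need at least n_test + n_folds trials", call. = FALSE)
  }
  if (n %% n_test != 0) {
    stop(sprintf(paste0("systematic sampling needs the trial count (%d) to be ",
                        "a multiple of n_test (%d); adjust n_test"),
                 n, n_test), call. = FALSE)
  }
  if ((n - n_test) %% n_folds != 0) {
    stop(sprintf(paste0("the %d non-test trials cannot be divided into %d ",
                        "equal folds; adjust n_folds"),
                 n - n_test, n_folds), call. = FALSE)
  }
  perm <- withr::with_seed(as.integer(shuffle_seed), sample(n))
  shuffled <- trial_ids[perm]
  k <- n %/% n_test
  test_pos <- seq(1, n, by = k)
  test_ids <- shuffled[test_pos]
  rest <- shuffled[-test_pos]
  fold_size <- length(rest) %/% n_folds
  assignment <- tibble::tibble(
    trial_id = c(test_ids, rest),
    assignment = c(rep("test", n_test),
                   rep(sprintf("fold %d", seq_len(n_folds)), each = fold_size))
  )
  assignment[match(trial_ids, assignment$trial_id), ]
}

#' Build the windowed decoding dataset for one subject
#'
#' Standardizes the cleaned epochs (subject scope by default), cuts sliding
#' windows with center-point labels, and attaches the trial-level split.
#'
#' @param epochs list of `clean_epoch` objects (32 x 700 at 100 Hz).
#' @param angle_epochs list of `angle_epoch` objects aligned with `epochs`.
#' @param shuffle_seed seed for the split permutation.
#' @param n_test,n_folds split sizes, see [split_dataset()].
#' @param win_samples,step_samples,label_index window geometry, see
#'   [slide_windows()].
#' @param scope `"subject"` (statistics over all epochs, the replication
#'   default) or `"train"` (statistics from non-test trials only).
#' @return a `window_dataset`: list with `windows` (32 x 100 x n array),
#'   `labels`, `trial_ids` (per window), `split` (tibble), `channel_stats`.
#' @export
build_window_dataset <- function(epochs, angle_epochs, shuffle_seed = 1L,
                                 n_test = 20, n_folds = 10,
                                 win_samples = 100, step_samples = 5,
                                 label_index = 50,
                                 scope = c("subject", "train")) {
  scope <- match.arg(scope)
  stopifnot(length(epochs) == length(angle_epochs))
  trial_ids <- vapply(epochs, function(e) e$trial_id, integer(1))
  split <- split_dataset(trial_ids, shuffle_seed, n_test, n_folds)

  if (scope == "subject") {
    std <- standardize(epochs)
  } else {
    train_idx <- which(split$assignment != "test")
    stats <- standardize(epochs[train_idx])$stats
    std <- standardize(epochs, stats = stats)
  }

  per_trial <- lapply(seq_along(epochs), function(i) {
    th <- angle_epochs[[i]]$theta
    slide_windows(std$epochs[[i]]$eeg, th, win_samples, step_samples,
                  label_index)
  })
  n_per <- vapply(per_trial, function(p) length(p$labels), integer(1))
  total <- sum(n_per)
  windows <- array(0, c(nrow(epochs[[1]]$eeg), win_samples, total))
  labels <- numeric(total)
  w_trial <- integer(total)
  off <- 0
  for (i in seq_along(per_trial)) {
    idx <- off + seq_len(n_per[i])
    windows[, , idx] <- per_trial[[i]]$windows
    labels[idx] <- per_trial[[i]]$labels
    w_trial[idx] <- trial_ids[i]
    off <- off + n_per[i]
  }
  structure(list(
    windows = windows,
    labels = labels,
    trial_ids = w_trial,
    split = split,
    channel_stats = std$stats,
    windows_per_trial = unique(n_per)
  ), class = "window_dataset")
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf(
    "<window_dataset> %d windows (%d x %d) from %d trials; %d test trials, %d folds\n",
    dim(x$windows)[3], dim(x$windows)[1], dim(x$windows)[2],
    length(unique(x$trial_ids)),
    sum(x$split$assignment == "test"),
    length(unique(x$split$assignment[x$split$assignment != "test"]))))
  invisible(x)
}
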