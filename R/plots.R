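#' Plot per-fold metrics of a cross-validation result
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = sprintf("%s%s: per-fold test metrics", object$model,
                                  if (object$chance) " (chance)" else ""),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot fold-averaged predicted angle traces against the truth
#'
#' @param cv a `cv_result`.
#' @param trials trial ids to show (default the first 4 test trials).
#' @return a ggplot with the ground-truth angle, the fold-averaged
#'   prediction and its 95% CI ribbon.
#' @export
plot_trial_traces <- function(cv, trials = NULL) {
  tr <- cv$trial_traces
  if (is.null(trials)) trials <- head(sort(unique(tr$trial_id)), 4)
  tr <- tr[tr$trial_id %in% trials, ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$window)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_mean), color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$label), color = "black") +
    ggplot2::facet_wrap(~trial_id) +
    ggplot2::labs(x = "window", y = "polar angle (rad)",
                  title = sprintf("%s: decoded vs. true angle", cv$model)) +
    ggplot2::theme_minimal()
}

#' Plot MRCP averages with confidence band
#'
#' @param mrcp tibble from [compute_mrcp()].
#' @return a ggplot.
#' @export
plot_mrcp <- function(mrcp) {
  ggplot2::ggplot(mrcp, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time from movement onset (s)", y = "voltage (uV)",
                  title = "Movement-related cortical potentials (0.1-4 Hz)") +
    ggplot2::theme_minimal()
}

#' Plot an ERSP time-frequency map
#'
#' @param ersp tibble from [compute_ersp()].
#' @return a ggplot.
#' @export
plot_ersp <- function(ersp) {
  ggplot2::ggplot(ersp, ggplot2::aes(x = .data$time, y = .data$freq,
                                     fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time from movement onset (s)", y = "frequency (Hz)",
                  fill = "dB", title = "Event-related spectral perturbation") +
    ggplot2::theme_minimal()
}

#' Plot per-fold training curves
#'
#' @param cv a `cv_result`.
#' @return a ggplot of train/validation loss per epoch, per fold.
#' @export
plot_training_history <- function(cv) {
  h <- tidyr::pivot_longer(cv$history, cols = c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~fold) +
    ggplot2::labs(x = "epoch", y = "MSE loss") +
    ggplot2::theme_minimal()
}
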