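#' Tidy a cross-validation result
#'
#' One row per fold and metric, broom style.
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return tibble: `model`, `chance`, `fold`, `metric`, `value`.
#' @export
tidy.cv_result <- function(x, ...) {
  out <- tidyr::pivot_longer(
    x$per_fold[, c("fold", "mse", "mae", "cc", "r2")],
    cols = c("mse", "mae", "cc", "r2"),
    names_to = "metric", values_to = "value")
  dplyr::mutate(out, model = x$model, chance = x$chance, .before = 1)
}

#' One-row summary of a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return one-row tibble with `<metric>_mean` and `<metric>_sd` columns,
#'   the fold count and the model label.
#' @export
glance.cv_result <- function(x, ...) {
  agg <- x$aggregate
  wide <- tibble::as_tibble(
    c(stats::setNames(as.list(agg$mean), paste0(agg$metric, "_mean")),
      stats::setNames(as.list(agg$sd), paste0(agg$metric, "_sd"))))
  dplyr::mutate(wide, n_folds = nrow(x$per_fold), model = x$model,
                chance = x$chance)
}

#' @export
tidy.eval_result <- function(x, ...) {
  tidyr::pivot_longer(x$metrics[, c("mse", "mae", "cc", "r2")],
                      cols = dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.eval_result <- function(x, ...) {
  x$metrics
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s%s; %d folds\n", x$model,
              if (x$chance) " (chance level)" else "", nrow(x$per_fold)))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-4s %7.3f +/- %.3f\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  }
  invisible(x)
}

#' @export
print.eval_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<eval_result> MSE %.3f rad^2, MAE %.3f rad, CC %.3f, R2 %.3f%s\n",
              m$mse, m$mae, m$cc, m$r2,
              if (m$degenerate) " (degenerate predictions)" else ""))
  invisible(x)
}
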