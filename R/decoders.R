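#' Specify one of the six decoding architectures
#'
#' Three convolutional families are supported, each with an optional
#' two-layer LSTM stage replacing the flatten/linear head:
#' \itemize{
#'   \item `"shallow"` (ShallowConvNet-style): one temporal convolution
#'     (40 filters) followed by a spatial filtering convolution across all
#'     channels, batch norm, squaring nonlinearity, average pooling and a log
#'     nonlinearity.
#'   \item `"deep"` (DeepConvNet-style): a temporal + spatial convolution
#'     pair (25 filters) followed by three convolution blocks of 50, 100 and
#'     200 filters, each with batch norm, ELU and max pooling.
#'   \item `"eegnet"` (EEGNet-8,2-style): temporal convolution (8 filters),
#'     depthwise spatial convolution (multiplier 2), then a separable
#'     convolution block, with batch norm, ELU and average pooling.
#' }
#' All carry dropout 0.2 and a single linear output unit (radians). Kernel
#' and pooling lengths are the canonical ones scaled to the 100 Hz,
#' 100-sample input (temporal kernels 0.1 s for shallow/deep blocks, 0.125 s
#' for EEGNet; pooling 0.3 s / stride 0.06 s for shallow). With `use_lstm`,
#' the final convolutional feature map is reshaped to (time steps x feature
#' vector) and passed through 2 stacked LSTM layers of 64 units (the first
#' returns the full sequence, the second its final state) before the linear
#' unit.
#'
#' @param family `"shallow"`, `"deep"` or `"eegnet"`.
#' @param use_lstm append the two-layer LSTM stage.
#' @param n_channels,n_samples input window shape (32 x 100 by default).
#' @param dropout dropout rate used throughout.
#' @param lstm_units,lstm_layers LSTM geometry (64 units x 2 layers).
#' @param first_layer_filters filters in the first convolution; defaults to
#'   the family's canonical count (40 shallow / 25 deep / 8 eegnet).
#' @return a `decoder_spec`.
#' @export
#' @examples
#' decoder_spec("eegnet", use_lstm = TRUE)
decoder_spec <- function(family = c("shallow", "deep", "eegnet"),
                         use_lstm = FALSE,
                         n_channels = 32, n_samples = 100,
                         dropout = 0.2,
                         lstm_units = 64, lstm_layers = 2,
                         first_layer_filters = NULL) {
  family <- match.arg(family)
  defaults <- c(shallow = 40, deep = 25, eegnet = 8)
  if (is.null(first_layer_filters)) {
    first_layer_filters <- unname(defaults[family])
  }
  if (lstm_layers != 2) {
    stop("the hybrid stage is fixed at 2 LSTM layers", call. = FALSE)
  }
  structure(list(
    family = family,
    use_lstm = isTRUE(use_lstm),
    n_channels = as.integer(n_channels),
    n_samples = as.integer(n_samples),
    dropout = dropout,
    lstm_units = as.integer(lstm_units),
    lstm_layers = as.integer(lstm_layers),
    first_layer_filters = as.integer(first_layer_filters)
  ), class = "decoder_spec")
}

#' @export
print.decoder_spec <- function(x, ...) {
  cat(sprintf("<decoder_spec> %s%s; input %d x %d; first-layer filters %d; dropout %g\n",
              x$family, if (x$use_lstm) " + LSTM" else "",
              x$n_channels, x$n_samples, x$first_layer_filters, x$dropout))
  invisible(x)
}

#' Canonical label for a decoder spec
#' @noRd
spec_label <- function(spec) {
  paste0(spec$family, if (spec$use_lstm) "_lstm" else "")
}

# Trace each family's layer stack, tracking the (maps, rows, time) shape so
# the head knows its input and the LSTM stage can verify its sequence length.
decoder_layers <- function(spec) {
  C <- spec$n_channels
  t_now <- spec$n_samples
  p <- spec$dropout
  layers <- list()
  add <- function(...) layers[[length(layers) + 1]] <<- list(...)

  if (spec$family == "shallow") {
    f <- spec$first_layer_filters
    k <- max(3L, round(spec$n_samples / 10))
    add(type = "conv_t", maps_in = 1L, rows = C, maps_out = f, k = k,
        lpad = 0L, rpad = 0L, bias = TRUE)
    t_now <- t_now - k + 1
    add(type = "conv_s", c_in = f * C, maps_out = f, bias = FALSE)
    add(type = "bn", maps = f, rows = 1L)
    add(type = "act", fun = "square")
    pool <- min(30L, t_now)
    add(type = "pool", fun = "avg", p = pool, s = 6L)
    t_now <- (t_now - pool) %/% 6 + 1
    add(type = "act", fun = "log")
    add(type = "dropout", p = p)
    feat <- f
  } else if (spec$family == "deep") {
    f1 <- spec$first_layer_filters
    k <- 5L
    add(type = "conv_t", maps_in = 1L, rows = C, maps_out = f1, k = k,
        lpad = 0L, rpad = 0L, bias = TRUE)
    t_now <- t_now - k + 1
    add(type = "conv_s", c_in = f1 * C, maps_out = f1, bias = TRUE)
    add(type = "bn", maps = f1, rows = 1L)
    add(type = "act", fun = "elu")
    add(type = "pool", fun = "max", p = 2L, s = 2L)
    t_now <- t_now %/% 2
    add(type = "dropout", p = p)
    maps <- f1
    for (f in c(2L, 4L, 8L) * f1) {
      add(type = "conv_t", maps_in = maps, rows = 1L, maps_out = f, k = k,
          lpad = 0L, rpad = 0L, bias = TRUE)
      t_now <- t_now - k + 1
      add(type = "bn", maps = f, rows = 1L)
      add(type = "act", fun = "elu")
      add(type = "pool", fun = "max", p = 2L, s = 2L)
      t_now <- t_now %/% 2
      add(type = "dropout", p = p)
      maps <- f
    }
    feat <- maps
  } else { # eegnet
    f <- spec$first_layer_filters
    d <- 2L
    k1 <- max(3L, round(spec$n_samples / 8))
    if (k1 %% 2 == 0) k1 <- k1 + 1L
    add(type = "conv_t", maps_in = 1L, rows = C, maps_out = f, k = k1,
        lpad = (k1 - 1L) %/% 2L, rpad = (k1 - 1L) %/% 2L, bias = FALSE)
    add(type = "bn", maps = f, rows = C)
    add(type = "conv_dw_s", maps = f, rows = C, mult = d)
    add(type = "bn", maps = f * d, rows = 1L)
    add(type = "act", fun = "elu")
    add(type = "pool", fun = "avg", p = 4L, s = 4L)
    t_now <- (t_now - 4) %/% 4 + 1
    add(type = "dropout", p = p)
    k2 <- 16L
    add(type = "conv_dw_t", maps = f * d, k = k2, lpad = (k2 - 1L) %/% 2L,
        rpad = k2 %/% 2L)
    add(type = "conv_t", maps_in = f * d, rows = 1L, maps_out = f * d,
        k = 1L, lpad = 0L, rpad = 0L, bias = FALSE)
    add(type = "bn", maps = f * d, rows = 1L)
    add(type = "act", fun = "elu")
    add(type = "pool", fun = "avg", p = 8L, s = 8L)
    t_now <- (t_now - 8) %/% 8 + 1
    add(type = "dropout", p = p)
    feat <- f * d
  }

  if (t_now < 1) {
    stop("temporal axis fully consumed; reduce kernel or pooling lengths",
         call. = FALSE)
  }
  if (spec$use_lstm) {
    if (t_now < 2) {
      stop(paste0("temporal axis collapsed to < 2 steps before the LSTM ",
                  "stage; adjust pooling"), call. = FALSE)
    }
    add(type = "lstm_head", c_in = feat, t_in = t_now,
        units = spec$lstm_units, dropout = p)
  } else {
    add(type = "dense_head", c_in = feat, t_in = t_now)
  }
  list(layers = layers, feat = feat, seq_len = t_now)
}

#' Build an untrained decoder
#'
#' Instantiates the network for a [decoder_spec()] with seeded Glorot-uniform
#' initialization (LSTM forget-gate biases start at 1).
#'
#' @param spec a [decoder_spec()].
#' @param seed integer seed for weight initialization and dropout.
#' @return an `eeg_decoder`: the live network handle plus its spec and layer
#'   trace.
#' @export
#' @examples
#' dec <- build_decoder(decoder_spec("eegnet"), seed = 1)
#' n_parameters(dec)
build_decoder <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "decoder_spec"))
  tr <- decoder_layers(spec)
  ptr <- nn_create(tr$layers, as.integer(seed))
  structure(list(
    spec = spec,
    ptr = ptr,
    layers = tr$layers,
    seq_len = tr$seq_len,
    seed = as.integer(seed)
  ), class = "eeg_decoder")
}

#' Attach the two-layer LSTM stage to a convolutional decoder
#'
#' Returns a freshly initialized hybrid whose convolutional stack matches the
#' base model's configuration; the flatten/linear head is replaced by the
#' reshape + 2 x 64-unit LSTM + linear-unit stage.
#'
#' @param base an `eeg_decoder` or `decoder_spec` without LSTM.
#' @param seed seed for the hybrid's initialization.
#' @return an `eeg_decoder` with `use_lstm = TRUE`.
#' @export
attach_lstm <- function(base, seed = 1L) {
  spec <- if (inherits(base, "eeg_decoder")) base$spec else base
  stopifnot(inherits(spec, "decoder_spec"))
  spec$use_lstm <- TRUE
  build_decoder(spec, seed = seed)
}

#' Number of trainable parameters
#' @param decoder an `eeg_decoder`.
#' @return integer parameter count.
#' @export
n_parameters <- function(decoder) {
  nn_num_params(decoder$ptr)
}

#' @export
print.eeg_decoder <- function(x, ...) {
  cat(sprintf("<eeg_decoder> %s; %d parameters; sequence length %d\n",
              spec_label(x$spec), n_parameters(x), x$seq_len))
  invisible(x)
}

#' Predict angles for a batch of EEG windows
#'
#' @param object an `eeg_decoder`.
#' @param windows channels x samples x n array of standardized EEG windows
#'   (a single matrix is treated as one window).
#' @param ... unused.
#' @return numeric vector of predicted angles (radians, unconstrained).
#' @export
predict.eeg_decoder <- function(object, windows, ...) {
  if (is.matrix(windows)) {
    windows <- array(windows, c(dim(windows), 1))
  }
  stopifnot(length(dim(windows)) == 3,
            dim(windows)[1] == object$spec$n_channels,
            dim(windows)[2] == object$spec$n_samples)
  n <- dim(windows)[3]
  chunk <- 512L # bound the transient im2col memory
  if (n <= chunk) return(nn_predict(object$ptr, windows))
  out <- numeric(n)
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1, n)
    out[i0:i1] <- nn_predict(object$ptr, windows[, , i0:i1, drop = FALSE])
  }
  out
}

#' One-line-per-layer text summary of a decoder
#' @param decoder an `eeg_decoder`.
#' @return character vector (one element per layer), invisibly printed.
#' @export
model_summary <- function(decoder) {
  lines <- vapply(decoder$layers, function(l) {
    paste0(l$type, ": ",
           paste(sprintf("%s=%s", setdiff(names(l), "type"),
                         unlist(l[setdiff(names(l), "type")])),
                 collapse = ", "))
  }, character(1))
  lines <- c(sprintf("%s (%d parameters)", spec_label(decoder$spec),
                     n_parameters(decoder)), lines)
  cat(lines, sep = "\n")
  invisible(lines)
}
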