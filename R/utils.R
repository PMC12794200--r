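#' Derive a child seed from a master seed
#'
#' All stochastic stages (per-trial simulation, fold shuffling, weight
#' initialization, label permutation) draw their seeds through this one
#' function so that a single master seed reproduces a whole run. The
#' derivation is a Lehmer step on the 31-bit ring, keeping every derived seed
#' a valid R integer.
#'
#' @param master integer master seed.
#' @param stream integer stream identifier (>= 0); distinct streams give
#'   distinct, deterministic child seeds.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 2)
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1,
            is.numeric(stream), length(stream) == 1, stream >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  a <- 48271
  x <- (abs(as.double(master)) %% m) + 1
  # one multiplicative step per stream unit plus a stream offset, done in
  # double precision (exact below 2^53)
  x <- (a * x + 2 * stream + 1) %% m
  x <- (a * x) %% m
  as.integer(ifelse(x < 1, 1, x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

#' Population standard deviation
#' @noRd
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

gcd_int <- function(a, b) {
  while (b != 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

#' Circular mean of angles in radians, mapped to `[0, 2*pi)`
#' @noRd
circ_mean <- function(theta) {
  a <- atan2(mean(sin(theta)), mean(cos(theta)))
  (a + 2 * pi) %% (2 * pi)
}
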