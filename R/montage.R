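#' Idealized 32-channel 10-10 montage
#'
#' Unit-sphere electrode positions for the 32-channel cap used throughout the
#' package. Positions are constructed from the idealized 10-10 angular scheme
#' (inclination from the vertex, azimuth from the nasion, positive towards the
#' right ear), which is accurate enough for spherical-spline interpolation,
#' neighbor correlations and the synthetic source topographies; it is not a
#' digitized head model.
#'
#' @return a tibble with columns `channel`, `x` (towards right ear), `y`
#'   (towards nasion), `z` (towards vertex), all on the unit sphere.
#' @export
#' @examples
#' m <- montage_1010_32()
#' m[m$channel %in% c("C3", "Cz", "C4"), ]
montage_1010_32 <- function() {
  spec <- list(
    # label, inclination (deg from vertex), azimuth (deg from nasion, + right)
    c("Fp1", 72, -18), c("Fp2", 72,  18),
    c("AF3", 61, -23), c("AF4", 61,  23),
    c("F7",  72, -54), c("F3",  50, -39), c("Fz", 36,   0),
    c("F4",  50,  39), c("F8",  72,  54),
    c("FC5", 62, -69), c("FC1", 31, -45), c("FC2", 31, 45), c("FC6", 62, 69),
    c("T7",  72, -90), c("C3",  45, -90), c("Cz",  0,   0),
    c("C4",  45,  90), c("T8",  72,  90),
    c("CP5", 62, -111), c("CP1", 31, -135), c("CP2", 31, 135), c("CP6", 62, 111),
    c("P7",  72, -126), c("P3",  50, -141), c("Pz", 36, 180),
    c("P4",  50,  141), c("P8",  72, 126),
    c("PO3", 61, -157), c("PO4", 61, 157),
    c("O1",  72, -162), c("Oz",  72, 180), c("O2", 72, 162)
  )
  ch <- vapply(spec, function(s) s[1], character(1))
  incl <- as.numeric(vapply(spec, function(s) s[2], character(1))) * pi / 180
  azim <- as.numeric(vapply(spec, function(s) s[3], character(1))) * pi / 180
  tibble::tibble(
    channel = ch,
    x = sin(incl) * sin(azim),
    y = sin(incl) * cos(azim),
    z = cos(incl)
  )
}

#' @noRd
montage_positions <- function(channels = NULL) {
  m <- montage_1010_32()
  if (!is.null(channels)) {
    idx <- match(channels, m$channel)
    if (anyNA(idx)) {
      stop("unknown channel(s): ", paste(channels[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    m <- m[idx, ]
  }
  m
}

# channel groups used for synthetic topographies and ocular scoring
frontal_channels <- function() c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz",
                                 "F4", "F8")
motor_channels <- function() c("FC5", "FC1", "FC2", "FC6", "C3", "Cz", "C4",
                               "CP1", "CP2")

#' Gaussian spatial weight profile centered on a reference channel
#'
#' @param center channel label at the bump's peak.
#' @param width angular width (radians of great-circle distance) of the
#'   Gaussian falloff.
#' @return numeric vector of length 32, max 1 at `center`.
#' @noRd
channel_bump <- function(center, width = 0.7) {
  m <- montage_positions()
  p0 <- unlist(m[m$channel == center, c("x", "y", "z")])
  d <- acos(pmin(1, pmax(-1, as.matrix(m[, c("x", "y", "z")]) %*% p0)))
  w <- exp(-0.5 * (d / width)^2)
  as.numeric(w)
}
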