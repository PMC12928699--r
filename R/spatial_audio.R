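#' Head/source geometry for binaural rendering
#'
#' Describes the geometry used to position a virtual sound source on the
#' display plane: the signed horizontal offset of the source from the display
#' centre, the forward distance from the ears to the display, the head
#' radius, and the speed of sound. Interaural time differences follow from
#' the difference in path length between the two ears, with the head radius
#' added to the horizontal offset for the left ear and subtracted for the
#' right.
#'
#' @param x Horizontal offset of the source from the display centre, metres
#'   (positive = right).
#' @param z Forward distance from the ears to the display plane, metres.
#' @param r Head radius, metres (default 0.08).
#' @param s Speed of sound, metres/second (default 343).
#' @return An object of class `head_geometry`.
#' @examples
#' geom <- head_geometry(x = 0, z = 0.54)
#' path_lengths(geom)
#' @export
head_geometry <- function(x, z, r = 0.08, s = 343) {
  vals <- c(x = x, z = z, r = r, s = s)
  if (!all(is.finite(vals))) {
    stop("invalid geometry: all of x, z, r, s must be finite", call. = FALSE)
  }
  if (z <= 0) stop("invalid geometry: z must be > 0", call. = FALSE)
  if (r < 0) stop("invalid geometry: r must be >= 0", call. = FALSE)
  if (s <= 0) stop("invalid geometry: s must be > 0", call. = FALSE)
  structure(list(x = x, z = z, r = r, s = s), class = "head_geometry")
}

#' Acoustic path lengths to the two ears
#'
#' dL = sqrt((x + r)^2 + z^2), dR = sqrt((x - r)^2 + z^2).
#'
#' @param geom A [head_geometry()].
#' @return Named numeric vector `c(dL, dR)`, metres.
#' @export
path_lengths <- function(geom) {
  stopifnot(inherits(geom, "head_geometry"))
  c(dL = sqrt((geom$x + geom$r)^2 + geom$z^2),
    dR = sqrt((geom$x - geom$r)^2 + geom$z^2))
}

#' Arrival times at the two ears
#'
#' The interaural time difference is `tL - tR`.
#'
#' @inheritParams path_lengths
#' @return Named numeric vector `c(tL, tR)`, seconds.
#' @export
itd_seconds <- function(geom) {
  d <- path_lengths(geom)
  c(tL = unname(d["dL"]) / geom$s, tR = unname(d["dR"]) / geom$s)
}

#' Interaural level gains
#'
#' Distance attenuation of a unit-amplitude source: each channel is divided
#' by its path length, so the gains are the reciprocal distances.
#'
#' @inheritParams path_lengths
#' @return Named numeric vector `c(gL, gR)`, dimensionless amplitude.
#' @export
ild_gains <- function(geom) {
  d <- path_lengths(geom)
  c(gL = 1 / unname(d["dL"]), gR = 1 / unname(d["dR"]))
}

#' Convert an azimuth in degrees of visual angle to a horizontal offset
#'
#' Stimuli are positioned in degrees of visual angle on a plane at viewing
#' distance `z`, so the horizontal offset is `x = z * tan(theta)`.
#'
#' @param location_deg Azimuth, degrees (positive = right).
#' @param z Viewing distance, metres.
#' @return Horizontal offset, metres.
#' @export
azimuth_to_x <- function(location_deg, z) {
  z * tan(location_deg * pi / 180)
}

#' Render a spatially localised stereo tone
#'
#' Renders a decaying sinusoid as heard from a virtual source at
#' `location_deg` azimuth: each channel is delayed by its relative arrival
#' time (fractional delay by linear interpolation of the time axis, zero
#' padded before onset) and scaled by its distance gain. Only the interaural
#' difference in arrival time is applied; the common absolute delay is
#' dropped.
#'
#' @param location_deg Source azimuth, degrees of visual angle.
#' @param geom A [head_geometry()]; its `x` is ignored and replaced by
#'   `azimuth_to_x(location_deg, geom$z)`.
#' @param freq Tone frequency, Hz.
#' @param dur Tone duration, seconds.
#' @param rate Sample rate, Hz.
#' @param decay_tau Exponential decay time constant, seconds.
#' @return A `stereo_render` list with elements `left`, `right` (equal-length
#'   waveforms), `sample_rate`, `itd` (seconds, left minus right arrival
#'   time), and `gains` `c(gL, gR)`.
#' @examples
#' geom <- head_geometry(x = 0, z = 0.54)
#' snd <- render_tone(7.5, geom)
#' length(snd$left)  # 4410 samples for 0.1 s at 44100 Hz
#' @export
render_tone <- function(location_deg, geom, freq = 850, dur = 0.1,
                        rate = 44100, decay_tau = 0.03) {
  stopifnot(inherits(geom, "head_geometry"))
  n <- round(dur * rate)
  if (n < 2) stop("degenerate tone: dur * rate must be >= 2 samples", call. = FALSE)
  g <- head_geometry(azimuth_to_x(location_deg, geom$z), geom$z, geom$r, geom$s)
  tt <- itd_seconds(g)
  gains <- ild_gains(g)
  # relative delays; the later-arriving channel is shifted, the earlier is not
  delays <- c(tt["tL"], tt["tR"]) - min(tt)
  t_axis <- (seq_len(n) - 1) / rate
  src <- function(t) {
    out <- sin(2 * pi * freq * t) * exp(-t / decay_tau)
    out[t < 0] <- 0
    out
  }
  # fractional delay by linear interpolation of the sampled source,
  # zero padded before onset
  delay_lin <- function(wave, delay_s) {
    d <- delay_s * rate
    if (d == 0) return(wave)
    stats::approx(x = seq_len(n) - 1 + d, y = wave, xout = seq_len(n) - 1,
                  method = "linear", yleft = 0, yright = 0)$y
  }
  base <- src(t_axis)
  left <- unname(gains["gL"] * delay_lin(base, delays[1]))
  right <- unname(gains["gR"] * delay_lin(base, delays[2]))
  structure(list(left = left, right = right, sample_rate = rate,
                 itd = unname(tt["tL"] - tt["tR"]),
                 gains = unname(gains)),
            class = "stereo_render")
}

#' Write a stereo render as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer (16-bit PCM, interleaved stereo). Waveforms are
#' scaled by `scale` and clipped to [-1, 1] before quantisation.
#'
#' @param render A `stereo_render` from [render_tone()].
#' @param path Output file path.
#' @param scale Amplitude scale applied before quantisation.
#' @return `path`, invisibly.
#' @export
write_wav <- function(render, path, scale = 1) {
  stopifnot(inherits(render, "stereo_render"))
  l <- pmin(1, pmax(-1, render$left * scale))
  r <- pmin(1, pmax(-1, render$right * scale))
  pcm <- as.integer(round(as.vector(rbind(l, r)) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(2L, con, size = 2, endian = "little")            # stereo
  writeBin(as.integer(render$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(render$sample_rate * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
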