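#' Re-reference epochs to the sensor average
#'
#' Subtracts, at every trial and sample, the mean over sensors, so the
#' sensor mean of the output is zero everywhere. Linear, idempotent, and
#' rejects any common-mode (offset) component.
#'
#' @param epochs An [epoch_set()] with at least two sensors.
#' @return The re-referenced [epoch_set()].
#' @export
rereference_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[2] < 2) stop("average re-reference needs >= 2 sensors", call. = FALSE)
  mu <- apply(epochs$data, c(1, 3), mean)          # trials x time
  epochs$data <- epochs$data - aperm(array(mu, c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Extracts a half-open window `[window[1], window[2])` around each onset.
#' The sample at time zero is the first sample at or after the onset, and
#' the window start is `ceiling(window[1] * rate)` samples relative to it,
#' with `floor(diff(window) * rate)` samples per epoch (e.g. 307 samples
#' for a [-0.1, 0.5) window at 512 Hz). Onsets too close to the recording
#' edge are dropped with a warning.
#'
#' @param continuous Numeric matrix, sensors x samples.
#' @param onsets_s Stimulus onset times, seconds from recording start.
#' @param sample_rate Sampling rate, Hz.
#' @param window Epoch window in seconds (default `c(-0.1, 0.5)`).
#' @param labels Optional data frame of per-onset labels (subset along with
#'   surviving onsets).
#' @return An [epoch_set()].
#' @export
segment_epochs <- function(continuous, onsets_s, sample_rate,
                           window = c(-0.1, 0.5), labels = NULL) {
  stopifnot(is.matrix(continuous), window[2] > window[1])
  n_samp <- ncol(continuous)
  s_start <- ceiling(window[1] * sample_rate)
  count <- floor((window[2] - window[1]) * sample_rate)
  onset_idx <- ceiling(onsets_s * sample_rate) + 1L   # first sample >= onset
  lo <- onset_idx + s_start
  hi <- lo + count - 1L
  ok <- lo >= 1L & hi <= n_samp
  if (any(!ok)) {
    warning(sum(!ok), " onset(s) too close to the recording edge; dropped")
  }
  lo <- lo[ok]
  n <- length(lo)
  dat <- array(0, c(n, nrow(continuous), count))
  for (i in seq_len(n)) {
    dat[i, , ] <- continuous[, lo[i]:(lo[i] + count - 1L)]
  }
  if (is.null(labels)) {
    labels <- data.frame(condition = rep("A", n), location_deg = rep(0, n))
  } else {
    labels <- labels[ok, , drop = FALSE]
  }
  times <- (s_start + seq_len(count) - 1) / sample_rate
  epoch_set(dat, times, sample_rate, labels)
}

# apply a filter function time-wise to every trial x sensor trace
filter_epochs <- function(epochs, fun) {
  d <- dim(epochs$data)
  for (i in seq_len(d[1])) {
    epochs$data[i, , ] <- t(apply(epochs$data[i, , , drop = FALSE][1, , ],
                                  1, fun))
  }
  epochs
}

#' Down-sample epochs by an integer factor
#'
#' Anti-alias low-pass filtering (zero-phase 4th-order Butterworth at 0.8 of
#' the new Nyquist frequency, applied forward and backward) followed by
#' decimation. A factor of 1 is the identity.
#'
#' @param epochs An [epoch_set()].
#' @param factor Integer decimation factor >= 1.
#' @return The down-sampled [epoch_set()].
#' @export
downsample <- function(epochs, factor) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (factor != round(factor) || factor < 1) {
    stop("decimation factor must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(epochs)
  bf <- signal::butter(4, 0.8 / factor, type = "low")
  epochs <- filter_epochs(epochs, function(x) {
    as.numeric(signal::filtfilt(bf, x))
  })
  pick <- seq(1, dim(epochs$data)[3], by = factor)
  epochs$data <- epochs$data[, , pick, drop = FALSE]
  epochs$times <- epochs$times[pick]
  epochs$sample_rate <- epochs$sample_rate / factor
  epochs
}

#' High-pass filter epochs to remove slow drifts
#'
#' Zero-phase (forward-backward) 2nd-order Butterworth high-pass at
#' `cutoff` Hz. Zero-phase filtering preserves stimulus-locked latencies.
#'
#' @param epochs An [epoch_set()].
#' @param cutoff Cutoff frequency in Hz (default 0.25); must be below the
#'   Nyquist frequency.
#' @return The filtered [epoch_set()].
#' @export
highpass <- function(epochs, cutoff = 0.25) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$sample_rate / 2
  if (cutoff >= nyq) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(2, cutoff / nyq, type = "high")
  filter_epochs(epochs, function(x) as.numeric(signal::filtfilt(bf, x)))
}

#' Exclude trials with large eye movements
#'
#' A trial is kept iff the maximum Euclidean deviation of 2-D gaze from
#' fixation over the whole epoch stays at or below the threshold (default
#' 3.75 degrees of visual angle). Exclusion is label-blind.
#'
#' @param epochs An [epoch_set()].
#' @param gaze A gaze trace set from [simulate_gaze()] (or any list with
#'   trials x samples matrices `x` and `y` in degrees).
#' @param threshold_deg Exclusion threshold, degrees (default 3.75).
#' @return List with `epochs` (kept flags updated) and `report`, a data
#'   frame of kept/excluded counts per condition.
#' @export
exclude_eye_trials <- function(epochs, gaze, threshold_deg = 3.75) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- dim(epochs$data)[1]
  if (nrow(gaze$x) != n || nrow(gaze$y) != n) {
    stop("gaze traces (", nrow(gaze$x), " trials) do not match epochs (",
         n, " trials)", call. = FALSE)
  }
  dev <- sqrt(gaze$x^2 + gaze$y^2)
  max_dev <- apply(dev, 1, max)
  keep <- max_dev <= threshold_deg
  epochs$labels$kept <- epochs$labels$kept & keep
  report <- aggregate(list(kept = keep),
                      by = list(condition = epochs$labels$condition),
                      FUN = function(k) sum(k))
  report$total <- as.vector(table(epochs$labels$condition)[report$condition])
  report$excluded <- report$total - report$kept
  list(epochs = epochs, report = report, max_deviation = max_dev)
}
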