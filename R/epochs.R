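#' Stimulus-locked multichannel epochs
#'
#' The central container of the package: a trials x sensors x time array of
#' stimulus-locked activity together with a per-trial label table and a
#' uniform time axis. Per timepoint, the sensors x trials slice is the data
#' matrix of the linear encoding model (see [fit_forward()]).
#'
#' @param data Numeric array, trials x sensors x time.
#' @param times Numeric vector of sample times in seconds relative to
#'   stimulus onset; strictly increasing and uniform.
#' @param sample_rate Sampling rate in Hz.
#' @param labels Data frame with one row per trial; must contain at least
#'   `condition` and `location_deg`; a logical `kept` column is added if
#'   absent.
#' @param sensor_names Optional character vector of sensor names.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sample_rate, labels, sensor_names = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(times) != dim(data)[3]) {
    stop("times length must equal the third dimension of data", call. = FALSE)
  }
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-9)) {
    stop("time axis must be strictly increasing and uniform", call. = FALSE)
  }
  if (!is.data.frame(labels) || nrow(labels) != dim(data)[1]) {
    stop("labels must be a data frame with one row per trial", call. = FALSE)
  }
  if (!all(c("condition", "location_deg") %in% names(labels))) {
    stop("labels must contain condition and location_deg columns", call. = FALSE)
  }
  if (is.null(labels$kept)) labels$kept <- rep(TRUE, nrow(labels))
  if (is.null(sensor_names)) {
    sensor_names <- sprintf("S%02d", seq_len(dim(data)[2]))
  }
  structure(list(data = data, times = as.numeric(times),
                 sample_rate = sample_rate, labels = labels,
                 sensor_names = sensor_names),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d sensors x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sample_rate))
  cat(sprintf("  time %g to %g s; conditions: %s; %d trials kept\n",
              min(x$times), max(x$times),
              paste(sort(unique(x$labels$condition)), collapse = "/"),
              sum(x$labels$kept)))
  invisible(x)
}

#' Subset an epoch set by trial
#'
#' @param epochs An [epoch_set()].
#' @param idx Logical or integer trial index.
#' @return An [epoch_set()] with the selected trials.
#' @export
subset_trials <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$times,
            epochs$sample_rate, epochs$labels[idx, , drop = FALSE],
            epochs$sensor_names)
}

# container format version for the on-disk layout
EPOCHS_FORMAT_VERSION <- 1L

#' Write an epoch set to disk
#'
#' Writes a directory holding `data.csv` (one row per trial x sensor, one
#' column per sample, full float64 precision), `labels.csv`, and a
#' `meta.json` sidecar carrying dimensions, the time axis, sample rate,
#' sensor names and a format version. The round trip through
#' [read_epochs()] is lossless (bit-exact for float64 payloads).
#'
#' @param epochs An [epoch_set()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  # 17 significant digits guarantee an exact float64 round trip via strtod
  con <- file(file.path(path, "data.csv"), "w")
  writeLines(paste(sprintf("t%03d", seq_len(d[3])), collapse = ","), con)
  writeLines(apply(flat, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = ",")
  }), con)
  close(con)
  readr::write_csv(epochs$labels, file.path(path, "labels.csv"), progress = FALSE)
  meta <- list(format = "avencode-epochs", version = EPOCHS_FORMAT_VERSION,
               n_trials = d[1], n_sensors = d[2], n_samples = d[3],
               sample_rate = epochs$sample_rate, times = epochs$times,
               sensor_names = epochs$sensor_names)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path Directory produced by [write_epochs()].
#' @return An [epoch_set()].
#' @export
read_epochs <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    stop("not an epoch container: missing meta.json in ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (!identical(meta$format, "avencode-epochs")) {
    stop("unrecognised epoch container format: ", meta$format, call. = FALSE)
  }
  if (meta$version > EPOCHS_FORMAT_VERSION) {
    stop("epoch container version ", meta$version,
         " is newer than supported (", EPOCHS_FORMAT_VERSION, ")", call. = FALSE)
  }
  vals <- tryCatch(
    scan(file.path(path, "data.csv"), what = double(), sep = ",",
         skip = 1, quiet = TRUE),
    warning = function(w) stop("epoch container data payload is corrupt",
                               call. = FALSE))
  labels <- as.data.frame(readr::read_csv(file.path(path, "labels.csv"),
                                          show_col_types = FALSE, progress = FALSE))
  n_tr <- meta$n_trials; n_se <- meta$n_sensors; n_ti <- meta$n_samples
  if (length(vals) != n_tr * n_se * n_ti || nrow(labels) != n_tr) {
    stop("epoch container is truncated or inconsistent with its metadata",
         call. = FALSE)
  }
  flat <- matrix(vals, nrow = n_tr * n_se, ncol = n_ti, byrow = TRUE)
  dat <- aperm(array(t(flat), dim = c(n_ti, n_se, n_tr)), c(3, 2, 1))
  epoch_set(dat, meta$times, meta$sample_rate, labels, meta$sensor_names)
}
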