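#' Univariate event-related potential
#'
#' Averages activity over the kept trials of one condition (optionally one
#' location) and then over a sensor subset, per timepoint. By default the
#' mean over the pre-stimulus interval is subtracted (baseline correction);
#' disable with `baseline = FALSE`.
#'
#' @param epochs An [epoch_set()].
#' @param condition Condition label to select.
#' @param location Optional stimulus location to select (default: all).
#' @param sensors Optional integer or character subset of sensors (default:
#'   all).
#' @param baseline Logical; subtract the mean over times < 0 (default TRUE).
#' @return An `erp_timecourse` list: `time`, `amplitude`, `condition`,
#'   `location`, `n_trials`.
#' @export
compute_erp <- function(epochs, condition, location = NULL, sensors = NULL,
                        baseline = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$labels$kept & epochs$labels$condition == condition
  if (!is.null(location)) sel <- sel & epochs$labels$location_deg == location
  if (!any(sel)) {
    stop("empty cell: no kept trials for condition ", condition,
         if (!is.null(location)) paste0(" at ", location, " deg"),
         call. = FALSE)
  }
  if (is.null(sensors)) sensors <- seq_len(dim(epochs$data)[2])
  if (is.character(sensors)) sensors <- match(sensors, epochs$sensor_names)
  sub <- epochs$data[sel, sensors, , drop = FALSE]
  amp <- apply(sub, 3, mean)
  if (baseline) {
    pre <- epochs$times < 0
    if (any(pre)) amp <- amp - mean(amp[pre])
  }
  structure(list(time = epochs$times, amplitude = amp,
                 condition = condition, location = location,
                 n_trials = sum(sel)),
            class = "erp_timecourse")
}

#' Additive ERP contrast: (A + V) - AV
#'
#' The pointwise difference between the summed unisensory responses and the
#' audiovisual response. Zero everywhere means the audiovisual evoked
#' response is exactly additive; systematic negative values indicate
#' super-additive amplitude.
#'
#' @param erp_a,erp_v,erp_av `erp_timecourse` objects on identical time
#'   axes.
#' @return An `erp_timecourse` holding the difference.
#' @export
additive_contrast <- function(erp_a, erp_v, erp_av) {
  if (!isTRUE(all.equal(erp_a$time, erp_v$time)) ||
      !isTRUE(all.equal(erp_a$time, erp_av$time))) {
    stop("ERP time axes do not match", call. = FALSE)
  }
  structure(list(time = erp_a$time,
                 amplitude = (erp_a$amplitude + erp_v$amplitude) -
                   erp_av$amplitude,
                 condition = "(A+V)-AV", location = erp_a$location,
                 n_trials = NA_integer_),
            class = "erp_timecourse")
}
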