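#' Ideal-observer parameters for behavioural simulation
#'
#' Describes a maximum-likelihood-estimation (MLE) observer: each modality
#' delivers an unbiased location estimate corrupted by Gaussian noise, and
#' the audiovisual estimate combines the two by reliability weighting, so
#' `sigmaAV^2 = sigmaA^2 * sigmaV^2 / (sigmaA^2 + sigmaV^2)`.
#'
#' @param sigma_a Auditory localisation noise SD, degrees.
#' @param sigma_v Visual localisation noise SD, degrees.
#' @param lapse Lapse probability (uniform guessing), in [0, 0.5).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(sigma_a = 4, sigma_v = 5, lapse = 0) {
  if (!(sigma_a > 0 && sigma_v > 0)) stop("sigmas must be > 0", call. = FALSE)
  if (!(lapse >= 0 && lapse < 0.5)) stop("lapse must be in [0, 0.5)", call. = FALSE)
  structure(list(sigma_a = sigma_a, sigma_v = sigma_v, lapse = lapse),
            class = "observer_params")
}

#' Condition-specific observer noise SD
#'
#' @param params An [observer_params()].
#' @param condition "A", "V" or "AV".
#' @return Noise SD in degrees; for "AV" the MLE-combined SD.
#' @export
observer_sigma <- function(params, condition) {
  s <- switch(condition,
              A = params$sigma_a,
              V = params$sigma_v,
              AV = sqrt(params$sigma_a^2 * params$sigma_v^2 /
                          (params$sigma_a^2 + params$sigma_v^2)),
              stop("unknown condition: ", condition, call. = FALSE))
  s
}

#' Generative configuration for synthetic multichannel epochs
#'
#' Ground-truth parameters of the epoch generator. The tuned (spatially
#' selective) component has per-condition gains `gain_a`, `gain_v`, and for
#' the audiovisual condition `gain_a + gain_v + gamma`: `gamma = 0` makes the
#' tuned audiovisual signal exactly additive, `gamma > 0` injects the
#' non-linear (super-additive) interaction. The untuned evoked component is
#' identical across locations and additive by default
#' (`evoked_amp["AV"] = evoked_amp["A"] + evoked_amp["V"]`), mirroring the
#' dissociation under study: additive event-related potentials alongside a
#' possibly super-additive multivariate code.
#'
#' @param n_sensors Number of sensors (default 64).
#' @param sample_rate_hz Sampling rate (default 512).
#' @param epoch_window_s Epoch window, seconds, half-open (default
#'   `c(-0.1, 0.5)`).
#' @param basis A [channel_basis()] describing the tuned location channels.
#' @param gain_a,gain_v Tuned-component gains for the unisensory conditions.
#' @param gamma Extra tuned gain in the audiovisual condition (dimensionless;
#'   0 = exactly additive).
#' @param evoked_amp Named numeric, untuned evoked amplitudes per condition.
#' @param tuned_latency_s,tuned_width_s Gaussian temporal kernel of the
#'   tuned component (defaults peak 0.18 s, SD 0.03 s).
#' @param evoked_latency_s,evoked_width_s Kernel of the untuned evoked
#'   component (defaults peak 0.10 s, SD 0.02 s).
#' @param noise_sd Sensor noise SD per sample.
#' @param noise_spatial_corr Weight in [0, 1) of a smooth spatially
#'   correlated noise component (0 = white across sensors).
#' @param noise_ar1 AR(1) coefficient of temporal noise correlation in
#'   [0, 1).
#' @param seed Integer seed controlling all randomness of the generator.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sensors = 64, sample_rate_hz = 512,
                       epoch_window_s = c(-0.1, 0.5),
                       basis = channel_basis(),
                       gain_a = 1, gain_v = 1, gamma = 0,
                       evoked_amp = c(A = 1, V = 1, AV = 2),
                       tuned_latency_s = 0.18, tuned_width_s = 0.03,
                       evoked_latency_s = 0.10, evoked_width_s = 0.02,
                       noise_sd = 1, noise_spatial_corr = 0.3,
                       noise_ar1 = 0, seed = 1L) {
  if (gain_a < 0 || gain_v < 0) stop("gains must be >= 0", call. = FALSE)
  if (!(noise_spatial_corr >= 0 && noise_spatial_corr < 1)) {
    stop("noise_spatial_corr must be in [0, 1)", call. = FALSE)
  }
  if (!(noise_ar1 >= 0 && noise_ar1 < 1)) {
    stop("noise_ar1 must be in [0, 1)", call. = FALSE)
  }
  if (!all(c("A", "V", "AV") %in% names(evoked_amp))) {
    stop("evoked_amp must name conditions A, V, AV", call. = FALSE)
  }
  structure(list(n_sensors = n_sensors, sample_rate_hz = sample_rate_hz,
                 epoch_window_s = epoch_window_s, basis = basis,
                 gain_a = gain_a, gain_v = gain_v, gamma = gamma,
                 evoked_amp = evoked_amp,
                 tuned_latency_s = tuned_latency_s,
                 tuned_width_s = tuned_width_s,
                 evoked_latency_s = evoked_latency_s,
                 evoked_width_s = evoked_width_s,
                 noise_sd = noise_sd,
                 noise_spatial_corr = noise_spatial_corr,
                 noise_ar1 = noise_ar1, seed = as.integer(seed)),
            class = "sim_config")
}

#' Derive a reproducible sub-seed
#'
#' Deterministically maps a master seed plus any number of integer stream
#' identifiers to a new seed below 2^31, so that every stochastic stage of
#' a pipeline can draw from its own stream while remaining reproducible
#' from a single master seed.
#'
#' @param seed Master seed (integer).
#' @param ... Integer identifiers of the substream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in ids) s <- (s * 48271 + as.double(k) * 7919 + 1) %% 2147483629
  as.integer(s)
}

# the five stimulus locations of the epoch sessions, degrees of azimuth
EEG_LOCATIONS <- c(-15, -7.5, 0, 7.5, 15)

#' Generate the rapid-sequence (EEG-style) session schedule
#'
#' Per condition (A, V, AV): 12 blocks of 10 trials, each trial a sequence
#' of 20 stimulus presentations at locations drawn i.i.d. uniformly from
#' the five azimuths -15, -7.5, 0, 7.5, 15 degrees, for 2400 presentations
#' per condition.
#'
#' @param participant_id Identifier stored with every row.
#' @param n_blocks,n_trials,n_presentations Schedule dimensions (defaults
#'   12, 10, 20).
#' @param conditions Conditions to schedule.
#' @param seed Integer seed.
#' @return Data frame with class `session_schedule`, one row per
#'   presentation: participant_id, session, condition, block, trial,
#'   presentation, location_deg.
#' @export
make_eeg_schedule <- function(participant_id = 1L, n_blocks = 12L,
                              n_trials = 10L, n_presentations = 20L,
                              conditions = c("A", "V", "AV"), seed = 1L) {
  set.seed(derive_seed(seed, 101, participant_id))
  per_cond <- n_blocks * n_trials * n_presentations
  out <- do.call(rbind, lapply(conditions, function(cond) {
    data.frame(participant_id = participant_id, session = "eeg",
               condition = cond,
               block = rep(seq_len(n_blocks), each = n_trials * n_presentations),
               trial = rep(rep(seq_len(n_trials), each = n_presentations),
                           times = n_blocks),
               presentation = rep(seq_len(n_presentations),
                                  times = n_blocks * n_trials),
               location_deg = sample(EEG_LOCATIONS, per_cond, replace = TRUE))
  }))
  rownames(out) <- NULL
  class(out) <- c("session_schedule", class(out))
  out
}

#' Generate the two-interval forced-choice behavioural session schedule
#'
#' Per condition: 48 target presentations at each of 8 locations evenly
#' spaced over [-15, 15] degrees (384 trials), with a central reference
#' stimulus; the interval carrying the target (1 or 2) is randomised per
#' trial and trial order is shuffled.
#'
#' @param participant_id Identifier stored with every row.
#' @param n_per_location Target presentations per location (default 48).
#' @param n_locations Number of target locations (default 8).
#' @param conditions Conditions to schedule.
#' @param seed Integer seed.
#' @return Data frame with class `session_schedule`: participant_id,
#'   session, condition, trial, location_deg, target_interval.
#' @export
make_behavioural_schedule <- function(participant_id = 1L,
                                      n_per_location = 48L, n_locations = 8L,
                                      conditions = c("A", "V", "AV"),
                                      seed = 1L) {
  set.seed(derive_seed(seed, 202, participant_id))
  locs <- seq(-15, 15, length.out = n_locations)
  out <- do.call(rbind, lapply(conditions, function(cond) {
    loc <- sample(rep(locs, each = n_per_location))
    n <- length(loc)
    data.frame(participant_id = participant_id, session = "behavioural",
               condition = cond, trial = seq_len(n), location_deg = loc,
               target_interval = sample(c(1L, 2L), n, replace = TRUE))
  }))
  rownames(out) <- NULL
  class(out) <- c("session_schedule", class(out))
  out
}

#' Simulate ideal-observer behavioural responses
#'
#' For a behavioural (two-interval forced-choice) schedule, the observer
#' forms noisy location estimates of the reference (0 deg) and target
#' stimuli with the condition's MLE noise SD and reports the interval
#' containing the more leftward estimate; `response_rightward` records
#' whether the target was judged right of the reference. For an EEG-style
#' schedule, the observer judges the side of every presentation in a trial
#' (`sign(location + noise)`) and reports the majority side; side-count
#' ties are answered at random. With probability `lapse` a response is a
#' uniform guess.
#'
#' @param schedule A schedule from [make_behavioural_schedule()] or
#'   [make_eeg_schedule()].
#' @param params An [observer_params()].
#' @param seed Integer seed.
#' @return For behavioural schedules, the schedule with columns
#'   `response_rightward`, `response_interval`, `correct`. For EEG
#'   schedules, one row per trial with the true majority side
#'   (`majority_side`: -1 left, 0 tie, 1 right), `response_right`, and the
#'   per-trial signed location sum.
#' @export
simulate_behavioural_responses <- function(schedule, params, seed = 1L) {
  stopifnot(inherits(params, "observer_params"))
  set.seed(derive_seed(seed, 303))
  if (identical(schedule$session[1], "behavioural")) {
    sig <- vapply(schedule$condition, observer_sigma, numeric(1),
                  params = params)
    est_target <- schedule$location_deg + stats::rnorm(nrow(schedule), 0, sig)
    est_ref <- stats::rnorm(nrow(schedule), 0, sig)
    right <- est_target > est_ref
    lapse_hit <- stats::runif(nrow(schedule)) < params$lapse
    right[lapse_hit] <- stats::runif(sum(lapse_hit)) < 0.5
    # which interval held the more leftward stimulus estimate
    target_leftmost <- !right
    resp_interval <- ifelse(target_leftmost, schedule$target_interval,
                            3L - schedule$target_interval)
    out <- schedule
    out$response_rightward <- right
    out$response_interval <- as.integer(resp_interval)
    out$correct <- (schedule$location_deg < 0) == target_leftmost
    return(out)
  }
  # EEG-style sequence task: majority-side judgement per trial
  sig <- vapply(schedule$condition, observer_sigma, numeric(1), params = params)
  est <- schedule$location_deg + stats::rnorm(nrow(schedule), 0, sig)
  key_chr <- paste(schedule$participant_id, schedule$condition,
                   schedule$block, schedule$trial, sep = "\r")
  key <- factor(key_chr, levels = unique(key_chr))   # appearance order
  agg <- function(v, f) as.vector(tapply(v, key, f))
  first <- !duplicated(key)
  n_right <- agg(est > 0, sum)
  n_pres <- agg(est, length)
  resp_right <- n_right > n_pres / 2
  obs_tie <- n_right == n_pres / 2
  resp_right[obs_tie] <- stats::runif(sum(obs_tie)) < 0.5
  lapse_hit <- stats::runif(length(resp_right)) < params$lapse
  resp_right[lapse_hit] <- stats::runif(sum(lapse_hit)) < 0.5
  n_right_true <- agg(schedule$location_deg > 0, sum)
  n_left_true <- agg(schedule$location_deg < 0, sum)
  data.frame(participant_id = schedule$participant_id[first],
             condition = schedule$condition[first],
             block = schedule$block[first], trial = schedule$trial[first],
             majority_side = sign(n_right_true - n_left_true),
             location_sum = agg(schedule$location_deg, sum),
             response_right = resp_right)
}

# Gaussian-smoothed random vectors across the sensor array: a crude but
# seed-stable stand-in for a smooth scalp projection
smooth_loadings <- function(n_sensors, n_cols, smooth_sd) {
  raw <- matrix(stats::rnorm(n_sensors * n_cols), n_sensors, n_cols)
  if (smooth_sd <= 0) return(raw)
  idx <- seq_len(n_sensors)
  k <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * smooth_sd^2)))
  k <- k / rowSums(k)
  sm <- k %*% raw
  # rescale columns to unit RMS so gains keep their meaning
  sm / rep(sqrt(colMeans(sm^2)), each = n_sensors)
}

# sensor-space noise covariance: (1 - rho) I + rho * smooth correlation
make_noise_cov <- function(n_sensors, rho, smooth_sd = n_sensors / 8) {
  if (rho == 0) return(diag(n_sensors))
  idx <- seq_len(n_sensors)
  r <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * smooth_sd^2)))
  sig <- (1 - rho) * diag(n_sensors) + rho * r
  sig
}

#' Simulate multichannel epochs with known spatial tuning
#'
#' The generative mirror of the linear encoding model: per presentation the
#' five-channel basis response to the stimulus location is projected to the
#' sensors through a fixed smooth random loading matrix - one per modality,
#' since auditory and visual responses occupy different scalp topographies -
#' and modulated by a Gaussian temporal kernel peaking at the information
#' latency. The unisensory conditions carry gains `gain_a` and `gain_v`;
#' the audiovisual tuned signal is the sum of the two unisensory
#' projections scaled so its total gain is `gain_a + gain_v + gamma`, which
#' makes `gamma = 0` exactly additive in sensor space (and, because the
#' loading matrices are near-orthogonal, makes the additive condition's
#' decoder sensitivity match the MLE quadrature prediction rather than
#' exceed it). An untuned evoked component (identical across locations,
#' earlier peak) and spatially correlated Gaussian sensor noise are added.
#' All randomness derives from `sim$seed` and the participant id.
#'
#' @param schedule An EEG-style schedule (one participant).
#' @param sim A [sim_config()].
#' @return A list with `epochs` (an [epoch_set()]) and `ground_truth`
#'   (loading matrix `M`, untuned pattern, per-condition tuned gains,
#'   `gamma`, kernels and seed).
#' @export
simulate_epochs <- function(schedule, sim) {
  stopifnot(inherits(sim, "sim_config"))
  pid <- schedule$participant_id[1]
  if (length(unique(schedule$participant_id)) != 1) {
    stop("simulate_epochs expects a single participant's schedule", call. = FALSE)
  }
  m <- sim$n_sensors
  rate <- sim$sample_rate_hz
  w <- sim$epoch_window_s
  s0 <- ceiling(w[1] * rate)
  n_t <- floor((w[2] - w[1]) * rate)
  times <- (s0 + seq_len(n_t) - 1) / rate
  n <- nrow(schedule)

  sig_noise <- make_noise_cov(m, sim$noise_spatial_corr)
  ev <- eigen(sig_noise, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("noise covariance is not positive definite", call. = FALSE)
  chol_l <- t(chol(sig_noise))

  # participant-level structure (fixed by seed + participant): each
  # modality projects the tuned channels through its own smooth random
  # loading matrix (auditory and visual topographies differ on a real
  # scalp); the audiovisual tuned signal is the sum of the two unisensory
  # projections, rescaled by (gA + gV + gamma)/(gA + gV) so that gamma = 0
  # is exactly additive in sensor space while the total tuned gain is
  # gA + gV + gamma
  set.seed(derive_seed(sim$seed, 404, pid))
  n_ch <- length(sim$basis$centres)
  loading_a <- smooth_loadings(m, n_cols = n_ch, smooth_sd = m / 16)
  loading_v <- smooth_loadings(m, n_cols = n_ch, smooth_sd = m / 16)
  # evoked topography rides on a consistent polarity (unit offset) so the
  # sensor-averaged ERP reflects the evoked amplitudes
  untuned <- smooth_loadings(m, 1, smooth_sd = m / 16)[, 1] + 1

  kern <- function(peak, width) exp(-(times - peak)^2 / (2 * width^2))
  a_t <- kern(sim$tuned_latency_s, sim$tuned_width_s)
  u_t <- kern(sim$evoked_latency_s, sim$evoked_width_s)

  gains <- c(A = sim$gain_a, V = sim$gain_v,
             AV = sim$gain_a + sim$gain_v + sim$gamma)
  av_scale <- if (sim$gain_a + sim$gain_v > 0) {
    gains["AV"] / (sim$gain_a + sim$gain_v)
  } else 0
  loading_cond <- list(A = sim$gain_a * loading_a,
                       V = sim$gain_v * loading_v,
                       AV = av_scale * (sim$gain_a * loading_a +
                                          sim$gain_v * loading_v))
  cmat <- design_matrix(sim$basis, schedule$location_deg)   # 5 x n
  e_tr <- sim$evoked_amp[schedule$condition]
  tuned_sensor <- matrix(0, m, n)
  for (cond in unique(schedule$condition)) {
    j <- schedule$condition == cond
    tuned_sensor[, j] <- loading_cond[[cond]] %*% cmat[, j, drop = FALSE]
  }

  set.seed(derive_seed(sim$seed, 505, pid))
  noise <- chol_l %*% matrix(stats::rnorm(m * n_t * n), m, n_t * n) * sim$noise_sd
  noise <- array(noise, c(m, n_t, n))
  if (sim$noise_ar1 > 0) {
    phi <- sim$noise_ar1
    for (t in 2:n_t) noise[, t, ] <- phi * noise[, t - 1, ] + sqrt(1 - phi^2) * noise[, t, ]
  }

  dat <- array(0, c(n, m, n_t))
  for (i in seq_len(n)) {
    dat[i, , ] <- outer(tuned_sensor[, i], a_t) +
      outer(untuned * e_tr[i], u_t) + noise[, , i]
  }

  labels <- data.frame(participant = pid,
                       condition = schedule$condition,
                       location_deg = schedule$location_deg,
                       block = schedule$block, trial = schedule$trial,
                       presentation = schedule$presentation,
                       kept = TRUE)
  list(epochs = epoch_set(dat, times, rate, labels),
       ground_truth = list(M_A = loading_a, M_V = loading_v,
                           loading_cond = loading_cond,
                           untuned_pattern = untuned,
                           gains = gains, gamma = sim$gamma,
                           tuned_kernel = a_t, evoked_kernel = u_t,
                           noise_cov = sig_noise, seed = sim$seed))
}

#' Simulate gaze traces for the eye-movement exclusion rule
#'
#' Each presentation gets a two-dimensional fixation-jitter trace; with
#' probability `saccade_prob` the trace additionally contains a horizontal
#' excursion of amplitude `saccade_amp` degrees for the second half of the
#' epoch.
#'
#' @param n_trials Number of presentations.
#' @param n_samples Samples per trace (match the epochs' time axis).
#' @param saccade_prob Probability a presentation contains a saccade.
#' @param saccade_amp Saccade amplitude, degrees.
#' @param jitter_sd Fixation jitter SD, degrees (default 0.1).
#' @param seed Integer seed.
#' @return A list with `x`, `y` (trials x samples matrices, degrees from
#'   fixation) and the logical `saccade` vector of ground truth.
#' @export
simulate_gaze <- function(n_trials, n_samples, saccade_prob = 0,
                          saccade_amp = 5, jitter_sd = 0.1, seed = 1L) {
  set.seed(derive_seed(seed, 606))
  x <- matrix(stats::rnorm(n_trials * n_samples, 0, jitter_sd),
              n_trials, n_samples)
  y <- matrix(stats::rnorm(n_trials * n_samples, 0, jitter_sd),
              n_trials, n_samples)
  sacc <- stats::runif(n_trials) < saccade_prob
  half <- seq.int(floor(n_samples / 2) + 1, n_samples)
  if (any(sacc)) {
    dir <- sample(c(-1, 1), sum(sacc), replace = TRUE)
    x[sacc, half] <- x[sacc, half] + dir * saccade_amp
  }
  list(x = x, y = y, saccade = sacc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
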