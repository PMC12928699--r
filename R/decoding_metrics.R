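# ideal channel vectors for each stimulus location: mean-centred then
# unit-normalised basis responses; centring makes the accuracy score
# invariant to a constant added to all channels and puts chance at zero
ideal_vectors <- function(basis, locations) {
  v <- design_matrix(basis, locations)     # channels x locations
  v <- sweep(v, 2, colMeans(v))
  sweep(v, 2, sqrt(colSums(v^2)), "/")
}

# per-trial accuracy scores for a trials x channels matrix of
# reconstructions at one timepoint; normalize = TRUE scores the direction
# of the reconstruction only (cosine variant), which bounds the score and
# tames heavy tails from ill-conditioned inversions
accuracy_score_trials <- function(recon_mat, true_locations, basis,
                                  location_set = sort(unique(true_locations)),
                                  normalize = FALSE) {
  if (normalize) {
    nn <- sqrt(rowSums(recon_mat^2))
    recon_mat <- recon_mat / pmax(nn, 1e-12)
  }
  ideals <- ideal_vectors(basis, location_set)        # channels x locations
  proj <- recon_mat %*% ideals                        # trials x locations
  true_col <- match(true_locations, location_set)
  proj[cbind(seq_len(nrow(proj)), true_col)] - rowMeans(proj)
}

#' Decoding accuracy timecourse
#'
#' Scores each reconstructed channel vector by its projection onto the
#' ideal (mean-centred, unit-normalised) channel vector of the presented
#' location minus the mean projection onto all locations' ideal vectors,
#' averaged over trials. The units are arbitrary and chance is zero by
#' construction.
#'
#' @param recon A `reconstruction` from [cross_validated_reconstruct()].
#' @param location_set Candidate locations for the comparison set (default:
#'   the distinct presented locations).
#' @param mode "projection" (default) scores the raw reconstruction;
#'   "cosine" scores its direction only (unit-normalised per trial).
#' @return List with `time` and `accuracy` (mean over trials per
#'   timepoint), plus the per-trial score matrix `trial_scores`.
#' @export
accuracy_score <- function(recon, location_set = NULL,
                           mode = c("projection", "cosine")) {
  stopifnot(inherits(recon, "reconstruction"))
  mode <- match.arg(mode)
  locs <- recon$labels$location_deg
  if (is.null(location_set)) location_set <- sort(unique(locs))
  n_t <- dim(recon$activities)[3]
  scores <- matrix(NA_real_, dim(recon$activities)[1], n_t)
  for (t in seq_len(n_t)) {
    scores[, t] <- accuracy_score_trials(recon$activities[, , t], locs,
                                         recon$basis, location_set,
                                         normalize = mode == "cosine")
  }
  list(time = recon$times, accuracy = colMeans(scores),
       trial_scores = scores)
}

#' Point estimate of decoded location
#'
#' Rectified centroid of the reconstructed channel activities: negative
#' activities are clipped to zero and the channel centres are averaged with
#' the remaining activities as weights. Trials where every activity is
#' non-positive are flagged degenerate and read out as zero.
#'
#' @param recon A `reconstruction`.
#' @return List with `estimate` (trials x time matrix, degrees) and
#'   `degenerate` (logical matrix of flagged readouts).
#' @export
location_estimate <- function(recon) {
  stopifnot(inherits(recon, "reconstruction"))
  centres <- recon$basis$centres
  act <- aperm(pmax(recon$activities, 0), c(2, 1, 3))  # channels x trials x time
  denom <- colSums(act)                                # trials x time
  num <- colSums(act * centres)
  degenerate <- denom <= 0
  est <- ifelse(degenerate, 0, num / ifelse(denom > 0, denom, 1))
  list(estimate = est, degenerate = degenerate)
}

# d' from hit and false-alarm counts with the 1/(2N) clipping rule
dprime_from_counts <- function(n_hit, n_signal, n_fa, n_noise) {
  clip <- function(p, n) pmin(1 - 1 / (2 * n), pmax(1 / (2 * n), p))
  stats::qnorm(clip(n_hit / n_signal, n_signal)) -
    stats::qnorm(clip(n_fa / n_noise, n_noise))
}

#' Decoder sensitivity (d') timecourse
#'
#' Binarises the decoded locations into left/right of centre, omitting
#' trials where the stimulus appeared at the display centre, and computes
#' the signal-detection sensitivity per timepoint with "right" as the
#' signal: hits are decoded-right given presented-right, false alarms
#' decoded-right given presented-left. Proportions are clipped to
#' `[1/(2N), 1 - 1/(2N)]` before the normal quantile transform.
#'
#' @param estimates Trials x time matrix of decoded locations (degrees),
#'   from [location_estimate()].
#' @param true_locations Per-trial presented locations, degrees.
#' @return List with `dprime` (per timepoint), `n_left`, `n_right`.
#' @export
decoder_dprime <- function(estimates, true_locations) {
  stopifnot(nrow(estimates) == length(true_locations))
  keep <- true_locations != 0
  est <- estimates[keep, , drop = FALSE]
  side <- true_locations[keep] > 0
  n_r <- sum(side)
  n_l <- sum(!side)
  if (n_r == 0 || n_l == 0) {
    stop("both sides must be represented to compute d'", call. = FALSE)
  }
  hits <- colSums(est[side, , drop = FALSE] > 0)
  fas <- colSums(est[!side, , drop = FALSE] > 0)
  list(dprime = dprime_from_counts(hits, n_r, fas, n_l),
       n_left = n_l, n_right = n_r)
}

#' Full decode of one condition: reconstruction, accuracy and d'
#'
#' Convenience wrapper chaining [cross_validated_reconstruct()],
#' [accuracy_score()], [location_estimate()] and [decoder_dprime()].
#'
#' @param epochs An [epoch_set()] holding a single condition's trials.
#' @param basis A [channel_basis()].
#' @param k Folds.
#' @param seed Integer seed.
#' @return List with `time`, `accuracy` (projection score), `accuracy_cos`
#'   (direction-normalised score, used for chance-level inference), and
#'   `dprime`.
#' @export
decode_condition <- function(epochs, basis, k = 10, seed = 1L) {
  recon <- cross_validated_reconstruct(epochs, basis, k = k, seed = seed)
  acc <- accuracy_score(recon)
  acc_cos <- accuracy_score(recon, mode = "cosine")
  est <- location_estimate(recon)
  dp <- decoder_dprime(est$estimate, recon$labels$location_deg)
  list(time = recon$times, accuracy = acc$accuracy,
       accuracy_cos = acc_cos$accuracy, dprime = dp$dprime)
}
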