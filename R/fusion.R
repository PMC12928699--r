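#' MLE-predicted audiovisual sensitivity
#'
#' Optimal (maximum-likelihood-estimation) combination of two independent
#' cues predicts `d'AV = sqrt(d'A^2 + d'V^2)`. Vectorised; symmetric,
#' homogeneous of degree 1, and never below either argument for
#' non-negative inputs.
#'
#' @param d_a,d_v Unisensory sensitivities (scalars or aligned vectors).
#' @return Predicted audiovisual d'.
#' @examples
#' mle_dprime(3, 4)  # 5
#' @export
mle_dprime <- function(d_a, d_v) {
  stopifnot(all(is.finite(d_a)), all(is.finite(d_v)))
  sqrt(d_a^2 + d_v^2)
}

#' Build the aggregate (additive) audiovisual dataset
#'
#' Constructs the sensor-concatenation baseline: within each stimulus
#' location, auditory and visual trials are paired at random (seeded,
#' subsampling the larger set to the smaller count) and each pair's sensor
#' vectors are concatenated, giving trials with twice the sensors whose
#' label is the shared location. The aggregate represents linear
#' co-occurrence of both unisensory responses with no interaction.
#'
#' @param epochs_a,epochs_v [epoch_set()]s of the two unisensory
#'   conditions, sharing time axis and location set.
#' @param seed Integer seed for the within-location pairing.
#' @return An [epoch_set()] with `sensorsA + sensorsV` sensors and
#'   condition label "AGG".
#' @export
build_aggregate <- function(epochs_a, epochs_v, seed = 1L) {
  stopifnot(inherits(epochs_a, "epoch_set"), inherits(epochs_v, "epoch_set"))
  if (!isTRUE(all.equal(epochs_a$times, epochs_v$times))) {
    stop("epoch time axes do not match", call. = FALSE)
  }
  la <- epochs_a$labels
  lv <- epochs_v$labels
  locs_a <- sort(unique(la$location_deg[la$kept]))
  locs_v <- sort(unique(lv$location_deg[lv$kept]))
  if (!identical(locs_a, locs_v)) {
    stop("location sets differ between conditions: ",
         paste(setdiff(union(locs_a, locs_v), intersect(locs_a, locs_v)),
               collapse = ", "), call. = FALSE)
  }
  set.seed(derive_seed(seed, 808))
  pairs_a <- integer(0)
  pairs_v <- integer(0)
  for (loc in locs_a) {
    ia <- which(la$kept & la$location_deg == loc)
    iv <- which(lv$kept & lv$location_deg == loc)
    n <- min(length(ia), length(iv))
    pairs_a <- c(pairs_a, sample(ia)[seq_len(n)])
    pairs_v <- c(pairs_v, sample(iv)[seq_len(n)])
  }
  d <- dim(epochs_a$data)
  dat <- array(0, c(length(pairs_a), d[2] + dim(epochs_v$data)[2], d[3]))
  dat[, seq_len(d[2]), ] <- epochs_a$data[pairs_a, , , drop = FALSE]
  dat[, d[2] + seq_len(dim(epochs_v$data)[2]), ] <-
    epochs_v$data[pairs_v, , , drop = FALSE]
  labels <- data.frame(condition = "AGG",
                       location_deg = la$location_deg[pairs_a],
                       kept = TRUE)
  if (!is.null(la$participant)) labels$participant <- la$participant[pairs_a]
  epoch_set(dat, epochs_a$times, epochs_a$sample_rate, labels,
            c(paste0("A_", epochs_a$sensor_names),
              paste0("V_", epochs_v$sensor_names)))
}

#' Test audiovisual sensitivity against an additive prediction
#'
#' Forms the per-participant, per-timepoint difference `d'AV - prediction`
#' and tests it against zero with the one-sided (AV > prediction)
#' mass-based cluster permutation test.
#'
#' @param dprime_av Participants x time matrix of audiovisual sensitivity.
#' @param prediction Participants x time matrix of the additive baseline
#'   (MLE-predicted or aggregate-decoded), same participants and times.
#' @param times Time axis, seconds.
#' @param n_perm Number of sign-flip permutations (default 5000).
#' @param alpha Cluster-forming pointwise alpha (default 0.05).
#' @param seed Integer seed.
#' @return A `cluster_result` (see [cluster_permutation_test()]) for the
#'   positive (AV > prediction) direction, plus the difference matrix in
#'   `$difference`.
#' @export
superadditivity_contrast <- function(dprime_av, prediction, times,
                                     n_perm = 5000, alpha = 0.05,
                                     seed = 1L) {
  if (!all(dim(dprime_av) == dim(prediction))) {
    stop("participant x time grids of the two inputs differ", call. = FALSE)
  }
  diff <- dprime_av - prediction
  res <- cluster_permutation_test(diff, mu0 = 0, times = times,
                                  n_perm = n_perm, alpha = alpha,
                                  seed = seed, alternative = "greater")
  res$difference <- diff
  res
}
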