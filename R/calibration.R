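#' Simulate one complete decoding experiment
#'
#' Runs the generator and the inverted-encoding decode for a cohort of
#' synthetic participants and returns the group-level sensitivity and
#' accuracy timecourses for the requested conditions, including the
#' aggregate (sensor-concatenation) baseline and the MLE prediction. This
#' is the unit of the package's calibration studies: null calibration
#' (`gamma = 0`, false-positive rate of the super-additivity test) and
#' power analysis (`gamma > 0`, detection rate).
#'
#' @param n_participants Cohort size.
#' @param sim A [sim_config()]; per-participant seeds are derived from its
#'   seed and `seed`.
#' @param schedule List with n_blocks, n_trials, n_presentations for
#'   [make_eeg_schedule()].
#' @param conditions Which decoded conditions to return (subset of
#'   A, V, AV, AGG).
#' @param k Cross-validation folds.
#' @param seed Integer seed.
#' @return List with `times`, `dprime` (named list of participants x time
#'   matrices, plus `MLE` when A and V are present), and `accuracy`.
#' @export
simulate_decoding_experiment <- function(n_participants, sim,
                                         schedule = list(n_blocks = 2,
                                                         n_trials = 5,
                                                         n_presentations = 10),
                                         conditions = c("A", "V", "AV", "AGG"),
                                         k = 5, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  need_uni <- any(c("AGG", "MLE") %in% conditions) ||
    all(c("A", "V") %in% conditions)
  dpr <- acc <- stats::setNames(vector("list", length(conditions)), conditions)
  times <- NULL
  for (p in seq_len(n_participants)) {
    pseed <- derive_seed(seed, 21, p)
    sch <- make_eeg_schedule(participant_id = p,
                             n_blocks = schedule$n_blocks,
                             n_trials = schedule$n_trials,
                             n_presentations = schedule$n_presentations,
                             seed = pseed)
    psim <- sim
    psim$seed <- pseed
    ep <- simulate_epochs(sch, psim)$epochs
    eps <- list()
    for (cc in intersect(c("A", "V", "AV"), c(conditions,
                                              if (need_uni) c("A", "V")))) {
      eps[[cc]] <- subset_trials(ep, ep$labels$condition == cc)
    }
    if ("AGG" %in% conditions) {
      eps$AGG <- build_aggregate(eps$A, eps$V, seed = pseed)
    }
    for (cc in conditions) {
      d <- decode_condition(eps[[cc]], sim$basis, k = k, seed = pseed)
      times <- d$time
      dpr[[cc]] <- rbind(dpr[[cc]], d$dprime)
      acc[[cc]] <- rbind(acc[[cc]], d$accuracy)
    }
  }
  if (all(c("A", "V") %in% conditions)) {
    dpr$MLE <- mle_dprime(dpr$A, dpr$V)
  }
  list(times = times, dprime = dpr, accuracy = acc)
}
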