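#' Pipeline configuration for the full synthetic experiment
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' Unknown keys in any block are rejected so typos fail loudly. The
#' defaults run a small but complete synthetic experiment; the full-scale
#' session design (12 blocks x 10 trials x 20 presentations, 64 sensors,
#' 512 Hz) is obtained by overriding `schedule` and `sim`.
#'
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param n_participants Number of synthetic participants.
#' @param schedule List: n_blocks, n_trials, n_presentations.
#' @param sim List of overrides for [sim_config()].
#' @param observer List of overrides for [observer_params()].
#' @param preprocess List: eye_threshold_deg, saccade_prob, saccade_amp.
#' @param decode List: k (folds).
#' @param stats List: n_perm, alpha.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_participants = 8,
                            schedule = list(), sim = list(),
                            observer = list(), preprocess = list(),
                            decode = list(), stats = list()) {
  check_keys <- function(given, allowed, block) {
    extra <- setdiff(names(given), allowed)
    if (length(extra)) {
      stop("unknown ", block, " key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
  }
  sch_def <- list(n_blocks = 2L, n_trials = 5L, n_presentations = 10L)
  pre_def <- list(eye_threshold_deg = 3.75, saccade_prob = 0.05,
                  saccade_amp = 5)
  dec_def <- list(k = 10L)
  st_def <- list(n_perm = 1000L, alpha = 0.05)
  check_keys(schedule, names(sch_def), "schedule")
  check_keys(sim, names(formals(sim_config)), "sim")
  check_keys(observer, names(formals(observer_params)), "observer")
  check_keys(preprocess, names(pre_def), "preprocess")
  check_keys(decode, names(dec_def), "decode")
  check_keys(stats, names(st_def), "stats")
  sch <- utils::modifyList(sch_def, schedule)
  pre <- utils::modifyList(pre_def, preprocess)
  dec <- utils::modifyList(dec_def, decode)
  st <- utils::modifyList(st_def, stats)
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 schedule = sch, sim = sim, observer = observer,
                 preprocess = pre, decode = dec, stats = st),
            class = "pipeline_config")
}

# decode one participant's conditions (A, V, AV, AGG) into accuracy and
# d-prime timecourses
decode_participant <- function(epochs, basis, k, seed) {
  split_cond <- function(cond) subset_trials(epochs, epochs$labels$condition == cond)
  eps <- list(A = split_cond("A"), V = split_cond("V"), AV = split_cond("AV"))
  eps$AGG <- build_aggregate(eps$A, eps$V, seed = seed)
  lapply(eps, decode_condition, basis = basis, k = k, seed = seed)
}

#' Run the full synthetic audiovisual decoding experiment
#'
#' Chains every stage of the analysis at the configured scale: session
#' scheduling, epoch simulation, gaze-based trial exclusion, average
#' re-referencing, ERPs with the additive (A+V vs AV) contrast,
#' cross-validated inverted-encoding decoding of the A, V, AV and
#' aggregate conditions, accuracy and d' timecourses, the MLE prediction,
#' the two super-additivity cluster tests (AV vs MLE, AV vs aggregate),
#' decoding-vs-chance cluster tests, simulated behavioural responses with
#' d' and Wilcoxon comparisons, and the neurobehavioural rank correlation.
#' All tables are written as tidy CSV, cluster summaries as JSON, and a
#' manifest records the seed and configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); NULL skips writing.
#' @return Invisibly, a list with all intermediate and final results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  sim_args <- utils::modifyList(config$sim, list(seed = seed))
  sim <- do.call(sim_config, sim_args)
  obs <- do.call(observer_params, config$observer)
  basis <- sim$basis
  np <- config$n_participants

  acc <- acc_cos <- dpr <- list()
  erps <- list()
  behav <- list()
  excl <- list()
  for (p in seq_len(np)) {
    sch <- make_eeg_schedule(participant_id = p,
                             n_blocks = config$schedule$n_blocks,
                             n_trials = config$schedule$n_trials,
                             n_presentations = config$schedule$n_presentations,
                             seed = seed)
    simmed <- simulate_epochs(sch, sim)
    ep <- simmed$epochs
    gaze <- simulate_gaze(nrow(sch), length(ep$times),
                          saccade_prob = config$preprocess$saccade_prob,
                          saccade_amp = config$preprocess$saccade_amp,
                          seed = derive_seed(seed, 11, p))
    ex <- exclude_eye_trials(ep, gaze, config$preprocess$eye_threshold_deg)
    ep <- rereference_average(ex$epochs)
    excl[[p]] <- cbind(participant = p, ex$report)

    erp_cond <- lapply(c(A = "A", V = "V", AV = "AV"),
                       function(cc) compute_erp(ep, cc))
    erps[[p]] <- list(A = erp_cond$A, V = erp_cond$V, AV = erp_cond$AV,
                      additive = additive_contrast(erp_cond$A, erp_cond$V,
                                                   erp_cond$AV))

    dec <- decode_participant(ep, basis, config$decode$k,
                              derive_seed(seed, 12, p))
    acc[[p]] <- lapply(dec, `[[`, "accuracy")
    acc_cos[[p]] <- lapply(dec, `[[`, "accuracy_cos")
    dpr[[p]] <- lapply(dec, `[[`, "dprime")

    resp <- simulate_behavioural_responses(sch, obs,
                                           seed = derive_seed(seed, 13, p))
    behav[[p]] <- vapply(c("A", "V", "AV"), function(cc) {
      behavioural_dprime(resp[resp$condition == cc, ])$dprime
    }, numeric(1))
  }
  times <- erps[[1]]$A$time
  stack <- function(lst, cond) do.call(rbind, lapply(lst, `[[`, cond))
  conds <- c("A", "V", "AV", "AGG")
  acc_mat <- lapply(stats::setNames(conds, conds), function(cc) stack(acc, cc))
  acc_cos_mat <- lapply(stats::setNames(conds, conds),
                        function(cc) stack(acc_cos, cc))
  dpr_mat <- lapply(stats::setNames(conds, conds), function(cc) stack(dpr, cc))
  dpr_mat$MLE <- mle_dprime(dpr_mat$A, dpr_mat$V)

  st <- config$stats
  # chance-level inference uses the direction-normalised score, whose null
  # is symmetric under cross-validation (see the methods vignette)
  chance_tests <- lapply(acc_cos_mat[c("A", "V", "AV")], function(m) {
    cluster_permutation_test(m, mu0 = 0, times = times, n_perm = st$n_perm,
                             alpha = st$alpha, alternative = "greater",
                             seed = derive_seed(seed, 14))
  })
  sup_mle <- superadditivity_contrast(dpr_mat$AV, dpr_mat$MLE, times,
                                      n_perm = st$n_perm, alpha = st$alpha,
                                      seed = derive_seed(seed, 15))
  sup_agg <- superadditivity_contrast(dpr_mat$AV, dpr_mat$AGG, times,
                                      n_perm = st$n_perm, alpha = st$alpha,
                                      seed = derive_seed(seed, 16))
  erp_add_mat <- do.call(rbind, lapply(erps, function(e) e$additive$amplitude))
  erp_test <- cluster_permutation_test(erp_add_mat, mu0 = 0, times = times,
                                       n_perm = st$n_perm, alpha = st$alpha,
                                       seed = derive_seed(seed, 17))

  behav_mat <- do.call(rbind, behav)
  wilcox <- list(
    AV_vs_A = wilcoxon_signed_rank(behav_mat[, "AV"], behav_mat[, "A"]),
    AV_vs_V = wilcoxon_signed_rank(behav_mat[, "AV"], behav_mat[, "V"]),
    AV_vs_MLE = wilcoxon_signed_rank(behav_mat[, "AV"],
                                     mle_dprime(behav_mat[, "A"],
                                                behav_mat[, "V"])))
  win <- times >= 0.15 & times <= 0.25
  neuro <- lapply(stats::setNames(c("A", "V", "AV"), c("A", "V", "AV")),
                  function(cc) {
                    spearman_rho(rowMeans(dpr_mat[[cc]][, win, drop = FALSE]),
                                 behav_mat[, cc])
                  })

  res <- list(times = times, accuracy = acc_mat,
              accuracy_cos = acc_cos_mat, dprime = dpr_mat,
              erps = erps, erp_additive = erp_add_mat,
              chance_tests = chance_tests, superadditivity_mle = sup_mle,
              superadditivity_aggregate = sup_agg, erp_additive_test = erp_test,
              behaviour = behav_mat, wilcoxon = wilcox,
              neurobehavioural = neuro, exclusions = do.call(rbind, excl),
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

# tidy long-format export of every statistical table + cluster JSON
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tidy_tc <- function(mats, metric) {
    do.call(rbind, lapply(names(mats), function(cc) {
      m <- mats[[cc]]
      data.frame(participant = rep(seq_len(nrow(m)), times = ncol(m)),
                 condition = cc, metric = metric,
                 time = rep(res$times, each = nrow(m)),
                 value = as.vector(m))
    }))
  }
  readr::write_csv(rbind(tidy_tc(res$accuracy, "accuracy"),
                         tidy_tc(res$accuracy_cos, "accuracy_cos"),
                         tidy_tc(res$dprime, "dprime")),
                   file.path(out_dir, "timecourses.csv"), progress = FALSE)
  bm <- as.data.frame(res$behaviour)
  bm$participant <- seq_len(nrow(bm))
  readr::write_csv(bm, file.path(out_dir, "behaviour.csv"), progress = FALSE)
  readr::write_csv(res$exclusions, file.path(out_dir, "exclusions.csv"),
                   progress = FALSE)
  cluster_json <- function(cr) {
    list(clusters = cr$clusters, threshold_pos = cr$threshold_pos,
         threshold_neg = cr$threshold_neg, n_permutations = cr$n_permutations,
         alternative = cr$alternative)
  }
  jsonlite::write_json(
    list(decoding_vs_chance = lapply(res$chance_tests, cluster_json),
         av_vs_mle = cluster_json(res$superadditivity_mle),
         av_vs_aggregate = cluster_json(res$superadditivity_aggregate),
         erp_additive = cluster_json(res$erp_additive_test),
         wilcoxon = res$wilcoxon, neurobehavioural = res$neurobehavioural),
    file.path(out_dir, "statistics.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "avencode",
                   version = as.character(utils::packageVersion("avencode")),
                   seed = res$config$seed,
                   n_participants = res$config$n_participants,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
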