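test_that("EEG-session schedule has the full factorial design", {
  sch <- make_eeg_schedule(participant_id = 3L, seed = 7)
  counts <- table(sch$condition)
  expect_equal(unname(counts[c("A", "V", "AV")]), rep(2400L, 3),
               ignore_attr = TRUE)
  expect_true(all(sch$location_deg %in% c(-15, -7.5, 0, 7.5, 15)))
  expect_equal(max(sch$block), 12L)
  expect_equal(max(sch$trial), 10L)
  expect_equal(max(sch$presentation), 20L)
  # determinism
  expect_identical(sch, make_eeg_schedule(participant_id = 3L, seed = 7))
  expect_false(identical(sch$location_deg,
                         make_eeg_schedule(participant_id = 3L,
                                           seed = 8)$location_deg))
})

test_that("behavioural schedule balances targets over eight locations", {
  sch <- make_behavioural_schedule(seed = 3)
  for (cc in c("A", "V", "AV")) {
    sub <- sch[sch$condition == cc, ]
    expect_equal(nrow(sub), 384L)
    tab <- table(sub$location_deg)
    expect_length(tab, 8L)
    expect_true(all(tab == 48L))
  }
  locs <- sort(unique(sch$location_deg))
  expect_equal(locs, seq(-15, 15, length.out = 8))
  expect_equal(locs, -rev(locs))  # symmetric about zero
  # interval order is ~50/50 across many trials
  big <- do.call(rbind, lapply(1:10, function(s) {
    make_behavioural_schedule(seed = s)
  }))
  p1 <- mean(big$target_interval == 1L)
  expect_lt(abs(p1 - 0.5), 0.02)
})

test_that("MLE observer noise combines unisensory reliabilities", {
  p <- observer_params(sigma_a = 3, sigma_v = 3)
  expect_equal(observer_sigma(p, "AV"), 3 / sqrt(2))
  p2 <- observer_params(sigma_a = 4, sigma_v = 2)
  expect_equal(observer_sigma(p2, "AV"), sqrt(16 * 4 / 20))
  expect_error(observer_params(sigma_a = 0), "sigmas")
  expect_error(observer_params(lapse = 0.6), "lapse")
})

test_that("2IFC observer accuracy approaches 1 as noise vanishes", {
  sch <- make_behavioural_schedule(conditions = "A", seed = 5)
  resp <- simulate_behavioural_responses(
    sch, observer_params(sigma_a = 1e-6, sigma_v = 1e-6), seed = 5)
  off_centre <- resp$location_deg != 0
  expect_true(all(resp$correct[off_centre]))
  # response_rightward must match the sign of the target for sigma -> 0
  expect_equal(resp$response_rightward[off_centre],
               resp$location_deg[off_centre] > 0)
})

test_that("audiovisual psychometric slope shows the root-2 MLE gain", {
  p <- observer_params(sigma_a = 4, sigma_v = 4)
  big <- do.call(rbind, lapply(1:26, function(s) {
    sch <- make_behavioural_schedule(participant_id = s, seed = s)
    simulate_behavioural_responses(sch, p, seed = 100 + s)
  }))
  fitA <- fit_psychometric(big$location_deg[big$condition == "A"],
                           big$response_rightward[big$condition == "A"])
  fitAV <- fit_psychometric(big$location_deg[big$condition == "AV"],
                            big$response_rightward[big$condition == "AV"])
  expect_equal(fitAV$slope_at_pse / fitA$slope_at_pse, sqrt(2),
               tolerance = 0.05)
})

test_that("epoch generator is deterministic and respects its dimensions", {
  sim <- tiny_sim()
  sch <- tiny_schedule()
  out1 <- tiny_epochs(sim, sch)
  out2 <- tiny_epochs(sim, sch)
  expect_identical(out1$epochs$data, out2$epochs$data)
  d <- dim(out1$epochs$data)
  expect_equal(d[1], nrow(sch))
  expect_equal(d[2], sim$n_sensors)
  expect_equal(d[3], floor(0.6 * sim$sample_rate_hz))
  expect_equal(out1$epochs$labels$location_deg, sch$location_deg)
})

test_that("gamma = 0 audiovisual signal is exactly the sum of unisensory signals", {
  # noiseless generator: AV epochs must equal A-loading + V-loading signals
  sim <- tiny_sim(noise_sd = 0)
  sch <- tiny_schedule()
  out <- tiny_epochs(sim, sch)
  gt <- out$ground_truth
  ep <- out$epochs
  av <- which(ep$labels$condition == "AV")
  i <- av[5]
  loc <- ep$labels$location_deg[i]
  cvec <- basis_response(sim$basis, loc)
  expected <- outer((gt$M_A + gt$M_V) %*% cvec, gt$tuned_kernel)[, 1, ] +
    outer(gt$untuned_pattern * sim$evoked_amp["AV"], gt$evoked_kernel)
  expect_equal(ep$data[i, , ], expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(gt$gains["AV"]), sim$gain_a + sim$gain_v)
})

test_that("sensor-averaged AV ERP is additive when gamma is zero", {
  sim <- tiny_sim(noise_sd = 2, seed = 21)
  sch <- make_eeg_schedule(1L, n_blocks = 4L, n_trials = 5L,
                           n_presentations = 10L, seed = 21)
  ep <- simulate_epochs(sch, sim)$epochs
  erpA <- compute_erp(ep, "A", baseline = FALSE)
  erpV <- compute_erp(ep, "V", baseline = FALSE)
  erpAV <- compute_erp(ep, "AV", baseline = FALSE)
  resid <- (erpA$amplitude + erpV$amplitude) - erpAV$amplitude
  # residual additivity error is pure noise: compare to its own SE
  noise_se <- sim$noise_sd / sqrt(200 * sim$n_sensors)
  expect_lt(max(abs(resid)), 6 * noise_se * sqrt(3))
})

test_that("gaze traces hit the requested saccade rate and amplitude", {
  g0 <- simulate_gaze(500, 20, saccade_prob = 0, seed = 2)
  expect_true(all(sqrt(g0$x^2 + g0$y^2) < 1))
  g <- simulate_gaze(2400, 20, saccade_prob = 0.1, saccade_amp = 5, seed = 3)
  frac <- mean(apply(sqrt(g$x^2 + g$y^2), 1, max) > 3.75)
  expect_gt(frac, 0.1 - 3 * sqrt(0.1 * 0.9 / 2400))
  expect_lt(frac, 0.1 + 3 * sqrt(0.1 * 0.9 / 2400))
  # 2-degree saccades: invisible at 3.75, all caught at 1.875
  g2 <- simulate_gaze(400, 20, saccade_prob = 0.5, saccade_amp = 2,
                      jitter_sd = 0.01, seed = 4)
  dev <- apply(sqrt(g2$x^2 + g2$y^2), 1, max)
  expect_equal(sum(dev > 3.75), 0L)
  expect_equal(dev > 1.875, g2$saccade)
})
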