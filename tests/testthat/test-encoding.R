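test_that("channel tuning curves are rectified power-of-cosine bumps", {
  b <- channel_basis()
  # each channel peaks at 1 on its own centre
  for (k in seq_along(b$centres)) {
    expect_equal(basis_response(b, b$centres[k])[k], 1)
  }
  # midpoint between adjacent centres activates both equally
  r <- basis_response(b, mean(b$centres[2:3]))
  expect_equal(r[2], r[3])
  # hand evaluation at -15 deg: cos(45 deg)^5 for the second channel
  r15 <- basis_response(b, -15)
  expect_equal(round(r15, 3), c(1, 0.177, 0, 0, 0))
  expect_true(all(basis_response(b, 3.21) >= 0))
  expect_error(channel_basis(centres = c(0, 0, 1, 2, 3)), "increasing")
})

test_that("design matrix stacks basis responses and flags missing locations", {
  b <- channel_basis()
  locs <- c(-15, -7.5, 0, 7.5, 15)
  C <- design_matrix(b, locs)
  expect_equal(dim(C), c(5L, 5L))
  expect_equal(qr(C)$rank, 5L)
  for (j in seq_along(locs)) {
    expect_equal(C[, j], basis_response(b, locs[j]))
  }
  # duplicated locations duplicate columns
  C2 <- design_matrix(b, c(0, 0))
  expect_equal(C2[, 1], C2[, 2])
  # a location never presented leaves a channel silent -> singular design
  C3 <- design_matrix(b, rep(c(-15, -7.5, 0, 7.5), 3))
  B3 <- matrix(rnorm(3 * 12), 3, 12)
  expect_error(fit_forward(B3, C3), "singular design")
})

test_that("forward fit matches exact recovery, scaling, and an optimiser oracle", {
  set.seed(42)
  b <- channel_basis()
  locs <- rep(c(-15, -7.5, 0, 7.5, 15), 6)
  C <- design_matrix(b, locs)
  W0 <- matrix(rnorm(3 * 5), 3, 5)
  B <- W0 %*% C
  W <- fit_forward(B, C)
  expect_equal(W, W0, tolerance = 1e-10)
  # linearity in B
  expect_equal(fit_forward(2 * B, C), 2 * W0, tolerance = 1e-10)
  # residual orthogonality on noisy data
  Bn <- B + matrix(rnorm(length(B)), nrow(B))
  Wn <- fit_forward(Bn, C)
  E <- Bn - Wn %*% C
  expect_lt(max(abs(E %*% t(C))), 1e-8)
  # independent oracle: direct numerical minimisation of ||B - WC||^2
  obj <- function(w) sum((Bn - matrix(w, 3, 5) %*% C)^2)
  opt <- optim(rep(0, 15), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(matrix(opt$par, 3, 5), Wn, tolerance = 1e-5)
})

test_that("shrinkage covariance is well-conditioned and correct in its limits", {
  set.seed(7)
  # independent unit-variance sensors, generous n: near-identity
  E <- matrix(rnorm(8 * 4000), 8, 4000)
  res <- estimate_noise_cov(E)
  off <- res$sigma[row(res$sigma) != col(res$sigma)]
  expect_lt(max(abs(off)), 0.1)
  expect_equal(diag(res$sigma), rep(1, 8), tolerance = 0.1)
  # n = 2 with 64 sensors must still be positive definite
  E2 <- matrix(rnorm(64 * 2), 64, 2)
  res2 <- estimate_noise_cov(E2)
  ev <- eigen(res2$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # forced full shrinkage is exactly diagonal
  res3 <- estimate_noise_cov(E, lambda = 1)
  expect_true(all(res3$sigma[row(res3$sigma) != col(res3$sigma)] == 0))
  expect_warning(estimate_noise_cov(rbind(matrix(rnorm(10), 2, 5),
                                          rep(0, 5))),
                 "zero-variance")
})

test_that("the inverse model reduces to known decoders and beats the pseudoinverse", {
  set.seed(8)
  W <- matrix(rnorm(6 * 5), 6, 5)
  # Sigma = I: equals the pseudoinverse
  D <- invert_model(W, diag(6))
  pinv <- solve(crossprod(W), t(W))
  expect_equal(D, pinv, tolerance = 1e-10)
  expect_equal(D %*% W, diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  # exact inversion of a noiseless sensor vector
  cvec <- c(0.2, 1, 0.3, 0, 0)
  expect_equal(as.numeric(D %*% (W %*% cvec)), cvec, tolerance = 1e-8)
  # GLS oracle: for anisotropic noise, matches generalised least squares and
  # has lower reconstruction variance than the pseudoinverse
  sig <- diag(c(5, 2, 0.1, 1, 3, 0.5))
  Dg <- invert_model(W, sig)
  gls <- solve(t(W) %*% solve(sig) %*% W) %*% t(W) %*% solve(sig)
  expect_equal(Dg, gls, tolerance = 1e-6)
  L <- chol(sig)
  draws <- t(L) %*% matrix(rnorm(6 * 5000), 6, 5000)
  var_gls <- mean(apply(Dg %*% draws, 1, var))
  var_ols <- mean(apply(D %*% draws, 1, var))
  expect_lt(var_gls, var_ols)
  expect_error(invert_model(W[, c(1, 1, 2, 3, 4)], diag(6)), "rank")
})

test_that("isotropic noise scale does not change the decoder", {
  set.seed(9)
  W <- matrix(rnorm(6 * 5), 6, 5)
  D1 <- invert_model(W, diag(6))
  D2 <- invert_model(W, 25 * diag(6))
  expect_equal(D1, D2, tolerance = 1e-10)
})

test_that("cross-validated reconstruction recovers noiseless channel profiles", {
  sim <- tiny_sim(noise_sd = 0, evoked_amp = c(A = 0, V = 0, AV = 0))
  out <- tiny_epochs(sim)
  ep <- out$epochs
  epA <- subset_trials(ep, ep$labels$condition == "A")
  rec <- cross_validated_reconstruct(epA, sim$basis, k = 5, seed = 3)
  pk <- which.min(abs(rec$times - sim$tuned_latency_s))
  ideal <- design_matrix(sim$basis, rec$labels$location_deg)
  expect_equal(t(rec$activities[, , pk]), ideal, tolerance = 1e-6)
})

test_that("cross-validation never decodes a trial with a model trained on it", {
  sim <- tiny_sim(seed = 61)
  out <- tiny_epochs(sim, tiny_schedule(seed = 61))
  ep <- out$epochs
  epA <- subset_trials(ep, ep$labels$condition == "A")
  # leak check by construction: fold of each trial excludes it from training
  folds <- avencode:::stratified_folds(epA$labels$location_deg, 5, 3)
  expect_equal(length(folds), sum(epA$labels$kept))
  expect_true(all(table(folds) > 0))
  for (loc in unique(epA$labels$location_deg)) {
    expect_true(all(table(folds[epA$labels$location_deg == loc]) >= 1))
  }
  expect_error(cross_validated_reconstruct(epA, sim$basis, k = 25, seed = 1),
               "fewer folds")
})

test_that("reconstruction is seed-deterministic and fold-seed stable", {
  sim <- tiny_sim(seed = 62)
  ep <- tiny_epochs(sim, tiny_schedule(seed = 62))$epochs
  epA <- subset_trials(ep, ep$labels$condition == "A")
  rec1 <- cross_validated_reconstruct(epA, sim$basis, k = 5, seed = 4)
  rec2 <- cross_validated_reconstruct(epA, sim$basis, k = 5, seed = 4)
  expect_identical(rec1$activities, rec2$activities)
  # a different fold split changes individual reconstructions but not the
  # group-level accuracy beyond its own sampling noise
  rec3 <- cross_validated_reconstruct(epA, sim$basis, k = 5, seed = 5)
  expect_false(identical(rec1$folds, rec3$folds))
  a1 <- accuracy_score(rec1)
  a3 <- accuracy_score(rec3)
  pk <- which.min(abs(rec1$times - sim$tuned_latency_s))
  se <- sd(a1$trial_scores[, pk]) / sqrt(nrow(a1$trial_scores))
  expect_lt(abs(a1$accuracy[pk] - a3$accuracy[pk]), 4 * se)
})

test_that("per-sensor information maps recover the generator's loading structure", {
  # sensors with zero tuned loading carry ~no information; ranking follows
  # the loading magnitudes at high SNR
  sim <- tiny_sim(n_sensors = 8, noise_sd = 0.5, seed = 77,
                  evoked_amp = c(A = 0, V = 0, AV = 0))
  sch <- make_eeg_schedule(1L, n_blocks = 4L, n_trials = 5L,
                           n_presentations = 10L, seed = 77)
  out <- simulate_epochs(sch, sim)
  ep <- out$epochs
  epA <- subset_trials(ep, ep$labels$condition == "A")
  # silence sensors 7 and 8 (keep their noise)
  gt <- out$ground_truth
  sil <- c(7, 8)
  for (i in which(epA$labels$kept)) {
    tuned <- outer(gt$M_A[sil, ] %*%
                     basis_response(sim$basis, epA$labels$location_deg[i]),
                   gt$tuned_kernel)[, 1, ]
    epA$data[i, sil, ] <- epA$data[i, sil, ] - tuned
  }
  scores <- per_sensor_information(epA, sim$basis, window = c(0.1, 0.3),
                                   k = 5, seed = 5)
  loading_size <- sqrt(rowSums(gt$M_A^2))
  expect_lt(mean(scores[sil]), mean(scores[-sil]) / 4)
  expect_gt(cor(loading_size[-sil], scores[-sil], method = "spearman"), 0.7)
  expect_error(per_sensor_information(epA, sim$basis, window = c(2, 3)),
               "outside")
})
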