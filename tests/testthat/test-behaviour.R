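test_that("psychometric fit recovers generating parameters", {
  set.seed(18)
  n <- 50000
  locs <- runif(n, -15, 15)
  resp <- runif(n) < pnorm((locs - 0) / 5)
  fit <- fit_psychometric(locs, resp)
  expect_equal(fit$sigma, 5, tolerance = 0.05)
  expect_equal(fit$slope_at_pse, 1 / (5 * sqrt(2 * pi)), tolerance = 0.03)
  expect_equal(fit$pse, 0, tolerance = 0.2)
  # internal consistency of the slope definition
  expect_equal(fit$slope_at_pse, 1 / (fit$sigma * sqrt(2 * pi)))
  # location shift equivariance
  fit2 <- fit_psychometric(locs + 2, resp)
  expect_equal(fit2$pse, fit$pse + 2, tolerance = 1e-3)
  expect_equal(fit2$slope_at_pse, fit$slope_at_pse, tolerance = 1e-4)
  # halving sigma doubles the slope
  resp_sharp <- runif(n) < pnorm(locs / 2.5)
  fit3 <- fit_psychometric(locs, resp_sharp)
  expect_equal(fit3$slope_at_pse / fit$slope_at_pse, 2, tolerance = 0.05)
  expect_error(fit_psychometric(locs[1:10], rep(TRUE, 10)),
               "non-identifiable")
  expect_error(fit_psychometric(rep(1, 20), rep(c(TRUE, FALSE), 10)),
               "distinct")
})

test_that("probit GLM cross-checks the ML fit at zero lapse", {
  set.seed(19)
  locs <- rep(seq(-15, 15, length.out = 8), each = 60)
  resp <- runif(length(locs)) < pnorm((locs - 1) / 4)
  fit <- fit_psychometric(locs, resp)
  g <- glm(resp ~ locs, family = binomial("probit"))
  expect_equal(fit$sigma, unname(1 / coef(g)[2]), tolerance = 1e-3)
  expect_equal(fit$pse, unname(-coef(g)[1] / coef(g)[2]), tolerance = 1e-3)
})

test_that("predicted audiovisual slope is the quadrature sum of unisensory slopes", {
  expect_equal(mle_predicted_slope(0.03, 0.02), sqrt(0.0013))
  expect_equal(mle_predicted_slope(0.03, 0.02), 0.0361, tolerance = 5e-3)
  expect_equal(mle_predicted_slope(0.05, 0), 0.05)
  expect_error(mle_predicted_slope(-0.1, 0.2), ">= 0")
})

test_that("observer recovery: fitted sigmas match the generating observer", {
  p <- observer_params(sigma_a = 4, sigma_v = 6)
  sig_hat <- sapply(1:40, function(s) {
    sch <- make_behavioural_schedule(participant_id = s,
                                     conditions = c("A", "V"), seed = s)
    resp <- simulate_behavioural_responses(sch, p, seed = 400 + s)
    c(A = fit_psychometric(resp$location_deg[resp$condition == "A"],
                           resp$response_rightward[resp$condition == "A"])$sigma,
      V = fit_psychometric(resp$location_deg[resp$condition == "V"],
                           resp$response_rightward[resp$condition == "V"])$sigma)
  })
  # responses compare target against an equally noisy reference, so the
  # effective discrimination sigma is sqrt(2) x the single-stimulus sigma
  expect_equal(mean(sig_hat["A", ]), 4 * sqrt(2), tolerance = 0.1)
  expect_equal(mean(sig_hat["V", ]), 6 * sqrt(2), tolerance = 0.1)
})

test_that("sequence-task d-prime handles ties and clipping", {
  # all correct with 50 trials per side: both proportions clipped
  tab <- data.frame(majority_side = rep(c(-1, 1), each = 50),
                    response_right = rep(c(FALSE, TRUE), each = 50))
  res <- behavioural_dprime(tab)
  expect_equal(res$dprime, 2 * qnorm(0.99), tolerance = 1e-6)
  expect_equal(round(res$dprime, 3), 4.653)
  # ties are excluded from the counts
  tab_tie <- rbind(tab, data.frame(majority_side = rep(0, 10),
                                   response_right = rep(TRUE, 10)))
  res2 <- behavioural_dprime(tab_tie)
  expect_equal(res2$n_excluded_ties, 10)
  expect_equal(res2$n_right + res2$n_left, 100)
  expect_error(behavioural_dprime(data.frame(majority_side = 0,
                                             response_right = TRUE)),
               "no valid")
})

test_that("random responding yields near-zero sequence d-prime", {
  set.seed(20)
  ds <- replicate(500, {
    tab <- data.frame(majority_side = rep(c(-1, 1), each = 30),
                      response_right = sample(c(TRUE, FALSE), 60, TRUE))
    behavioural_dprime(tab)$dprime
  })
  expect_lt(abs(mean(ds)), 2 * sd(ds) / sqrt(length(ds)) + 0.01)
})

test_that("signed-rank Z matches its construction and wilcox.test", {
  x <- c(2.1, 3.3, 1.2, 4.8, 2.2, 5.1, 3.9, 2.8, 4.4, 1.9,
         3.1, 2.6, 4.1, 3.7, 2.9, 5.3, 1.4, 3.5, 4.6, 2.4)
  y_shift <- x + 1
  res <- wilcoxon_signed_rank(y_shift, x)
  expect_lt(res$p, 0.001)
  expect_equal(res$w_plus, 20 * 21 / 2)  # all differences positive
  # agreement with the reference implementation (no continuity correction
  # difference at these data: compare p values)
  set.seed(21)
  a <- rnorm(15)
  b <- a + rnorm(15, 0.4)
  mine <- wilcoxon_signed_rank(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                      correct = TRUE))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
  expect_error(wilcoxon_signed_rank(a, a), "degenerate")
})

test_that("signed-rank null p-values are approximately uniform", {
  set.seed(22)
  ps <- replicate(1000, {
    a <- rnorm(20)
    b <- rnorm(20)
    wilcoxon_signed_rank(a, b)$p
  })
  d_stat <- suppressWarnings(ks.test(ps, "punif")$statistic)
  expect_lt(unname(d_stat), 0.08)
})

test_that("small-sample signed-rank matches exact enumeration", {
  # brute force over all 2^6 sign patterns of |d| gives the exact p
  x <- c(0.8, -1.1, 2.3, 1.7, -0.4, 2.9)
  y <- rep(0, 6)
  res <- wilcoxon_signed_rank(x, y)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  w_null <- as.matrix(signs) %*% r
  p_exact <- mean(abs(w_null - 10.5) >= abs(w_obs - 10.5))
  expect_lt(abs(res$p - p_exact), 0.02)
})

test_that("Spearman correlation is a rank statistic with t-based p", {
  x <- c(3, 1, 4, 1.5, 5, 9, 2.6, 5.3, 5.8, 9.7)
  expect_equal(spearman_rho(x, sort(x))$rho < 1, TRUE)
  expect_equal(spearman_rho(sort(x), seq_along(x))$rho, 1)
  expect_equal(spearman_rho(sort(x), rev(seq_along(x)))$rho, -1)
  set.seed(23)
  a <- rnorm(30)
  b <- a + rnorm(30, 0, 2)
  r1 <- spearman_rho(a, b)
  # invariant to strictly monotone transforms
  expect_equal(spearman_rho(exp(a), b)$rho, r1$rho)
  expect_equal(spearman_rho(a^3, b)$rho, r1$rho)
  # reference cross-check
  ref <- cor.test(a, b, method = "spearman", exact = FALSE)
  expect_equal(r1$rho, unname(ref$estimate))
  expect_equal(r1$p, ref$p.value, tolerance = 1e-6)
  expect_error(spearman_rho(rep(1, 10), rnorm(10)), "constant")
})
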