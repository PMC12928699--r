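#' Maximum-likelihood cumulative-Gaussian psychometric fit
#'
#' Fits `P(rightward) = lapse/2 + (1 - lapse) * pnorm((x - pse)/sigma)` to
#' binary responses by maximum likelihood (lapse fixed, default 0).
#' Sensitivity is the slope at the point of subjective equality,
#' `(1 - lapse) / (sigma * sqrt(2*pi))`, in proportion per degree.
#'
#' @param location_deg Stimulus locations, degrees.
#' @param response_rightward Logical (or 0/1) responses.
#' @param lapse Fixed lapse rate in [0, 0.5) (default 0).
#' @return A `psychometric_fit` list: `pse`, `sigma`, `slope_at_pse`,
#'   `loglik`, `n_trials`, `lapse`.
#' @export
fit_psychometric <- function(location_deg, response_rightward, lapse = 0) {
  y <- as.numeric(response_rightward)
  if (length(unique(location_deg)) < 2) {
    stop("need >= 2 distinct locations", call. = FALSE)
  }
  if (all(y == y[1])) {
    stop("non-identifiable: all responses identical", call. = FALSE)
  }
  # probit GLM supplies the exact ML fit at lapse = 0 and good starts otherwise
  g <- stats::glm(y ~ location_deg, family = stats::binomial("probit"))
  beta <- stats::coef(g)
  start <- c(pse = unname(-beta[1] / beta[2]),
             log_sigma = log(max(1 / abs(beta[2]), 1e-3)))
  nll <- function(par) {
    p <- lapse / 2 + (1 - lapse) *
      stats::pnorm((location_deg - par[1]) / exp(par[2]))
    p <- pmin(1 - 1e-12, pmax(1e-12, p))
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  sigma <- exp(opt$par[2])
  structure(list(pse = unname(opt$par[1]), sigma = unname(sigma),
                 slope_at_pse = unname((1 - lapse) / (sigma * sqrt(2 * pi))),
                 loglik = -opt$value, n_trials = length(y), lapse = lapse),
            class = "psychometric_fit")
}

#' MLE-predicted audiovisual psychometric slope
#'
#' For cumulative-Gaussian psychometric functions the slope at the PSE is
#' proportional to `1/sigma`, and optimal integration gives
#' `1/sigmaAV^2 = 1/sigmaA^2 + 1/sigmaV^2`; the predicted audiovisual
#' slope is therefore the quadrature sum `sqrt(slopeA^2 + slopeV^2)`.
#'
#' @param slope_a,slope_v Unisensory slopes (proportion per degree), >= 0.
#' @return Predicted audiovisual slope.
#' @export
mle_predicted_slope <- function(slope_a, slope_v) {
  stopifnot(all(slope_a >= 0), all(slope_v >= 0))
  sqrt(slope_a^2 + slope_v^2)
}

#' Behavioural d' for the sequence (EEG-session) task
#'
#' Signal-detection sensitivity of the left/right-majority judgements:
#' trials whose sequences have equal presentations on each side have no
#' correct answer and are excluded; hits are "responded right" given the
#' true majority was right, false alarms "responded right" given left,
#' with 1/(2N) clipping.
#'
#' @param trials Data frame from [simulate_behavioural_responses()] (EEG
#'   schedule form) or any table with columns `majority_side` (-1/0/1) and
#'   `response_right` (logical).
#' @return List with `dprime`, `n_right`, `n_left`, `n_excluded_ties`.
#' @export
behavioural_dprime <- function(trials) {
  valid <- trials$majority_side != 0
  if (!any(valid)) stop("no valid (untied) trials", call. = FALSE)
  right <- trials$majority_side[valid] > 0
  resp <- trials$response_right[valid]
  n_r <- sum(right)
  n_l <- sum(!right)
  if (n_r == 0 || n_l == 0) {
    stop("both majority sides must be represented", call. = FALSE)
  }
  list(dprime = dprime_from_counts(sum(resp[right]), n_r,
                                   sum(resp[!right]), n_l),
       n_right = n_r, n_left = n_l,
       n_excluded_ties = sum(!valid))
}

#' Two-sided Wilcoxon signed-rank test (normal approximation)
#'
#' Paired signed-rank test reported as a Z statistic: zero differences are
#' dropped, tied absolute differences receive mid-ranks, and the normal
#' approximation uses the tie-corrected variance and a 0.5 continuity
#' correction. Cross-validated against `stats::wilcox.test` (which reports
#' the same p but not Z).
#'
#' @param x,y Paired numeric vectors (n >= 5 after dropping zeros).
#' @return List with `z`, `p`, `w_plus` (sum of positive ranks), `n_used`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate: all differences are zero", call. = FALSE)
  if (n < 5) stop("need >= 5 non-zero differences", call. = FALSE)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- sign(w_plus - mu) * 0.5
  z <- (w_plus - mu - cc) / sqrt(sigma2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), w_plus = w_plus, n_used = n)
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of the rank-transformed data, with a two-sided p
#' value from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 5).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5) stop("need n >= 5", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}
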