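#' Idealised location-channel basis
#'
#' Five hypothetical location channels with evenly spaced preferred azimuths
#' spanning the stimulus range. Each channel's tuning curve is a half-wave
#' rectified sinusoid raised to a power:
#' `max(0, cos(2*pi*(theta - centre)/period))^exponent`. The default period
#' of 60 degrees gives each channel a 30-degree half-wave support, so the
#' five channels tile the [-15, 15] degree range and the 5 x 5 matrix of
#' channel responses at the five stimulus locations is invertible. Azimuth
#' is treated as a linear (non-circular) feature space.
#'
#' @param centres Channel preferred locations, degrees, strictly increasing
#'   (default five points from -15 to 15).
#' @param exponent Power applied to the rectified sinusoid (default 5).
#' @param period Spatial wavelength of the underlying sinusoid, degrees
#'   (default 60).
#' @return An object of class `channel_basis`.
#' @examples
#' b <- channel_basis()
#' basis_response(b, 0)
#' @export
channel_basis <- function(centres = seq(-15, 15, length.out = 5),
                          exponent = 5, period = 60) {
  if (any(diff(centres) <= 0)) {
    stop("channel centres must be strictly increasing", call. = FALSE)
  }
  if (exponent <= 0 || period <= 0) {
    stop("exponent and period must be > 0", call. = FALSE)
  }
  b <- structure(list(centres = as.numeric(centres), exponent = exponent,
                      period = period),
                 class = "channel_basis")
  gram <- design_matrix(b, centres)
  if (kappa(gram) > 1e6) {
    stop("basis is degenerate: channel responses at the channel centres ",
         "are not invertible (condition number > 1e6)", call. = FALSE)
  }
  b
}

#' Channel responses to a stimulus location
#'
#' @param basis A [channel_basis()].
#' @param location_deg Stimulus azimuth(s), degrees.
#' @return For one location, a vector of channel responses (one per
#'   channel); for several, see [design_matrix()].
#' @export
basis_response <- function(basis, location_deg) {
  stopifnot(inherits(basis, "channel_basis"))
  if (length(location_deg) > 1) {
    return(design_matrix(basis, location_deg))
  }
  phase <- 2 * pi * (location_deg - basis$centres) / basis$period
  pmax(0, cos(phase))^basis$exponent
}

#' Hypothesised channel activities for a set of presentations
#'
#' The design matrix C of the linear encoding model B = W C + E: column j
#' holds the channel responses to the j-th presented location.
#'
#' @param basis A [channel_basis()].
#' @param locations Vector of presented azimuths, degrees.
#' @return Numeric matrix, channels x presentations.
#' @export
design_matrix <- function(basis, locations) {
  stopifnot(inherits(basis, "channel_basis"))
  phase <- outer(basis$centres, locations,
                 function(cen, loc) 2 * pi * (loc - cen) / basis$period)
  unname(pmax(cos(phase), 0)^basis$exponent)
}

#' Least-squares forward (encoding) weights
#'
#' Solves B = W C + E for the weight matrix W (sensors x channels) by
#' ordinary least squares: `W = B C' (C C')^-1`. The residuals are
#' orthogonal to the design (`E C' = 0`).
#'
#' @param b Data matrix, sensors x presentations (one timepoint).
#' @param c_mat Design matrix from [design_matrix()], channels x
#'   presentations.
#' @return Weight matrix W, sensors x channels.
#' @export
fit_forward <- function(b, c_mat) {
  stopifnot(is.matrix(b), is.matrix(c_mat), ncol(b) == ncol(c_mat))
  if (ncol(c_mat) < nrow(c_mat)) {
    stop("need at least as many presentations as channels", call. = FALSE)
  }
  gram <- tcrossprod(c_mat)
  qr_g <- qr(gram)
  if (qr_g$rank < nrow(c_mat)) {
    resp <- apply(c_mat, 1, function(r) any(r > 1e-12))
    stop("singular design: channel(s) ",
         paste(which(!resp | is.na(resp)), collapse = ", "),
         " receive no activation; some locations are missing from the ",
         "training set", call. = FALSE)
  }
  t(solve(gram, c_mat %*% t(b)))
}

#' Shrinkage estimate of the residual noise covariance
#'
#' Analytic (Schaefer-Strimmer style) shrinkage of the sample covariance of
#' the residuals toward its diagonal:
#' `Sigma = (1 - lambda) S + lambda diag(S)`, with the shrinkage intensity
#' estimated from the variance of the off-diagonal entries. Guarantees a
#' positive-definite estimate even when presentations are scarcer than
#' sensors. Zero-variance sensors receive a small ridge (with a warning).
#'
#' @param e Residual matrix, sensors x presentations.
#' @param lambda Optional fixed shrinkage intensity in [0, 1]; by default
#'   estimated analytically.
#' @return List with `sigma` (sensors x sensors), `lambda`, and the sample
#'   covariance `s`.
#' @export
estimate_noise_cov <- function(e, lambda = NULL) {
  stopifnot(is.matrix(e))
  n <- ncol(e)
  if (n < 2) stop("need more than one presentation", call. = FALSE)
  ec <- e - rowMeans(e)
  s <- tcrossprod(ec) / (n - 1)
  if (any(diag(s) <= 0)) {
    warning("zero-variance sensor(s); adding ridge to the diagonal")
    diag(s) <- diag(s) + 1e-10 * max(diag(s), 1e-10)
  }
  if (is.null(lambda)) lambda <- shrink_lambda(ec, s, n)
  sigma <- (1 - lambda) * s + lambda * diag(diag(s), nrow(s))
  # guard against eigenvalues at numerical zero when n - 1 < sensors
  diag(sigma) <- diag(sigma) * (1 + 1e-10)
  list(sigma = sigma, lambda = lambda, s = s)
}

# analytic shrinkage intensity for the off-diagonal entries of S: the
# ratio of the summed sampling variances of the off-diagonal entries
# (estimated from the per-sample cross products) to their summed squares
shrink_lambda <- function(ec, s, n) {
  w_bar <- s * (n - 1) / n
  cp2 <- tcrossprod(ec^2)                      # sum_k (ec_i ec_j)^2
  var_s <- (n / ((n - 1)^3)) * (cp2 - n * w_bar^2)
  off_var <- sum(var_s) - sum(diag(var_s))
  off2 <- sum(s^2) - sum(diag(s)^2)
  if (off2 > 0) min(1, max(0, off_var / off2)) else 1
}

# lean path used inside the cross-validation loop (no diagnostics)
shrink_cov <- function(e, lambda = NULL) {
  n <- ncol(e)
  ec <- e - rowMeans(e)
  s <- tcrossprod(ec) / (n - 1)
  dg <- diag(s)
  if (any(dg <= 0)) {
    dg <- dg + 1e-10 * max(dg, 1e-10)
    diag(s) <- dg
  }
  if (is.null(lambda)) lambda <- shrink_lambda(ec, s, n)
  sig <- (1 - lambda) * s
  diag(sig) <- (diag(sig) + lambda * dg) * (1 + 1e-10)
  sig
}

#' Noise-covariance-aware inverse (decoding) model
#'
#' The generalised-least-squares inverse of the forward weights:
#' `D = (W' Sigma^-1 W)^-1 W' Sigma^-1`, so that `D W = I` and channel
#' estimates `D b` weight sensors by the inverse noise covariance. With
#' `Sigma = I` this reduces to the Moore-Penrose pseudoinverse of W.
#'
#' @param w Forward weights, sensors x channels.
#' @param sigma Noise covariance, sensors x sensors, positive definite.
#' @return Decoder matrix D, channels x sensors.
#' @export
invert_model <- function(w, sigma) {
  stopifnot(is.matrix(w), is.matrix(sigma), nrow(w) == nrow(sigma))
  if (qr(w)$rank < ncol(w)) {
    stop("rank-deficient weight matrix: channels are not separable",
         call. = FALSE)
  }
  si_w <- solve(sigma, w)               # Sigma^-1 W
  solve(crossprod(w, si_w), t(si_w))
}

# Moore-Penrose pseudoinverse via SVD with a relative rank tolerance
pinv <- function(a, tol = 1e-10) {
  sv <- svd(a)
  keep <- sv$d > tol * max(sv$d)
  if (!any(keep)) return(matrix(0, ncol(a), nrow(a)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

# stratified k-fold assignment: within each location, trials are split as
# evenly as possible across folds (seeded)
stratified_folds <- function(locations, k, seed) {
  set.seed(derive_seed(seed, 707))
  fold <- integer(length(locations))
  for (loc in unique(locations)) {
    idx <- which(locations == loc)
    if (length(idx) < k) {
      stop("only ", length(idx), " trials at location ", loc,
           "; use fewer folds (k <= ", length(idx), ")", call. = FALSE)
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated channel reconstruction per timepoint
#'
#' The inverted-encoding decode: for every timepoint, forward weights and
#' residual noise covariance are estimated on the training folds and the
#' held-out trials' sensor vectors are mapped through the inverse model,
#' so every trial is decoded exactly once by a model fit without it. Folds
#' are stratified by stimulus location.
#'
#' @param epochs An [epoch_set()] (only `kept` trials are used).
#' @param basis A [channel_basis()].
#' @param k Number of cross-validation folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param shrinkage Optional fixed shrinkage intensity passed to
#'   [estimate_noise_cov()].
#' @return A `reconstruction` list: `activities` (trials x channels x time
#'   array), `labels` (the kept trials' labels), `times`, `basis`, `folds`.
#' @export
cross_validated_reconstruct <- function(epochs, basis, k = 10, seed = 1L,
                                        shrinkage = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(basis, "channel_basis"))
  keep <- which(epochs$labels$kept)
  dat <- epochs$data[keep, , , drop = FALSE]
  labels <- epochs$labels[keep, , drop = FALSE]
  locs <- labels$location_deg
  n <- length(keep)
  n_ch <- length(basis$centres)
  n_t <- dim(dat)[3]
  fold <- stratified_folds(locs, k, seed)
  c_all <- design_matrix(basis, locs)
  recon <- array(NA_real_, c(n, n_ch, n_t))
  m <- dim(dat)[2]
  for (f in seq_len(k)) {
    te <- fold == f
    tr <- !te
    c_tr <- c_all[, tr, drop = FALSE]
    n_tr <- sum(tr)
    gram <- tcrossprod(c_tr)
    if (qr(gram)$rank < n_ch) {
      stop("singular design in fold ", f, ": some locations are missing ",
           "from the training set", call. = FALSE)
    }
    # fold-constant least-squares projector: W_t = B_t %*% proj
    proj <- t(solve(gram, c_tr))                 # n_tr x channels
    for (t in seq_len(n_t)) {
      b_tr <- t(dat[tr, , t])
      b_te <- t(matrix(dat[te, , t, drop = FALSE], nrow = sum(te)))
      w <- b_tr %*% proj
      e <- b_tr - w %*% c_tr
      sig <- shrink_cov(e, lambda = shrinkage)
      si_w <- solve(sig, w)
      d <- solve(crossprod(w, si_w), t(si_w))
      recon[te, , t] <- t(d %*% b_te)
    }
  }
  structure(list(activities = recon, labels = labels,
                 times = epochs$times, basis = basis, folds = fold),
            class = "reconstruction")
}

#' Per-sensor location information map
#'
#' Scores how much location information each sensor carries by treating
#' time as the decoding dimension: for each sensor, the samples inside
#' `window` are the features of a cross-validated inverted-encoding decode,
#' and the sensor's score is the mean decoding accuracy over trials.
#'
#' @param epochs An [epoch_set()].
#' @param basis A [channel_basis()].
#' @param window Time window in seconds (default `c(0.15, 0.25)`).
#' @param k Folds (default 10).
#' @param seed Integer seed.
#' @return Named numeric vector of per-sensor accuracy scores.
#' @export
per_sensor_information <- function(epochs, basis, window = c(0.15, 0.25),
                                   k = 10, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  t_idx <- which(epochs$times >= window[1] & epochs$times <= window[2])
  if (length(t_idx) < length(basis$centres)) {
    stop("window [", window[1], ", ", window[2], "] s lies outside the ",
         "epoch or holds too few samples", call. = FALSE)
  }
  keep <- which(epochs$labels$kept)
  labels <- epochs$labels[keep, , drop = FALSE]
  locs <- labels$location_deg
  fold <- stratified_folds(locs, k, seed)
  c_all <- design_matrix(basis, locs)
  n_sensors <- dim(epochs$data)[2]
  scores <- numeric(n_sensors)
  for (s in seq_len(n_sensors)) {
    feat <- t(epochs$data[keep, s, t_idx])     # time-features x trials
    recon <- matrix(NA_real_, length(keep), length(basis$centres))
    for (f in seq_len(k)) {
      te <- fold == f
      tr <- !te
      w <- fit_forward(feat[, tr, drop = FALSE], c_all[, tr, drop = FALSE])
      e <- feat[, tr, drop = FALSE] - w %*% c_all[, tr, drop = FALSE]
      sig <- estimate_noise_cov(e)$sigma
      # a single sensor often carries one temporal profile, making W
      # effectively rank deficient in channel space; invert the channel
      # Gram with a truncated pseudoinverse (directions below 5% of the
      # dominant one are noise fits, not signal)
      si_w <- solve(sig, w)
      d <- pinv(crossprod(w, si_w), tol = 0.05) %*% t(si_w)
      recon[te, ] <- t(d %*% feat[, te, drop = FALSE])
    }
    # direction-only (cosine) scoring: a single sensor's reconstruction has
    # an essentially arbitrary overall scale, and normalising bounds the
    # score's sampling noise
    scores[s] <- mean(accuracy_score_trials(recon, locs, basis,
                                            normalize = TRUE))
  }
  names(scores) <- epochs$sensor_names
  scores
}
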