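# Independent oracles and fixture builders. Everything here is written
# against the mathematical definitions directly (explicit H matrices,
# double loops), never against the package's own computational path.

rand_psd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  crossprod(A) / n
}

rand_orthonormal <- function(n, h) {
  qr.Q(qr(matrix(rnorm(n * h), n, h)))[, seq_len(h), drop = FALSE]
}

# HSIC by explicit centering-matrix products: (n-1)^-2 * sum_ij (HKH)_ij L_ij
hsic_oracle <- function(K, L) {
  n <- nrow(K)
  H <- diag(n) - 1 / n
  HKH <- H %*% K %*% H
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + HKH[i, j] * L[i, j]
  s / (n - 1)^2
}

# Largest principal angle (radians) between the column spans of A and B.
principal_angle <- function(A, B) {
  Qa <- qr.Q(qr(A))
  Qb <- qr.Q(qr(B))
  sv <- svd(crossprod(Qa, Qb))$d
  acos(max(-1, min(1, min(sv))))
}

# MICF objective by naive full matrix products (independent of the
# package's centered-product shortcut).
micf_objective_naive <- function(W, Kx, Ky, mu) {
  n <- nrow(Kx)
  H <- diag(n) - 1 / n
  sum(diag(-t(W) %*% Kx %*% H %*% Ky %*% H %*% Kx %*% W)) +
    mu * sum(diag(t(W) %*% Kx %*% H %*% Kx %*% W))
}

# Two-class Gaussian domains: source at means (+/-2, 0), target shifted
# by +1 along the second axis; n samples per domain, unit variance.
gaussian_shift_domains <- function(seed, n = 200) {
  set.seed(seed)
  half <- n / 2
  Zs <- rbind(matrix(rnorm(n), half, 2) + cbind(rep(2, half), 0),
              matrix(rnorm(n), half, 2) + cbind(rep(-2, half), 0))
  Zt <- rbind(matrix(rnorm(n), half, 2) + cbind(rep(2, half), 1),
              matrix(rnorm(n), half, 2) + cbind(rep(-2, half), 1))
  list(Zs = Zs, ys = rep(1:2, each = half),
       Zt = Zt, yt = rep(1:2, each = half))
}

# Small labeled sample set with random features for IO round trips.
rand_sample_set <- function(seed, n = 12, m = 4, n_batches = 2) {
  set.seed(seed)
  sample_set(
    features = matrix(rnorm(n * m), n, m),
    labels = sample(1:3, n, replace = TRUE),
    concentrations = exp(runif(n, log(10), log(1000))),
    batch_ids = rep(seq_len(n_batches), length.out = n)
  )
}

# Row subset of a sample_set via the public constructor.
subset_samples_for_test <- function(s, idx) {
  sample_set(s$features[idx, , drop = FALSE], s$labels[idx],
             s$concentrations[idx], s$batch_ids[idx], s$roles[idx],
             s$eval_labels[idx], s$eval_concentrations[idx])
}

# A widely separated instrument: class gains differ by much more than the
# noise floor, so classes are trivially separable (Bayes oracle setting).
separated_config <- function(seed = 1, noise_sd = 0.01, n_batches = 3,
                             samples_per_cell = 10,
                             batch_gain_drift = NULL,
                             batch_offset_drift = NULL,
                             concentration_grid = c(100)) {
  drift_sim_config(
    n_classes = 3, n_sensors = 4, n_batches = n_batches,
    samples_per_cell = samples_per_cell,
    concentration_grid = concentration_grid,
    response_gain = outer(c(1, 2, 4, 8), c(1, 20, 400)),
    response_exponent = matrix(0.5, 4, 3),
    batch_gain_drift = batch_gain_drift,
    batch_offset_drift = batch_offset_drift,
    noise_sd = noise_sd, seed = seed
  )
}
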