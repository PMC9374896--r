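# Shared fixture builders. Everything is generated in code; no files.

# well-conditioned random SPD matrix
rand_spd <- function(n, seed = NULL, scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  S <- crossprod(A) / n + diag(n) * 0.5
  (S + t(S)) / 2 * scale
}

# random SPD with eigenvalues spread over several decades but condition < 1e6
rand_spd_spread <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  U <- qr.Q(qr(matrix(rnorm(n * n), n)))
  lam <- 10^runif(n, -2.5, 1.5)
  S <- U %*% (lam * t(U))
  (S + t(S)) / 2
}

# trajectory of small perturbations around a set of base matrices
cluster_traj <- function(bases, per_cluster, jitter = 0.01, seed = 1) {
  set.seed(seed)
  mats <- list()
  labels <- integer(0)
  for (q in seq_along(bases)) {
    Lq <- spd_logm(bases[[q]])
    for (i in seq_len(per_cluster)) {
      Z <- matrix(rnorm(length(Lq), sd = jitter), nrow(Lq))
      mats <- c(mats, list(spd_expm(Lq + (Z + t(Z)) / 2)))
      labels <- c(labels, q)
    }
  }
  list(traj = spd_trajectory(mats, subject_id = "fix"), labels = labels)
}

# small separable piecewise-stationary simulation for training tests
toy_design <- function(seed = 1, durations = rep(50L, 4L), n_regions = 10L,
                       window = 15L) {
  sim_design(n_regions = n_regions, durations = durations, window = window,
             seed = seed)
}

frob <- function(M) sqrt(sum(M^2))
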