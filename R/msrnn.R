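# Mean-shift recurrence on the SPD manifold. The recurrence operates in the
# log-Euclidean chart: each layer replaces every log-matrix by the Gaussian
# kernel-weighted average of all log-matrices, which in manifold terms is the
# exp-map step V <- exp(log V + Z) with Z the mean-shift vector.

# stack the matrix logs of a trajectory as rows of a T x P^2 matrix
.traj_log_rows <- function(traj) {
  t(vapply(traj$matrices, function(M) as.vector(spd_logm(M)),
           numeric(length(traj$matrices[[1]]))))
}

.rows_to_mats <- function(L, p) {
  lapply(seq_len(nrow(L)), function(i) .sym(matrix(L[i, ], p, p)))
}

# pairwise squared Frobenius distances between rows
.row_sqdist <- function(L) {
  sq <- rowSums(L^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(L)
  D2[D2 < 0] <- 0
  D2
}

#' Mean-shift parameters
#'
#' One Gaussian kernel bandwidth per mean-shift layer. With
#' `bandwidth = "relative"` (default) each layer's effective bandwidth is
#' `sigma * s` where `s` is the median pairwise geodesic distance of that
#' layer's input: the recurrence is then scale-free, so the kernel stays
#' matched to the shrinking point cloud instead of degenerating into global
#' averaging once the cloud collapses below a fixed bandwidth.
#' `"absolute"` uses the bandwidths as given.
#'
#' @param sigmas positive numeric vector of bandwidths, one per layer (the
#'   published initialisation is 0.5; the default depth is 5 layers).
#' @param bandwidth `"relative"` or `"absolute"`.
#' @return An object of class `msrnn_params`.
#' @export
msrnn_params <- function(sigmas = rep(0.5, 5L),
                         bandwidth = c("relative", "absolute")) {
  if (any(sigmas <= 0)) stop("all bandwidths must be positive")
  structure(list(sigmas = as.numeric(sigmas), bandwidth = match.arg(bandwidth)),
            class = "msrnn_params")
}

#' Mean-shift vector of one trajectory point
#'
#' \eqn{Z_t} points from \eqn{\log V_t} to the kernel-weighted average of all
#' log-matrices, with Gaussian weights
#' \eqn{k(g) = \exp(-g^2 / 2\sigma^2)} on the pairwise geodesic distances.
#' It vanishes when all points coincide, and tends to zero as
#' \eqn{\sigma \to 0^+} (the self weight dominates).
#'
#' @param t 1-based index of the point within the trajectory.
#' @param traj an [spd_trajectory()].
#' @param sigma positive kernel bandwidth.
#' @return A symmetric matrix (tangent vector in the log chart).
#' @export
ms_vector <- function(t, traj, sigma) {
  if (sigma <= 0) stop("'sigma' must be positive")
  L <- .traj_log_rows(traj)
  g2 <- rowSums((L - matrix(L[t, ], nrow(L), ncol(L), byrow = TRUE))^2)
  w <- exp(-g2 / (2 * sigma^2))
  target <- colSums(w * L) / sum(w)
  p <- nrow(traj$matrices[[1]])
  .sym(matrix(target - L[t, ], p, p))
}

#' Apply a mean-shift vector to an SPD matrix
#'
#' The exp-map update \eqn{V \leftarrow \exp(\log V + Z)}.
#'
#' @param V SPD matrix.
#' @param Z symmetric tangent matrix of the same dimension.
#' @return The shifted SPD matrix.
#' @export
ms_apply <- function(V, Z) {
  if (!all(dim(V) == dim(Z))) stop("shape mismatch")
  spd_expm(spd_logm(V) + .sym(Z))
}

# One synchronous mean-shift layer on the log-row matrix; returns the new
# rows plus the quantities needed for backpropagation. For relative
# bandwidths the layer scale (median pairwise distance of the input) is
# treated as a constant in the backward pass.
.ms_layer <- function(L, sigma, bandwidth = "absolute") {
  D2 <- .row_sqdist(L)
  scale <- if (bandwidth == "relative") median(sqrt(D2[upper.tri(D2)])) else 1
  sig <- sigma * scale
  if (!is.finite(sig) || sig <= 0) { # fully collapsed input: nothing to move
    n <- nrow(L)
    return(list(L = L, A = diag(n), D2 = D2, sigma_eff = sigma, scale = 1))
  }
  W <- exp(-D2 / (2 * sig^2))
  A <- W / rowSums(W)
  list(L = A %*% L, A = A, D2 = D2, sigma_eff = sig, scale = scale)
}

#' Mean-shift recurrence over a trajectory
#'
#' Applies `length(params$sigmas)` synchronous mean-shift layers: all shift
#' vectors of a layer are computed before any point moves. Points belonging
#' to the same state collapse towards a common mode, separable states remain
#' apart.
#'
#' @param params an [msrnn_params()].
#' @param traj an [spd_trajectory()].
#' @return The stratified [spd_trajectory()].
#' @export
msrnn_forward <- function(params, traj) {
  stopifnot(inherits(params, "msrnn_params"), inherits(traj, "spd_trajectory"))
  if (!length(params$sigmas)) return(traj)
  L <- .traj_log_rows(traj)
  for (sigma in params$sigmas) L <- .ms_layer(L, sigma, params$bandwidth)$L
  p <- nrow(traj$matrices[[1]])
  mats <- lapply(.rows_to_mats(L, p), spd_expm)
  spd_trajectory(mats, times = traj$times, subject_id = traj$subject_id,
                 validate = FALSE)
}

#' State labelling of a stratified trajectory
#'
#' Groups the stratified matrices by single-linkage agglomeration under the
#' log-Euclidean geodesic distance, cutting at `tol`; each group's mode is
#' the Frechet mean of its members.
#'
#' @param stratified an [spd_trajectory()], typically the output of
#'   [msrnn_forward()].
#' @param tol positive linkage threshold. `NULL` (default) uses
#'   `0.1 *` the median pairwise geodesic distance of the stratified set
#'   (floored at `1e-8` for fully-collapsed inputs). The rule is scale free
#'   and matched to the trained representation geometry: the contrastive
#'   objective drives same-state distances towards 0 and different-state
#'   distances towards 1 or more, so the median pairwise distance sits at
#'   the between-mode scale and a tenth of it cleanly separates the
#'   collapsed modes.
#' @param min_size smallest group accepted as a genuine mode. Windows
#'   straddling a state transition carry mixed correlations and end up
#'   between modes; under single linkage they form small chain fragments.
#'   Any group smaller than `min_size` (default 5 windows, mirroring the
#'   change-point minimum duration) is absorbed into the group with the
#'   nearest mode, so only persistent states are counted. Set to 1 to
#'   disable.
#' @return An object of class `state_labeling`: `labels` (integer per
#'   window), `modes` (list of SPD matrices), `Q_detected`, `times`.
#' @export
group_modes <- function(stratified, tol = NULL, min_size = 5L) {
  stopifnot(inherits(stratified, "spd_trajectory"))
  L <- .traj_log_rows(stratified)
  d <- dist(L)
  n <- nrow(L)
  hc <- if (n > 1L) hclust(d, method = "single")
  if (is.null(tol)) tol <- max(0.1 * median(d), 1e-8)
  if (tol <= 0) stop("'tol' must be positive")
  labels <- if (n == 1L) 1L else cutree(hc, h = tol)
  # log-chart group centroids (= log of the log-Euclidean Frechet mean)
  centroid <- function(q) colMeans(L[labels == q, , drop = FALSE])
  cents <- lapply(sort(unique(labels)), centroid)
  names(cents) <- sort(unique(labels))
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) <= 1L) break
    q <- small[which.min(sizes[small])]
    others <- setdiff(names(sizes), q)
    dd <- vapply(others, function(o)
      sqrt(sum((cents[[q]] - cents[[o]])^2)), numeric(1))
    tgt <- others[which.min(dd)]
    labels[labels == as.integer(q)] <- as.integer(tgt)
    cents[[tgt]] <- colMeans(L[labels == as.integer(tgt), , drop = FALSE])
    cents[[q]] <- NULL
  }
  labels <- as.integer(factor(labels, levels = unique(labels)))
  modes <- lapply(seq_len(max(labels)), function(q)
    frechet_mean(stratified$matrices[labels == q]))
  structure(list(labels = labels, modes = modes,
                 Q_detected = max(labels), times = stratified$times,
                 tol = tol),
            class = "state_labeling")
}

#' @export
print.state_labeling <- function(x, ...) {
  cat(sprintf("state_labeling: %d windows, %d states (tol %.3g)\n",
              length(x$labels), x$Q_detected, x$tol))
  invisible(x)
}

#' Write state labels as two-column delimited text
#'
#' Columns: window-centre time index, integer state label.
#'
#' @param labeling a `state_labeling` (or list with `times` and `labels`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_state_labels <- function(labeling, path) {
  write.table(data.frame(time = labeling$times, state = labeling$labels),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
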