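# SPD feature-learning network: stacked bilinear dimension-reduction (BiMap)
# and eigenvalue-rectification (ReEig) layers, with analytic eigen-gradients
# and Stiefel-manifold updates for the bilinear weights.

#' Random semi-orthogonal BiMap weight
#'
#' Draws a seeded Gaussian matrix and orthonormalises its rows (QR with sign
#' fix), giving `W` with `W %*% t(W) = I` exactly up to round-off and a
#' deterministic result for a given seed.
#'
#' @param rows,cols target shape, `rows <= cols`.
#' @param seed integer seed.
#' @return A `rows x cols` semi-orthogonal matrix.
#' @export
init_semiorthogonal <- function(rows, cols, seed = 1L) {
  if (rows > cols) stop("'rows' must not exceed 'cols'")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  A <- matrix(rnorm(cols * rows), nrow = cols, ncol = rows)
  .orthonormal_rows(t(A))
}

# Orthonormalise the rows of W (rows <= cols) via QR of t(W), with the sign
# of diag(R) fixed so the map is deterministic and close to the input.
.orthonormal_rows <- function(W) {
  qr_ <- qr(t(W))
  Q <- qr.Q(qr_)
  R <- qr.R(qr_)
  s <- sign(diag(R))
  s[s == 0] <- 1
  t(Q %*% diag(s, nrow = length(s)))
}

#' Construct an SPD network model
#'
#' An ordered stack of BiMap layers (each followed by a ReEig rectification)
#' taking `dims[1] x dims[1]` SPD inputs down to `dims[K+1]`-dimensional SPD
#' representations.
#'
#' @param dims strictly decreasing (or equal-ending) integer vector of layer
#'   sizes, e.g. `c(10, 8, 6, 4)`.
#' @param epsilon ReEig rectification threshold, scalar or one value per
#'   layer.
#' @param seed seed for the semi-orthogonal weight initialisation.
#' @return An object of class `spdnet_model` with fields `W` (list of weight
#'   matrices), `epsilon`, `dims`.
#' @export
spdnet_model <- function(dims, epsilon = 1e-4, seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) < 2L) stop("'dims' needs at least input and output sizes")
  if (any(diff(dims) > 0)) stop("'dims' must be non-increasing")
  K <- length(dims) - 1L
  epsilon <- rep(epsilon, length.out = K)
  if (any(epsilon <= 0)) stop("'epsilon' must be positive")
  W <- lapply(seq_len(K), function(k)
    init_semiorthogonal(dims[k + 1L], dims[k], seed = seed + k - 1L))
  structure(list(W = W, epsilon = epsilon, dims = dims),
            class = "spdnet_model")
}

#' @export
print.spdnet_model <- function(x, ...) {
  cat(sprintf("spdnet_model: %s (ReEig eps %s)\n",
              paste(x$dims, collapse = " -> "),
              paste(signif(x$epsilon, 3), collapse = "/")))
  invisible(x)
}

#' BiMap layer forward pass
#'
#' The bilinear positive map \eqn{W X W^\top}, reducing SPD dimension while
#' preserving positive-definiteness when `W` has full row rank.
#'
#' @param W `rows x cols` weight matrix.
#' @param X SPD matrix of dimension `cols`.
#' @return SPD matrix of dimension `rows`.
#' @export
bimap_forward <- function(W, X) {
  if (ncol(W) != nrow(X)) stop("dimension mismatch between 'W' and 'X'")
  .sym(W %*% X %*% t(W))
}

#' ReEig layer forward pass
#'
#' Eigenvalue rectification \eqn{U \max(\epsilon I, \Lambda) U^\top}, the SPD
#' analogue of ReLU: it bounds the spectrum away from zero and is idempotent.
#'
#' @param X symmetric PSD matrix.
#' @param epsilon positive rectification threshold.
#' @return SPD matrix with min eigenvalue at least `epsilon`.
#' @export
reeig_forward <- function(X, epsilon = 1e-4) {
  if (epsilon <= 0) stop("'epsilon' must be positive")
  e <- eigen(.sym(X), symmetric = TRUE)
  .sym(e$vectors %*% (pmax(e$values, epsilon) * t(e$vectors)))
}

#' Apply the SPD network to a trajectory
#'
#' Runs each matrix independently through the alternating BiMap/ReEig stack.
#'
#' @param model an [spdnet_model()].
#' @param traj an [spd_trajectory()] with matrix dimension `model$dims[1]`.
#' @return The transformed [spd_trajectory()] of dimension `dims[K+1]`.
#' @export
spdnet_forward <- function(model, traj) {
  stopifnot(inherits(model, "spdnet_model"), inherits(traj, "spd_trajectory"))
  if (nrow(traj$matrices[[1]]) != model$dims[1])
    stop("trajectory dimension does not match model input size")
  mats <- lapply(traj$matrices, function(X) .spdnet_forward_one(model, X)$out)
  spd_trajectory(mats, times = traj$times, subject_id = traj$subject_id,
                 validate = FALSE)
}

# Forward one matrix, caching per-layer inputs and eigendecompositions for
# the backward pass. The ReEig output shares eigenvectors with its input, so
# one decomposition per layer serves the forward map, its gradient, and (at
# the last layer) the log-chart map of the output.
.spdnet_forward_one <- function(model, X) {
  K <- length(model$W)
  cache <- vector("list", K)
  for (k in seq_len(K)) {
    W <- model$W[[k]]
    e <- eigen(.sym(W %*% X %*% t(W)), symmetric = TRUE)
    lam <- pmax(e$values, model$epsilon[k])
    cache[[k]] <- list(Xin = X, e = e, lam = lam)
    X <- .sym(e$vectors %*% (lam * t(e$vectors)))
  }
  list(out = X, cache = cache)
}

# ---- analytic gradients -----------------------------------------------------

# Daleckii-Krein gradient of S -> U f(Lambda) U' pulled back through the
# Loewner matrix, given the eigendecomposition `e` of symmetric S. G is the
# (symmetrised) upstream gradient.
.loewner_backward <- function(e, G, f, fprime, tie_tol = 1e-12) {
  lam <- e$values
  U <- e$vectors
  dl <- outer(lam, lam, `-`)
  ties <- abs(dl) < tie_tol
  dl[ties] <- 1 # placeholder, overwritten below
  Fm <- outer(f(lam), f(lam), `-`) / dl
  mid <- fprime((outer(lam, lam, `+`)) / 2)
  Fm[ties] <- mid[ties]
  .sym(U %*% (Fm * (t(U) %*% .sym(G) %*% U)) %*% t(U))
}

# as above, from the matrix itself
.eigfun_backward <- function(S, G, f, fprime, tie_tol = 1e-12) {
  .loewner_backward(eigen(.sym(S), symmetric = TRUE), G, f, fprime, tie_tol)
}

# gradient through reeig_forward wrt its input
.reeig_backward <- function(Xb, G, epsilon) {
  .eigfun_backward(Xb, G,
                   f = function(x) pmax(x, epsilon),
                   fprime = function(x) as.numeric(x > epsilon))
}

# gradient through spd_logm wrt its input
.logm_backward <- function(S, G) {
  .eigfun_backward(S, G, f = log, fprime = function(x) 1 / x)
}

# backward through the whole stack for one matrix; returns grad wrt input and
# the per-layer weight gradients (list of matrices shaped like W)
.spdnet_backward_one <- function(model, cache, G) {
  K <- length(model$W)
  gW <- vector("list", K)
  for (k in rev(seq_len(K))) {
    eps <- model$epsilon[k]
    G <- .loewner_backward(cache[[k]]$e, G,
                           f = function(x) pmax(x, eps),
                           fprime = function(x) as.numeric(x > eps))
    W <- model$W[[k]]
    gW[[k]] <- 2 * G %*% W %*% cache[[k]]$Xin
    G <- t(W) %*% G %*% W
  }
  list(gX = G, gW = gW)
}

#' Riemannian gradient step on the Stiefel manifold
#'
#' For each BiMap weight the Euclidean gradient is projected onto the tangent
#' space of the row-semi-orthogonal matrices
#' (\eqn{\tilde G = G - W G^\top W}), a descent step of size `lr` is taken,
#' and the result is retracted onto the manifold by QR row
#' re-orthonormalisation, restoring `W %*% t(W) = I`.
#'
#' @param model an [spdnet_model()].
#' @param euclidean_grads list of per-layer gradient matrices shaped like the
#'   weights.
#' @param lr step size (the published training rate is 0.01).
#' @return The updated model.
#' @export
stiefel_step <- function(model, euclidean_grads, lr = 0.01) {
  stopifnot(length(euclidean_grads) == length(model$W))
  for (k in seq_along(model$W)) {
    W <- model$W[[k]]
    G <- euclidean_grads[[k]]
    Gt <- G - W %*% t(G) %*% W
    model$W[[k]] <- .orthonormal_rows(W - lr * Gt)
  }
  model
}

# ---- checkpoint I/O ---------------------------------------------------------

#' Save / load an SPD network model as text
#'
#' The checkpoint is a directory holding a JSON manifest (`dims`, `epsilon`)
#' plus one tab-separated file per layer weight.
#'
#' @param model an [spdnet_model()].
#' @param dir checkpoint directory (created if missing).
#' @return `save_spdnet` returns `dir` invisibly; `load_spdnet` the model.
#' @export
save_spdnet <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(dims = model$dims, epsilon = model$epsilon),
                       file.path(dir, "manifest.json"), digits = NA)
  for (k in seq_along(model$W))
    write_spd_matrix(model$W[[k]], file.path(dir, sprintf("W%d.tsv", k)))
  invisible(dir)
}

#' @rdname save_spdnet
#' @export
load_spdnet <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  K <- length(man$dims) - 1L
  W <- lapply(seq_len(K), function(k)
    read_spd_matrix(file.path(dir, sprintf("W%d.tsv", k))))
  structure(list(W = W, epsilon = rep(man$epsilon, length.out = K),
                 dims = as.integer(man$dims)),
            class = "spdnet_model")
}
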