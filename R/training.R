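# Self-supervised contrastive objective on the learned SPD representations,
# and the joint optimisation loop over network weights (Stiefel manifold) and
# mean-shift bandwidths (softplus-reparameterised).

#' Pairwise similarity from geodesic distance
#'
#' \eqn{d = 1 / (1 + g)}: 1 for coincident points, strictly decreasing in the
#' geodesic distance.
#'
#' @param g non-negative geodesic distance (vectorised).
#' @return Similarity in `(0, 1]`.
#' @export
pairwise_similarity <- function(g) {
  if (any(g < 0)) stop("'g' must be non-negative")
  1 / (1 + g)
}

#' Training configuration
#'
#' @param alpha margin in `(0, 1]` for negative (different-state) pairs.
#' @param label_source `"ms_grouping"` (self-supervised labels from the
#'   mean-shift mode grouping) or `"known_schedule"` (supervise with a known
#'   per-window schedule, the pretext-task variant).
#' @param lr learning rate (published value 0.01).
#' @param epochs number of epochs.
#' @param seed integer seed controlling pair subsampling.
#' @param group_tol linkage threshold for the self-supervised grouping;
#'   `NULL` for the adaptive default of [group_modes()].
#' @param train_sigma whether the kernel bandwidths are trained jointly.
#' @param pair_cap trajectories longer than this use subsampled pairs.
#' @param n_pairs number of ordered pairs sampled per epoch above the cap.
#' @param max_grad_norm global gradient-norm clip (the usual recurrent-net
#'   safeguard: near-coincident same-state pairs make the raw pair-sum
#'   gradient unbounded).
#' @param sigma_floor lower bound kept on the bandwidths during training.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.5, label_source = c("ms_grouping",
                                                      "known_schedule"),
                        lr = 0.01, epochs = 20L, seed = 1L, group_tol = NULL,
                        train_sigma = TRUE, pair_cap = 400L,
                        n_pairs = 50000L, max_grad_norm = 10,
                        sigma_floor = 1e-3) {
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  if (lr <= 0) stop("'lr' must be positive")
  structure(list(alpha = alpha, label_source = match.arg(label_source),
                 lr = lr, epochs = as.integer(epochs), seed = as.integer(seed),
                 group_tol = group_tol, train_sigma = isTRUE(train_sigma),
                 pair_cap = as.integer(pair_cap),
                 n_pairs = as.integer(n_pairs),
                 max_grad_norm = max_grad_norm, sigma_floor = sigma_floor),
            class = "loss_config")
}

# loss and gradient on the log-chart rows; pairs = NULL means all ordered
# pairs, otherwise a 2-column matrix of sampled ordered pairs (t, s) whose sum
# is rescaled to estimate the full pair sum.
.contrastive_on_rows <- function(L, labels, alpha, pairs = NULL,
                                 want_grad = TRUE) {
  n <- nrow(L)
  if (is.null(pairs)) {
    G <- sqrt(.row_sqdist(L))
    d <- 1 / (1 + G)
    same <- outer(labels, labels, `==`)
    term <- ifelse(same, 1 - d, pmax(d - alpha, 0))
    diag(term) <- 0
    loss <- sum(term)
    if (!want_grad) return(list(loss = loss))
    # d(term)/dg per ordered pair
    M <- ifelse(same, d^2, -d^2 * (d > alpha))
    diag(M) <- 0
    K <- matrix(0, n, n)
    nz <- G > 0
    K[nz] <- 2 * M[nz] / G[nz]
    grad <- rowSums(K) * L - K %*% L
    return(list(loss = loss, grad = grad))
  }
  t_ <- pairs[, 1]; s_ <- pairs[, 2]
  Dif <- L[t_, , drop = FALSE] - L[s_, , drop = FALSE]
  g <- sqrt(rowSums(Dif^2))
  d <- 1 / (1 + g)
  same <- labels[t_] == labels[s_]
  term <- ifelse(same, 1 - d, pmax(d - alpha, 0))
  scale <- (n * (n - 1)) / nrow(pairs)
  loss <- scale * sum(term)
  if (!want_grad) return(list(loss = loss))
  coef <- ifelse(same, d^2, -d^2 * (d > alpha))
  coef[g == 0] <- 0
  unit <- Dif / ifelse(g > 0, g, 1)
  contrib <- scale * coef * unit
  grad <- matrix(0, n, ncol(L))
  gt <- rowsum(contrib, t_)
  grad[as.integer(rownames(gt)), ] <- grad[as.integer(rownames(gt)), ] + gt
  gs <- rowsum(-contrib, s_)
  grad[as.integer(rownames(gs)), ] <- grad[as.integer(rownames(gs)), ] + gs
  list(loss = loss, grad = grad)
}

#' Self-supervised contrastive loss
#'
#' Sums, over all ordered pairs of windows \eqn{(t, t')}, \eqn{t \neq t'}:
#' \eqn{1 - d_{tt'}} for same-state pairs and
#' \eqn{\max(d_{tt'} - \alpha, 0)} for different-state pairs, where
#' \eqn{d_{tt'} = 1/(1 + g_{tt'})} is the similarity of the log-Euclidean
#' geodesic distance. Zero iff same-state pairs coincide and different-state
#' pairs are at least `1/alpha - 1` apart.
#'
#' @param traj an [spd_trajectory()] of representations.
#' @param labels integer state label per window (or a `state_labeling`).
#' @param alpha margin for negative pairs.
#' @return Non-negative scalar loss.
#' @export
contrastive_loss <- function(traj, labels, alpha = 0.5) {
  if (inherits(labels, "state_labeling")) labels <- labels$labels
  stopifnot(inherits(traj, "spd_trajectory"))
  if (length(labels) != length(traj$matrices))
    stop("'labels' length must match the trajectory")
  L <- .traj_log_rows(traj)
  .contrastive_on_rows(L, labels, alpha, want_grad = FALSE)$loss
}

# backward through one mean-shift layer; see .ms_layer for the forward
.ms_layer_backward <- function(Lin, A, D2, sigma, Ghat) {
  gL <- t(A) %*% Ghat
  C0 <- Ghat %*% t(Lin)
  cbar <- rowSums(A * C0)
  B <- A * (C0 - cbar)
  gL <- gL - (rowSums(B) * Lin - B %*% Lin) / sigma^2
  gL <- gL + (t(B) %*% Lin - colSums(B) * Lin) / sigma^2
  gsigma <- sum(B * D2) / sigma^3
  list(gL = gL, gsigma = gsigma)
}

# Full forward for one trajectory with caches; returns everything needed for
# the loss and the backward sweep. The log-chart rows reuse the last layer's
# eigendecomposition (ReEig output and its log share eigenvectors). With
# `model = NULL` the network stage is skipped (bandwidth-only training).
.pipeline_forward <- function(model, ms, traj) {
  if (is.null(model)) {
    P <- nrow(traj$matrices[[1]])
    fw <- NULL
    L <- .traj_log_rows(traj)
  } else {
    arr <- array(unlist(traj$matrices),
                 dim = c(model$dims[1], model$dims[1], length(traj$matrices)))
    fw <- .spdnet_batch_forward_cpp(arr, model$W, model$epsilon)
    P <- model$dims[length(model$dims)]
    L <- fw$L0
  }
  layers <- vector("list", length(ms$sigmas))
  for (e in seq_along(ms$sigmas)) {
    st <- .ms_layer(L, ms$sigmas[e], ms$bandwidth)
    layers[[e]] <- list(Lin = L, A = st$A, D2 = st$D2,
                        sigma_eff = st$sigma_eff, scale = st$scale)
    L <- st$L
  }
  list(fw = fw, L = L, layers = layers, P = P)
}

# backward from grad on the final log rows down to weight/bandwidth grads
.pipeline_backward <- function(model, ms, state, gL) {
  gsig <- numeric(length(ms$sigmas))
  for (e in rev(seq_along(state$layers))) {
    ly <- state$layers[[e]]
    bk <- .ms_layer_backward(ly$Lin, ly$A, ly$D2, ly$sigma_eff, gL)
    gL <- bk$gL
    gsig[e] <- bk$gsigma * ly$scale
  }
  if (is.null(model)) return(list(gW = list(), gsigma = gsig))
  gW <- .spdnet_batch_backward_cpp(state$fw, model$W, model$epsilon, gL)
  list(gW = gW, gsigma = gsig)
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

#' Jointly train the SPD network and mean-shift bandwidths
#'
#' Per epoch and trajectory: forward through the network and the mean-shift
#' recurrence, obtain state labels (from the mode grouping, or a known
#' schedule), evaluate the contrastive loss on the stratified
#' representations, and backpropagate analytically through both stages.
#' Network weights take a Riemannian step on the Stiefel manifold
#' ([stiefel_step()]); bandwidths take a gradient step through a softplus
#' reparameterisation that keeps them positive. Labels are discrete and
#' recomputed every epoch; no gradient flows through the grouping.
#'
#' @param model an [spdnet_model()], or `NULL` to train the mean-shift
#'   bandwidths alone on the raw trajectories (the network-off ablation).
#' @param ms an [msrnn_params()].
#' @param data list of aligned [spd_trajectory()] objects; for
#'   `label_source = "known_schedule"` each element must carry a `truth`
#'   field of per-window labels.
#' @param cfg a [loss_config()].
#' @return List with the trained `model`, `ms`, and `history` (total loss per
#'   epoch). Deterministic for a fixed `cfg$seed`.
#' @export
train_geometric <- function(model, ms, data, cfg = loss_config()) {
  stopifnot(is.null(model) || inherits(model, "spdnet_model"),
            inherits(ms, "msrnn_params"))
  data <- lapply(data, function(d) {
    if (inherits(d, "spd_trajectory")) list(traj = d, truth = d$truth) else d
  })
  if (cfg$label_source == "known_schedule" &&
      any(vapply(data, function(d) is.null(d$truth), TRUE)))
    stop("label_source 'known_schedule' requires per-window 'truth' labels")
  history <- numeric(0)
  rho <- .softplus_inv(ms$sigmas)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  for (ep in seq_len(cfg$epochs)) {
    total <- 0
    for (d in data) {
      st <- .pipeline_forward(model, ms, d$traj)
      n <- nrow(st$L)
      labels <- if (cfg$label_source == "known_schedule") d$truth else {
        strat <- spd_trajectory(lapply(.rows_to_mats(st$L, st$P), spd_expm),
                                times = d$traj$times, validate = FALSE)
        group_modes(strat, tol = cfg$group_tol)$labels
      }
      pairs <- NULL
      if (n > cfg$pair_cap) {
        t_ <- sample.int(n, cfg$n_pairs, replace = TRUE)
        s_ <- sample.int(n - 1L, cfg$n_pairs, replace = TRUE)
        s_ <- ifelse(s_ >= t_, s_ + 1L, s_)
        pairs <- cbind(t_, s_)
      }
      cl <- .contrastive_on_rows(st$L, labels, cfg$alpha, pairs = pairs)
      if (!is.finite(cl$loss))
        stop(sprintf("non-finite loss at epoch %d (subject '%s')",
                     ep, d$traj$subject_id))
      total <- total + cl$loss
      bk <- .pipeline_backward(model, ms, st, cl$grad)
      # global gradient-norm clip over weights and bandwidths
      gnorm <- sqrt(sum(vapply(bk$gW, function(g) sum(g^2), numeric(1))) +
                      sum(bk$gsigma^2))
      if (is.finite(gnorm) && gnorm > cfg$max_grad_norm) {
        sc <- cfg$max_grad_norm / gnorm
        bk$gW <- lapply(bk$gW, `*`, sc)
        bk$gsigma <- bk$gsigma * sc
      }
      if (!is.null(model)) model <- stiefel_step(model, bk$gW, cfg$lr)
      if (cfg$train_sigma) {
        rho <- rho - cfg$lr * bk$gsigma * (1 / (1 + exp(-rho)))
        rho <- pmax(rho, .softplus_inv(cfg$sigma_floor))
        ms$sigmas <- .softplus(rho)
      }
    }
    history <- c(history, total)
  }
  list(model = model, ms = ms, history = history)
}
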