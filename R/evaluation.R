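# Purity scoring, change-point extraction, spectral-clustering baseline and
# the component ablation harness.

#' Clustering purity against a known schedule
#'
#' \eqn{\frac{1}{T}\sum_{q} \max_{c} |\pi_q \cap c|}: each predicted cluster
#' votes for its majority true class. 1 for a perfect (refinement-free)
#' match; invariant under relabelling of either argument.
#'
#' @param pred predicted labels (integer vector or `state_labeling`).
#' @param truth true labels, same length.
#' @return Purity in `(0, 1]`.
#' @export
purity_score <- function(pred, truth) {
  if (inherits(pred, "state_labeling")) pred <- pred$labels
  if (length(pred) != length(truth)) stop("'pred' and 'truth' length mismatch")
  tab <- table(pred, truth)
  sum(apply(tab, 1, max)) / length(truth)
}

#' Change points of a label sequence
#'
#' Runs shorter than `min_duration` are merged into the preceding run (the
#' leading run, having no predecessor, merges forward), suppressing
#' single-window flicker. The change points are the 0-based indices of the
#' first element of each remaining run after the first.
#'
#' @param labels integer label sequence (one per window).
#' @param min_duration minimum run length kept as a genuine state visit.
#' @return Integer vector of 0-based change positions (empty when constant).
#' @export
extract_change_points <- function(labels, min_duration = 5L) {
  if (!length(labels)) stop("'labels' must be non-empty")
  r <- rle(as.vector(labels))
  repeat {
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_duration)
    if (!length(short)) break
    i <- short[1]
    j <- if (i == 1L) 2L else i - 1L # absorb into neighbour
    r$lengths[j] <- r$lengths[j] + r$lengths[i]
    r$lengths <- r$lengths[-i]
    r$values <- r$values[-i]
    # collapse newly adjacent equal runs
    r <- rle(inverse.rle(r))
  }
  if (length(r$lengths) <= 1L) return(integer(0))
  cumsum(r$lengths)[-length(r$lengths)]
}

#' Spectral clustering of an SPD trajectory
#'
#' Baseline stratification: clusters the matrices with kernel spectral
#' clustering on the affinity \eqn{d = 1/(1+g)} of pairwise log-Euclidean
#' geodesic distances.
#'
#' @param traj an [spd_trajectory()].
#' @param Q number of clusters.
#' @param seed seed for the k-means stage.
#' @return A `state_labeling` (modes are the per-cluster Frechet means).
#' @export
spectral_cluster_states <- function(traj, Q, seed = 1L) {
  stopifnot(inherits(traj, "spd_trajectory"))
  L <- .traj_log_rows(traj)
  A <- pairwise_similarity(sqrt(.row_sqdist(L)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sc <- kernlab::specc(kernlab::as.kernelMatrix(A), centers = Q)
  labels <- as.integer(sc)
  labels <- as.integer(factor(labels, levels = unique(labels)))
  modes <- lapply(seq_len(max(labels)), function(q)
    frechet_mean(traj$matrices[labels == q]))
  structure(list(labels = labels, modes = modes, Q_detected = max(labels),
                 times = traj$times, tol = NA_real_),
            class = "state_labeling")
}

#' Component ablation harness
#'
#' Runs the pipeline on pre-windowed trajectories with either learning stage
#' switched on or off, mirroring the published ablation design:
#' with the SPD network off, raw aligned connectivity feeds the next stage;
#' with the mean-shift recurrence off, kernel spectral clustering (affinity
#' \eqn{1/(1+g)}, `Q` clusters) replaces mode grouping; with both off, the
#' baseline is spectral clustering on the raw aligned connectivity.
#'
#' @param data list with `train` and `test`, each a list of elements carrying
#'   `traj` (an [spd_trajectory()]) and `truth` (per-window labels).
#' @param cfg a [loss_config()] used whenever a stage is trained.
#' @param use_spd_dnn,use_ms_rnn stage switches. With the network off the
#'   mean-shift bandwidths are still trained (on the raw aligned
#'   trajectories); with the mean-shift stage off the network is trained with
#'   the known schedule (the pretext labels) since no grouping exists to
#'   provide self-labels.
#' @param Q number of states assumed by the spectral-clustering fallback.
#' @param dims network layer sizes when the SPD network is on.
#' @param ms initial [msrnn_params()] when the mean-shift stage is on.
#' @param min_size minimum mode support passed to [group_modes()].
#' @return List with per-test-series `purity`, its `mean` and `sd`, and the
#'   test `labelings`.
#' @export
ablation_run <- function(data, cfg = loss_config(), use_spd_dnn = TRUE,
                         use_ms_rnn = TRUE, Q = 4L,
                         dims = NULL, ms = msrnn_params(), min_size = 5L) {
  stopifnot(is.list(data$train), is.list(data$test))
  get_traj <- function(d) if (inherits(d, "spd_trajectory")) d else d$traj
  train_trajs <- lapply(data$train, get_traj)
  al <- align_trajectories(train_trajs)
  pop <- al$population_mean
  align_to_pop <- function(tr) {
    m <- frechet_mean(tr$matrices)
    E <- .transport_operator(m, pop)
    tr$matrices <- lapply(tr$matrices, function(X) .sym(E %*% X %*% t(E)))
    tr
  }
  train <- mapply(function(a, d) list(traj = a, truth = d$truth),
                  al$trajectories, data$train, SIMPLIFY = FALSE)
  test <- lapply(data$test, function(d)
    list(traj = align_to_pop(get_traj(d)), truth = d$truth))

  N <- nrow(train[[1]]$traj$matrices[[1]])
  model <- NULL
  if (use_spd_dnn) {
    if (is.null(dims)) dims <- c(N, 8L, 6L, 4L)
    dims[1] <- N
    model <- spdnet_model(dims, seed = cfg$seed)
  }
  if (use_spd_dnn || use_ms_rnn) {
    fit_cfg <- cfg
    if (!use_ms_rnn) fit_cfg$label_source <- "known_schedule"
    fit <- train_geometric(model, ms, train, fit_cfg)
    model <- fit$model
    if (use_ms_rnn) ms <- fit$ms
  }
  represent <- function(tr) if (use_spd_dnn) spdnet_forward(model, tr) else tr
  stratify <- function(rep_traj) {
    if (use_ms_rnn)
      group_modes(msrnn_forward(ms, rep_traj), tol = cfg$group_tol,
                  min_size = min_size)
    else
      spectral_cluster_states(rep_traj, Q = Q, seed = cfg$seed)
  }
  labelings <- lapply(test, function(d) stratify(represent(d$traj)))
  purity <- mapply(function(lab, d) purity_score(lab, d$truth),
                   labelings, test)
  list(purity = purity, mean = mean(purity), sd = sd(purity),
       labelings = labelings,
       model = model, ms = ms)
}
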