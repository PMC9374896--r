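# Block-modular synthetic BOLD generator: a covariance-driven stand-in for
# SimTB-style state simulations, sufficient because downstream analysis only
# sees the data through windowed correlations.

.default_partitions <- function(n_regions = 10L) {
  # four distinct 3-block partitions obtained by rotating block boundaries
  if (n_regions == 10L) {
    list(
      list(1:3, 4:6, 7:10),
      list(1:4, 5:7, 8:10),
      list(1:2, 3:6, 7:10),
      list(1:3, 4:7, 8:10)
    )
  } else {
    # generic: 4 partitions into 3 contiguous blocks with shifted cuts
    lapply(0:3, function(s) {
      c1 <- max(1L, n_regions %/% 3 + s - 1L)
      c2 <- min(n_regions - 1L, 2L * (n_regions %/% 3) + s)
      list(1:c1, (c1 + 1L):c2, (c2 + 1L):n_regions)
    })
  }
}

#' Simulation design for block-modular brain states
#'
#' Describes a piecewise-stationary multichannel series: `Q` states, each a
#' block-modular correlation template (within-module connectivity 1,
#' cross-module 0, unit diagonal), visited in order for the given durations.
#' The defaults give 10 regions, four states of 100 time points each (state
#' transitions at t = 100, 200, 300) and a window width of 25.
#'
#' @param n_regions number of regions N.
#' @param states list of module partitions, one per state; each partition is a
#'   list of integer index vectors that disjointly cover `1:n_regions`.
#' @param durations per-state segment lengths (time points).
#' @param noise_sd standard deviation of additive white observation noise.
#' @param lambda template/identity mixing weight in (0, 1]: the generating
#'   covariance of a state is `lambda * template + (1 - lambda) * I`.
#' @param window sliding-window width used downstream.
#' @param seed integer seed making the simulation reproducible.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_regions = 10L, states = NULL,
                       durations = rep(100L, 4L), noise_sd = 0.1,
                       lambda = 0.7, window = 25L, seed = 1L) {
  if (is.null(states)) states <- .default_partitions(n_regions)[seq_along(durations)]
  if (length(states) != length(durations))
    stop("'states' and 'durations' must have equal length")
  if (any(durations <= 0)) stop("'durations' must be positive")
  for (p in states) {
    idx <- sort(as.integer(unlist(p)))
    if (!identical(idx, seq_len(as.integer(n_regions))))
      stop("each partition must disjointly cover all regions")
  }
  structure(list(n_regions = as.integer(n_regions), states = states,
                 durations = as.integer(durations), noise_sd = noise_sd,
                 lambda = lambda, window = as.integer(window),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' State correlation templates of a design
#'
#' One binary block matrix per state: 1 within modules (and on the diagonal),
#' 0 across modules. Templates are pairwise distinct by construction of the
#' default partitions.
#'
#' @param design a [sim_design()].
#' @return List of `Q` `n_regions x n_regions` 0/1 matrices.
#' @export
make_state_templates <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  lapply(design$states, function(p) {
    M <- matrix(0, design$n_regions, design$n_regions)
    for (mod in p) M[mod, mod] <- 1
    diag(M) <- 1
    M
  })
}

#' Simulate a piecewise-stationary BOLD-like series
#'
#' Within each state segment, time points are independent draws from a
#' zero-mean multivariate normal with covariance
#' `lambda * ensure_spd(template) + (1 - lambda) * I`, plus additive white
#' noise of standard deviation `noise_sd`. Segments are concatenated in state
#' order, so transitions sit exactly at the cumulative duration boundaries.
#'
#' @param design a [sim_design()].
#' @param seed optional seed overriding `design$seed`.
#' @return List with `series` (a [bold_series()]) and `labels` (integer state
#'   per time point, length `sum(durations)`).
#' @export
simulate_series <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (is.null(seed)) seed <- design$seed
  templates <- make_state_templates(design)
  covs <- lapply(templates, function(Tm)
    design$lambda * ensure_spd(.sym(Tm), 1e-6) +
      (1 - design$lambda) * diag(design$n_regions))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  segs <- vector("list", length(covs))
  for (q in seq_along(covs)) {
    n <- design$durations[q]
    seg <- MASS::mvrnorm(n, mu = rep(0, design$n_regions), Sigma = covs[[q]])
    if (design$noise_sd > 0)
      seg <- seg + matrix(rnorm(length(seg), sd = design$noise_sd), nrow = n)
    segs[[q]] <- seg
  }
  values <- do.call(rbind, segs)
  labels <- rep(seq_along(design$durations), design$durations)
  list(series = bold_series(values, subject_id = sprintf("sim%d", seed)),
       labels = labels)
}

#' Simulate a dataset split into train / validation / test
#'
#' Draws `n_series` independent series from the design (seeds
#' `design$seed + 0:(n_series-1)`) and partitions them, in order, into the
#' three splits.
#'
#' @param design a [sim_design()].
#' @param n_series total number of series.
#' @param split integer vector `(train, validation, test)` summing to
#'   `n_series`.
#' @return List with elements `train`, `validation`, `test`; each a list of
#'   `simulate_series()` results.
#' @export
make_dataset <- function(design, n_series = 2000L,
                         split = c(900L, 100L, 1000L)) {
  if (length(split) != 3L || sum(split) != n_series)
    stop("'split' must be (train, validation, test) summing to 'n_series'")
  sims <- lapply(seq_len(n_series) - 1L,
                 function(i) simulate_series(design, seed = design$seed + i))
  idx <- cumsum(c(0L, split))
  out <- lapply(1:3, function(k)
    if (split[k] > 0) sims[(idx[k] + 1L):idx[k + 1L]] else list())
  names(out) <- c("train", "validation", "test")
  out
}

#' Truth labels at window centres
#'
#' Maps a per-time-point label sequence to per-window labels by reading the
#' label at each window-centre index.
#'
#' @param labels integer label per time point (1-based vector).
#' @param times 0-based window-centre indices (as produced by
#'   [sliding_window_fc()]).
#' @return Integer labels, one per window.
#' @export
window_truth_labels <- function(labels, times) {
  labels[times + 1L]
}
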