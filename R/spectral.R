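# Spectral / shape signatures of learned SPD representations: eigen-spectra,
# system energy, subsample stability, eigenmode perturbation, reconstruction
# of high-dimensional circuits and subnetwork degree shares.

#' Eigen-spectrum of an SPD matrix
#'
#' Descending eigendecomposition (identical to the SVD for SPD matrices),
#' with the sign convention that the first nonzero component of every
#' eigenvector is positive.
#'
#' @param S SPD matrix.
#' @return An object of class `eigen_spectrum` with `values` (descending)
#'   and `vectors` (orthonormal columns).
#' @export
eigen_spectrum <- function(S) {
  .assert_spd(S)
  e <- eigen(.sym(S), symmetric = TRUE)
  U <- e$vectors
  for (j in seq_len(ncol(U))) {
    nz <- which(abs(U[, j]) > 1e-12)[1]
    if (!is.na(nz) && U[nz, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(values = e$values, vectors = U), class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("eigen_spectrum: %d modes, lambda_1 = %.4g .. lambda_%d = %.4g\n",
              length(x$values), x$values[1], length(x$values),
              x$values[length(x$values)]))
  invisible(x)
}

#' System energy of a spectrum
#'
#' The sum of squared eigenvalues, equal to the squared Frobenius norm of the
#' source matrix: a scalar summary of how strongly the system's modes are
#' excited.
#'
#' @param spec an [eigen_spectrum()] (or an SPD matrix).
#' @return Positive scalar.
#' @export
system_energy <- function(spec) {
  if (is.matrix(spec)) spec <- eigen_spectrum(spec)
  sum(spec$values^2)
}

#' Subsample-resampled state energies
#'
#' Per state and iteration: draw a fraction of the state's representation
#' matrices without replacement, take their Frechet mean, and record the mean
#' matrix's system energy. The spread over iterations measures the stability
#' of the state's energy.
#'
#' @param reps named list of states, each a list of at least two SPD
#'   matrices.
#' @param frac subsample fraction (default 0.70; with `frac = 1` every
#'   iteration uses the full set and the energies are constant).
#' @param n_iter number of resampling iterations (default 1000).
#' @param seed integer seed.
#' @param metric metric for the Frechet mean.
#' @return `data.frame` with columns `state`, `iteration`, `energy`.
#' @export
energy_resampling <- function(reps, frac = 0.70, n_iter = 1000L, seed = 1L,
                              metric = "log_euclidean") {
  if (frac <= 0 || frac > 1) stop("'frac' must be in (0, 1]")
  if (is.null(names(reps))) names(reps) <- sprintf("state%d", seq_along(reps))
  bad <- vapply(reps, length, 1L) < 2L
  if (any(bad))
    stop(sprintf("state '%s' has fewer than 2 matrices", names(reps)[bad][1]))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- lapply(names(reps), function(st) {
    mats <- reps[[st]]
    m <- ceiling(frac * length(mats))
    energy <- vapply(seq_len(n_iter), function(it) {
      idx <- sample.int(length(mats), m)
      system_energy(eigen_spectrum(frechet_mean(mats[idx], metric)))
    }, numeric(1))
    data.frame(state = st, iteration = seq_len(n_iter), energy = energy)
  })
  do.call(rbind, out)
}

#' Perturb a single eigenmode
#'
#' Retains eigenpair `i` alone (all other modes nulled) and shifts its
#' eigenvalue by `sign * delta`, returning the rank-one matrix
#' \eqn{(\lambda_i \pm \delta)\, u_i u_i^\top} lifted to SPD by a `1e-8`
#' ridge. A shifted eigenvalue that would become non-positive is floored at
#' `1e-8` with a warning.
#'
#' @param spec an [eigen_spectrum()].
#' @param i mode index (1 = largest eigenvalue).
#' @param delta perturbation magnitude (e.g. the population standard
#'   deviation of eigenvalue `i`).
#' @param sign `+1` or `-1`.
#' @return SPD matrix describing the perturbed mode.
#' @export
perturb_eigenmode <- function(spec, i, delta, sign = 1) {
  stopifnot(inherits(spec, "eigen_spectrum"))
  lam <- spec$values[i] + sign * delta
  if (lam <= 0) {
    warning("perturbed eigenvalue non-positive; floored at 1e-8")
    lam <- 1e-8
  }
  u <- spec$vectors[, i]
  .sym(lam * tcrossprod(u)) + diag(1e-8, length(u))
}

#' Reconstruct the high-dimensional circuit of a low-dimensional mode
#'
#' Inverts the bilinear (BiMap) chain of the network by the Moore-Penrose
#' pseudoinverse of the composite map \eqn{W = W_K \cdots W_1}
#' (rectification layers are skipped): \eqn{\hat X = W^+ V (W^+)^\top}. The
#' result is the symmetric PSD matrix of rank at most `P` whose forward
#' projection reproduces `V` exactly.
#'
#' @param V SPD matrix of the network's output dimension.
#' @param model an [spdnet_model()].
#' @return `N x N` symmetric PSD matrix.
#' @export
reconstruct_highdim <- function(V, model) {
  stopifnot(inherits(model, "spdnet_model"))
  Wc <- Reduce(function(acc, W) W %*% acc, model$W)
  if (nrow(V) != nrow(Wc)) stop("'V' does not match the model output size")
  Wp <- MASS::ginv(Wc)
  .sym(Wp %*% V %*% t(Wp))
}

# top-fraction |off-diagonal| edge set of a symmetric matrix, as an index
# matrix (i < j)
.top_edges <- function(circuit, edge_frac) {
  if (edge_frac <= 0 || edge_frac > 1) stop("'edge_frac' must be in (0, 1]")
  n <- nrow(circuit)
  ut <- which(upper.tri(circuit), arr.ind = TRUE)
  w <- abs(circuit[ut])
  k <- max(1L, ceiling(edge_frac * nrow(ut)))
  keep <- order(w, decreasing = TRUE)[seq_len(k)]
  cbind(ut[keep, , drop = FALSE], weight = circuit[ut[keep, , drop = FALSE]])
}

#' Subnetwork shares of connectivity degree
#'
#' Thresholds the circuit to its top `edge_frac` fraction of off-diagonal
#' absolute weights, counts the incident edges of every node, and reports
#' each subnetwork's share of the total degree (percentages summing to 100).
#'
#' @param circuit `N x N` symmetric matrix (e.g. a reconstructed eigenmode
#'   circuit).
#' @param map subnetwork assignment: named character vector or a
#'   two-column data.frame `(node, subnetwork)` covering every node once.
#' @param edge_frac fraction of strongest edges kept (default 0.05).
#' @return Named numeric vector of percentages, one per subnetwork present in
#'   `map`.
#' @export
subnetwork_degree_share <- function(circuit, map, edge_frac = 0.05) {
  n <- nrow(circuit)
  if (is.data.frame(map)) {
    assign_ <- as.character(map[[2]])[order(as.integer(map[[1]]))]
  } else assign_ <- as.character(map)
  if (length(assign_) != n) stop("'map' must assign every node exactly once")
  edges <- .top_edges(circuit, edge_frac)
  if (!nrow(edges)) stop("empty edge set")
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  tot <- sum(deg)
  shares <- vapply(split(deg, assign_), sum, numeric(1)) / tot * 100
  nets <- unique(assign_)
  out <- shares[nets]
  out[is.na(out)] <- 0
  names(out) <- nets
  out
}

#' Edges shared by two perturbed circuits
#'
#' Intersection of the top-fraction edge sets of the `-delta` and `+delta`
#' perturbation circuits: the connections robust to the perturbation
#' direction.
#'
#' @param c_minus,c_plus symmetric matrices of equal dimension.
#' @param edge_frac fraction of strongest edges kept in each.
#' @return `data.frame` with columns `i`, `j` (node indices, `i < j`).
#' @export
common_circuit <- function(c_minus, c_plus, edge_frac = 0.05) {
  if (!all(dim(c_minus) == dim(c_plus))) stop("shape mismatch")
  e1 <- .top_edges(c_minus, edge_frac)
  e2 <- .top_edges(c_plus, edge_frac)
  k1 <- paste(e1[, 1], e1[, 2])
  k2 <- paste(e2[, 1], e2[, 2])
  keep <- e1[k1 %in% k2, , drop = FALSE]
  data.frame(i = as.integer(keep[, 1]), j = as.integer(keep[, 2]))
}

#' Read a subnetwork map from two-column text
#'
#' @param path file with columns node id and subnetwork name (tab-separated,
#'   with header).
#' @return Named character vector, node order.
#' @export
read_subnetwork_map <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- as.character(x[[2]])[order(as.integer(x[[1]]))]
  names(out) <- sort(as.integer(x[[1]]))
  out
}
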