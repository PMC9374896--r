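#' @useDynLib spdstates, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cov dist hclust cutree kmeans median rnorm runif sd
#' @importFrom utils head read.table write.table
NULL

# ---- internal helpers -------------------------------------------------------

.sym <- function(S) (S + t(S)) / 2

.sym_tol <- 1e-8

.is_symmetric <- function(S, tol = .sym_tol) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) return(FALSE)
  scale <- max(abs(S), 1)
  max(abs(S - t(S))) <= tol * scale
}

# Ridge-lift nearly singular inputs before matrix functions so that log/inverse
# stay finite; the lift is tiny relative to the matrix scale.
.ridge_lift <- function(S, warn = TRUE) {
  n <- nrow(S)
  ev_min <- min(eigen(.sym(S), symmetric = TRUE, only.values = TRUE)$values)
  thr <- 1e-12 * sum(diag(S)) / n
  if (ev_min <= thr) {
    if (warn) warning("near-singular SPD input; applying ridge lift")
    S <- S + diag(1e-10 * sum(diag(S)) / n, n)
  }
  S
}

.assert_spd <- function(S, arg = "S") {
  if (!.is_symmetric(S))
    stop(sprintf("'%s' must be a symmetric square matrix", arg))
  ev <- eigen(.sym(S), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("'%s' is not positive definite (min eigenvalue %.3e)",
                 arg, min(ev)))
  invisible(TRUE)
}

# Apply a scalar function to the spectrum: U f(Lambda) U'.
.spd_fun <- function(S, f) {
  e <- eigen(.sym(S), symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

#' Matrix logarithm of an SPD matrix
#'
#' Computes \eqn{\log S = U \log(\Lambda) U^\top} from the eigendecomposition
#' of a symmetric positive-definite matrix. This is the chart map of the
#' log-Euclidean geometry: distances between SPD matrices become Frobenius
#' distances between their logarithms.
#'
#' @param S symmetric positive-definite matrix.
#' @return A symmetric matrix \code{L} with \code{spd_expm(L)} equal to
#'   \code{S}.
#' @seealso [spd_expm()], [geodesic_distance()]
#' @export
spd_logm <- function(S) {
  if (!.is_symmetric(S)) stop("'S' must be symmetric")
  S <- .ridge_lift(S, warn = FALSE)
  .assert_spd(S)
  .sym(.spd_fun(S, log))
}

#' Matrix exponential of a symmetric matrix
#'
#' Inverse of [spd_logm()]: maps a tangent-space (log-chart) symmetric matrix
#' back to the SPD manifold.
#'
#' @param L symmetric matrix.
#' @return An SPD matrix.
#' @export
spd_expm <- function(L) {
  if (!.is_symmetric(L)) stop("'L' must be symmetric")
  .sym(.spd_fun(L, exp))
}

# principal square root / inverse square root
.spd_sqrtm <- function(S) .sym(.spd_fun(S, sqrt))
.spd_isqrtm <- function(S) .sym(.spd_fun(S, function(x) 1 / sqrt(x)))

#' Geodesic distance between SPD matrices
#'
#' Log-Euclidean distance \eqn{\|\log A - \log B\|_F} (default), or the
#' affine-invariant distance \eqn{\|\log(A^{-1/2} B A^{-1/2})\|_F}.
#'
#' @param A,B SPD matrices of equal dimension.
#' @param metric `"log_euclidean"` (default) or `"affine_invariant"`.
#' @return Non-negative scalar; zero iff `A == B`.
#' @export
geodesic_distance <- function(A, B,
                              metric = c("log_euclidean", "affine_invariant")) {
  metric <- match.arg(metric)
  if (!all(dim(A) == dim(B))) stop("dimension mismatch between 'A' and 'B'")
  if (metric == "log_euclidean") {
    sqrt(sum((spd_logm(A) - spd_logm(B))^2))
  } else {
    iA <- .spd_isqrtm(.ridge_lift(A, warn = FALSE))
    sqrt(sum(spd_logm(.sym(iA %*% B %*% iA))^2))
  }
}

#' Frechet (Karcher) mean of SPD matrices
#'
#' The point minimising the sum of squared geodesic distances to a set of SPD
#' matrices. Under the log-Euclidean metric the minimiser is closed form,
#' \eqn{\exp(\frac1n \sum_i \log S_i)}; under the affine-invariant metric it
#' is found by Karcher fixed-point iteration (unit step, gradient equal to the
#' mean of the logs at the current point).
#'
#' @param matrices non-empty list of SPD matrices of equal dimension.
#' @param metric `"log_euclidean"` or `"affine_invariant"`.
#' @param tol convergence tolerance on the gradient norm (affine-invariant).
#' @param max_iter iteration cap (affine-invariant); on hitting it a warning
#'   is issued and the last iterate returned.
#' @return An SPD matrix.
#' @export
frechet_mean <- function(matrices,
                         metric = c("log_euclidean", "affine_invariant"),
                         tol = 1e-8, max_iter = 100) {
  metric <- match.arg(metric)
  if (!length(matrices)) stop("'matrices' must be a non-empty list")
  d <- vapply(matrices, nrow, 1L)
  if (length(unique(d)) != 1L) stop("all matrices must share a dimension")
  if (metric == "log_euclidean") {
    logs <- lapply(matrices, spd_logm)
    return(spd_expm(Reduce(`+`, logs) / length(logs)))
  }
  M <- matrices[[1]]
  for (it in seq_len(max_iter)) {
    iM <- .spd_isqrtm(M)
    sM <- .spd_sqrtm(M)
    G <- Reduce(`+`, lapply(matrices, function(S)
      spd_logm(.sym(iM %*% S %*% iM)))) / length(matrices)
    M <- .sym(sM %*% spd_expm(G) %*% sM)
    if (sqrt(sum(G^2)) < tol) return(M)
  }
  warning("Karcher iteration did not converge; returning last iterate")
  M
}

#' Parallel transport of an SPD matrix between base points
#'
#' Moves `X` from the neighbourhood of `source_mean` to that of `target_mean`
#' by the congruence \eqn{E X E^\top} with
#' \eqn{E = (\mathrm{target} \cdot \mathrm{source}^{-1})^{1/2}} (principal
#' square root). This is the standard SPD domain-adaptation transport: it
#' maps the source base point exactly onto the target one and preserves
#' affine-invariant geometry within the transported set.
#'
#' @param X SPD matrix to transport.
#' @param source_mean,target_mean SPD base points (e.g. subject and
#'   population Frechet means).
#' @return The transported SPD matrix.
#' @export
parallel_transport <- function(X, source_mean, target_mean) {
  .assert_spd(source_mean, "source_mean")
  .assert_spd(target_mean, "target_mean")
  if (!all(dim(X) == dim(source_mean)) ||
      !all(dim(X) == dim(target_mean)))
    stop("dimension mismatch")
  E <- .transport_operator(source_mean, target_mean)
  .sym(E %*% X %*% t(E))
}

# E = (T S^-1)^{1/2} via the SPD-similar form S^{1/2} (S^{-1/2} T S^{-1/2})^{1/2} S^{-1/2}
.transport_operator <- function(source_mean, target_mean) {
  sS <- .spd_sqrtm(source_mean)
  iS <- .spd_isqrtm(source_mean)
  sS %*% .spd_sqrtm(.sym(iS %*% target_mean %*% iS)) %*% iS
}

#' Trajectory of SPD matrices
#'
#' A time-ordered sequence of equal-dimension SPD matrices with window-centre
#' time indices, representing one subject's dynamic connectivity.
#'
#' @param matrices list of SPD matrices of equal dimension.
#' @param times integer window-centre indices, strictly increasing; defaults
#'   to `0:(length(matrices)-1)`.
#' @param subject_id identifier string.
#' @param validate check SPD-ness of every matrix (set `FALSE` for trusted
#'   internal construction).
#' @return An object of class `spd_trajectory` with fields `matrices`,
#'   `times`, `subject_id`.
#' @export
spd_trajectory <- function(matrices, times = NULL, subject_id = "subj",
                           validate = TRUE) {
  if (!length(matrices)) stop("'matrices' must be non-empty")
  d <- vapply(matrices, nrow, 1L)
  if (length(unique(d)) != 1L) stop("all matrices must share a dimension")
  if (is.null(times)) times <- seq_along(matrices) - 1L
  times <- as.integer(times)
  if (length(times) != length(matrices)) stop("'times' length mismatch")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (validate) for (i in seq_along(matrices)) .assert_spd(matrices[[i]])
  structure(list(matrices = matrices, times = times, subject_id = subject_id),
            class = "spd_trajectory")
}

#' @export
length.spd_trajectory <- function(x) length(x$matrices)

#' @export
print.spd_trajectory <- function(x, ...) {
  cat(sprintf("spd_trajectory '%s': %d matrices of dim %d, t = %d..%d\n",
              x$subject_id, length(x$matrices), nrow(x$matrices[[1]]),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Align SPD trajectories to a common population mean
#'
#' Removes between-subject offsets in three steps: (1) the Frechet mean of
#' each subject's trajectory, (2) the population Frechet mean of the subject
#' means, (3) parallel transport of every matrix from its subject mean to the
#' population mean. After alignment all subject means coincide with the
#' population mean, leaving only within-trajectory (state-related) variation.
#'
#' @param trajs list of [spd_trajectory()] objects of equal matrix dimension.
#' @param metric metric for the Frechet means, see [frechet_mean()].
#' @param passes number of alignment sweeps (the procedure may be iterated;
#'   one pass is the default and is idempotent up to numerical error).
#' @return List with `trajectories` (aligned) and `population_mean`.
#' @export
align_trajectories <- function(trajs,
                               metric = c("log_euclidean", "affine_invariant"),
                               passes = 1L) {
  metric <- match.arg(metric)
  if (!length(trajs)) stop("need at least one trajectory")
  pop <- NULL
  for (p in seq_len(passes)) {
    subj_means <- lapply(trajs, function(tr) frechet_mean(tr$matrices, metric))
    pop <- frechet_mean(subj_means, metric)
    trajs <- mapply(function(tr, m) {
      E <- .transport_operator(m, pop)
      tr$matrices <- lapply(tr$matrices, function(X) .sym(E %*% X %*% t(E)))
      tr
    }, trajs, subj_means, SIMPLIFY = FALSE)
  }
  list(trajectories = trajs, population_mean = pop)
}

# ---- serialization ----------------------------------------------------------

#' Read / write SPD matrices as tab-separated text
#'
#' Full square matrices, tab-separated, no row or column names.
#'
#' @param S matrix to write.
#' @param path file path.
#' @return `read_spd_matrix` returns the matrix; `write_spd_matrix` its path,
#'   invisibly.
#' @export
write_spd_matrix <- function(S, path) {
  write.table(S, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spd_matrix
#' @export
read_spd_matrix <- function(path) {
  x <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(x) <- NULL
  x
}
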