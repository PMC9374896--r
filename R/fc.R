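# Sliding-window functional connectivity construction.

#' Multichannel BOLD-like series
#'
#' Container for a T x N matrix of regional time courses.
#'
#' @param values numeric matrix, rows = time points, columns = regions; no
#'   missing values allowed.
#' @param region_ids optional character vector of region names.
#' @param subject_id identifier string.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(values, region_ids = NULL, subject_id = "subj") {
  values <- as.matrix(values)
  if (anyNA(values)) stop("'values' must not contain missing values")
  if (is.null(region_ids)) {
    region_ids <- colnames(values)
    if (is.null(region_ids)) region_ids <- sprintf("R%d", seq_len(ncol(values)))
  }
  if (length(region_ids) != ncol(values)) stop("'region_ids' length mismatch")
  colnames(values) <- region_ids
  structure(list(values = values, region_ids = region_ids,
                 subject_id = subject_id),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("bold_series '%s': %d time points x %d regions\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a BOLD series from delimited text
#'
#' Rows are time points, columns are regions; an optional header row carries
#' region names.
#'
#' @param path file path (tab- or whitespace-delimited).
#' @param header whether the first row holds region names.
#' @param subject_id identifier for the returned series.
#' @return A [bold_series()] object.
#' @export
read_bold_series <- function(path, header = TRUE, subject_id = NULL) {
  x <- read.table(path, header = header, sep = "\t", check.names = FALSE)
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  bold_series(as.matrix(x), subject_id = subject_id)
}

#' Write a BOLD series to delimited text
#' @param series a [bold_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bold_series <- function(series, path) {
  write.table(series$values, path, sep = "\t", row.names = FALSE,
              col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Clip a symmetric matrix onto the SPD cone
#'
#' Eigenvalues below `floor` are raised to `floor`, leaving eigenvectors
#' untouched. Short correlation windows (width below the number of regions)
#' yield rank-deficient matrices; this restores strict positive-definiteness.
#'
#' @param C symmetric matrix.
#' @param floor positive eigenvalue floor.
#' @return An SPD matrix; `C` unchanged when its spectrum already clears the
#'   floor.
#' @export
ensure_spd <- function(C, floor = 1e-6) {
  if (!.is_symmetric(C)) stop("'C' must be symmetric")
  if (floor <= 0) stop("'floor' must be positive")
  e <- eigen(.sym(C), symmetric = TRUE)
  if (min(e$values) >= floor) return(C)
  .sym(e$vectors %*% (pmax(e$values, floor) * t(e$vectors)))
}

#' Sliding-window Pearson connectivity trajectory
#'
#' Computes the Pearson correlation matrix of the series inside each sliding
#' window and returns the sequence as an SPD trajectory. Windows are centred:
#' with 0-based time and width `w`, window `i` covers rows
#' `[i, i+w-1]` and is indexed by its centre `i + floor(w/2)`, producing
#' exactly `T - w + 1` matrices at stride 1. Each correlation matrix is
#' regularised by [ensure_spd()] so the trajectory lives strictly inside the
#' SPD cone.
#'
#' @param series a [bold_series()].
#' @param window positive window width (time points), at most the series
#'   length.
#' @param stride step between window starts (default 1, the every-time-point
#'   convention).
#' @param floor eigenvalue floor passed to [ensure_spd()].
#' @return An [spd_trajectory()] whose `times` are 0-based window centres.
#' @export
sliding_window_fc <- function(series, window, stride = 1L, floor = 1e-6) {
  stopifnot(inherits(series, "bold_series"))
  x <- series$values
  T_ <- nrow(x)
  if (window < 2 || window > T_) stop("'window' must be in [2, T]")
  starts <- seq.int(1L, T_ - window + 1L, by = stride)
  mats <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + window - 1L), , drop = FALSE]
    sds <- apply(seg, 2, sd)
    if (any(sds == 0)) {
      bad <- which(sds == 0)[1]
      stop(sprintf("zero-variance region '%s' in window starting at t=%d",
                   series$region_ids[bad], starts[k] - 1L))
    }
    C <- cor(seg)
    mats[[k]] <- ensure_spd(.sym(C), floor)
  }
  centres <- (starts - 1L) + window %/% 2L
  spd_trajectory(mats, times = centres, subject_id = series$subject_id,
                 validate = FALSE)
}
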