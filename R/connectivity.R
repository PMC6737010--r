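# ROI time series -> masked Fisher-z connectivity matrix.

#' Construct an ROI time-series object
#'
#' @param data Numeric T x N matrix of BOLD amplitudes, one column per ROI;
#'   column names are ROI ids.
#' @param subject_id Subject identifier.
#' @param tr_seconds Sampling interval in seconds (default 2).
#' @param scrub_fraction Fraction of volumes removed by motion scrubbing,
#'   in [0, 1). Subjects with 0.30 or more are excluded from analysis.
#' @return A `roi_timeseries` object.
#' @export
time_series <- function(data, subject_id = "subj", tr_seconds = 2,
                        scrub_fraction = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time series must be numeric")
  if (nrow(data) < 3L) stop("time series needs at least 3 volumes")
  if (anyNA(data)) stop("time series contains missing values")
  if (scrub_fraction < 0 || scrub_fraction >= 1)
    stop("scrub_fraction must be in [0, 1)")
  if (is.null(colnames(data))) colnames(data) <- as.character(seq_len(ncol(data)))
  structure(list(data = data, subject_id = as.character(subject_id),
                 tr_seconds = tr_seconds, scrub_fraction = scrub_fraction),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("roi_timeseries '%s': %d volumes x %d ROIs (TR %gs, scrub %.1f%%)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds,
              100 * x$scrub_fraction))
  invisible(x)
}

#' Pearson correlation matrix of ROI time series
#'
#' @param ts A `roi_timeseries` or a numeric T x N matrix.
#' @return N x N symmetric Pearson correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  x <- if (inherits(ts, "roi_timeseries")) ts$data else as.matrix(ts)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    stop("constant time series for ROI(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(x)
  # guard against fp drift outside [-1, 1]
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Fisher z transform of a correlation matrix
#'
#' Elementwise `atanh(r)`, variance-stabilizing; the unit of all correlation
#' weight metrics in the pipeline. The diagonal (r = 1) is passed through as
#' `Inf` and must be removed by masking before any averaging; off-diagonal
#' cells with |r| = 1 indicate degenerate data and raise an error.
#'
#' @param r Correlation matrix (or any numeric array of correlations).
#' @return Matrix of Fisher z values.
#' @export
fisher_transform <- function(r) {
  off <- r
  if (is.matrix(off) && nrow(off) == ncol(off)) diag(off) <- 0
  if (any(abs(off) >= 1, na.rm = TRUE))
    stop("|r| = 1 off the diagonal: degenerate time series")
  atanh(r)
}

#' Apply diagonal and proximity masks to a Fisher-z matrix
#'
#' One stored object serves both analysis conventions: masked cells are
#' flagged, never replaced by a sentinel value. [conn_na_view()] returns the
#' matrix with masked cells as `NA` (for averaging); [conn_zero_view()]
#' returns them as 0 (for graph construction).
#'
#' @param z N x N Fisher-z matrix (symmetric; diagonal may be `Inf`).
#' @param pairs Two-column integer matrix of proximity-excluded ROI pairs,
#'   as from [proximity_exclusion_pairs()]; may have zero rows.
#' @param node_ids Integer ROI ids labelling rows/columns of `z`
#'   (default `1:N`, or integer column names of `z` if present).
#' @return A `connectivity_matrix` with fields `z`, `mask` (TRUE = excluded)
#'   and `node_ids`.
#' @export
apply_masks <- function(z, pairs = NULL, node_ids = NULL) {
  z <- as.matrix(z)
  n <- nrow(z)
  stopifnot(ncol(z) == n)
  if (is.null(node_ids)) {
    node_ids <- if (!is.null(colnames(z)) &&
                    !anyNA(suppressWarnings(as.integer(colnames(z)))))
      as.integer(colnames(z)) else seq_len(n)
  }
  stopifnot(length(node_ids) == n, !anyDuplicated(node_ids))
  mask <- diag(TRUE, n)
  if (!is.null(pairs) && NROW(pairs) > 0L) {
    pairs <- as.matrix(pairs)
    pos_i <- match(pairs[, 1], node_ids)
    pos_j <- match(pairs[, 2], node_ids)
    if (anyNA(pos_i) || anyNA(pos_j))
      stop("proximity pair references unknown node id")
    mask[cbind(pos_i, pos_j)] <- TRUE
    mask[cbind(pos_j, pos_i)] <- TRUE
  }
  dimnames(z) <- list(node_ids, node_ids)
  structure(list(z = z, mask = mask, node_ids = as.integer(node_ids)),
            class = "connectivity_matrix")
}

#' Masked view for averaging: excluded cells as `NA`
#' @param C A `connectivity_matrix`.
#' @return N x N matrix with masked cells set to `NA`.
#' @export
conn_na_view <- function(C) {
  stopifnot(inherits(C, "connectivity_matrix"))
  out <- C$z
  out[C$mask] <- NA_real_
  out
}

#' Masked view for graph construction: excluded cells as 0
#' @param C A `connectivity_matrix`.
#' @return N x N matrix with masked cells set to 0.
#' @export
conn_zero_view <- function(C) {
  stopifnot(inherits(C, "connectivity_matrix"))
  out <- C$z
  out[C$mask] <- 0
  out
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d nodes, %d masked cells\n",
              nrow(x$z), sum(x$mask)))
  invisible(x)
}

#' Full pipeline from one time series to a masked connectivity matrix
#'
#' Convenience wrapper: Pearson correlation, Fisher z, masking.
#'
#' @inheritParams correlation_matrix
#' @inheritParams apply_masks
#' @return A `connectivity_matrix`.
#' @export
connectivity_from_timeseries <- function(ts, pairs = NULL, node_ids = NULL) {
  r <- correlation_matrix(ts)
  diag(r) <- 0                       # diagonal is masked; keep z finite
  z <- fisher_transform(r)
  C <- apply_masks(z, pairs = pairs, node_ids = node_ids)
  C
}
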