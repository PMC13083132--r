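#' Motion-based quality-control decision
#'
#' A subject x run is excluded when at least `max_fraction` of its volumes
#' exceed the framewise-displacement threshold. The boundary is inclusive:
#' exactly 20% of high-motion volumes excludes.
#'
#' @param trace an [fd_trace()].
#' @param fd_threshold displacement threshold in mm.
#' @param max_fraction maximum tolerated fraction of high-motion volumes.
#' @return list with `exclude` (logical) and `proportion`.
#' @export
qc_exclude <- function(trace, fd_threshold = 0.5, max_fraction = 0.20) {
  stopifnot(inherits(trace, "fd_trace"))
  prop <- mean(trace$fd > fd_threshold)
  list(exclude = prop >= max_fraction, proportion = prop)
}

#' Pairwise Pearson correlation matrix of ROI signals
#'
#' @param ts a [roi_timeseries()].
#' @return symmetric R x R correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  sds <- apply(ts$data, 1L, stats::sd)
  flat <- which(sds == 0)
  if (length(flat))
    stop_fmt("constant signal in ROI(s): %s",
             paste(rownames(ts$data)[utils::head(flat, 5L)], collapse = ", "))
  r <- stats::cor(t(ts$data))
  # guard against tiny asymmetries from floating point
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Fisher r-to-z transform
#'
#' Elementwise `atanh` with |r| clipped at `1 - 1e-7` so that duplicate
#' series do not produce infinities; the diagonal is zeroed.
#'
#' @param r correlation matrix (or vector), |r| <= 1.
#' @return z-transformed matrix with zero diagonal.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12))
    stop_fmt("fisher_z input must be finite with |r| <= 1")
  z <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
  if (is.matrix(z) && nrow(z) == ncol(z)) diag(z) <- 0
  z
}

#' Percentile-threshold a z matrix into a sparse weighted graph
#'
#' The cutoff is the linear-interpolation percentile (quantile type 7) of
#' the absolute off-diagonal values; entries with |z| >= cutoff keep their
#' signed value (set `signed = FALSE` to keep magnitudes), the rest are
#' zeroed. At the default 85th percentile roughly 15% of edges survive.
#'
#' @param z symmetric matrix with zero diagonal (see [fisher_z()]).
#' @param percentile percentile of |z| defining the cutoff.
#' @param subject_id,group,condition optional metadata carried on the graph.
#' @param signed keep the sign of retained weights (default) or store |z|.
#' @return an object of class `connectome_graph`: `weights` (sparse
#'   symmetric matrix), `cutoff`, `retained_fraction`, plus metadata.
#' @export
threshold_sparsify <- function(z, percentile = 85, subject_id = NA_character_,
                               group = NA_character_, condition = NA_character_,
                               signed = TRUE) {
  z <- as.matrix(z)
  R <- nrow(z)
  if (R < 3L) stop_fmt("need at least 3 nodes, got %d", R)
  if (!isTRUE(all.equal(z, t(z), tolerance = 1e-10)))
    stop_fmt("z matrix must be symmetric")
  if (any(diag(z) != 0)) stop_fmt("z matrix must have zero diagonal")
  off <- abs(z[row(z) != col(z)])
  cutoff <- unname(stats::quantile(off, percentile / 100, type = 7))
  w <- z
  w[abs(z) < cutoff] <- 0
  if (!signed) w <- abs(w)
  diag(w) <- 0
  ut <- upper.tri(w)
  structure(list(subject_id = subject_id, group = group, condition = condition,
                 weights = w, cutoff = cutoff,
                 retained_fraction = mean(w[ut] != 0)),
            class = "connectome_graph")
}

#' @export
print.connectome_graph <- function(x, ...) {
  cat(sprintf(
    "connectome_graph: %s [%s, %s] %d nodes, %.1f%% edges retained (cutoff %.4f)\n",
    x$subject_id, x$group, x$condition, nrow(x$weights),
    100 * x$retained_fraction, x$cutoff))
  invisible(x)
}

#' Build a connectome graph from a ROI time series
#'
#' Convenience composition: Pearson correlation, Fisher r-to-z, percentile
#' thresholding, carrying the subject metadata through.
#'
#' @inheritParams pearson_matrix
#' @inheritParams threshold_sparsify
#' @return a `connectome_graph`.
#' @export
build_connectome <- function(ts, percentile = 85, signed = TRUE) {
  threshold_sparsify(fisher_z(pearson_matrix(ts)), percentile = percentile,
                     subject_id = ts$subject_id, group = ts$group,
                     condition = ts$condition, signed = signed)
}
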