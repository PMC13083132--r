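#' Min-max normalize the clinical table to the unit interval
#'
#' Applies listwise deletion first (any subject with a missing feature is
#' dropped), then scales each feature by `(x - x_min)/(x_max - x_min)`.
#' Symptom columns use their theoretical 0-5 scale bounds by default;
#' cognitive columns use the observed complete-case range. Per-column
#' bounds can be overridden.
#'
#' @param table clinical data.frame (see [read_clinical_table()]).
#' @param bounds optional named list of `c(min, max)` per column,
#'   overriding the defaults.
#' @param feature_cols feature columns to use (default: all 20).
#' @return list of class `normalized_clinical`: `data` (complete-case
#'   normalized matrix with subject ids as rownames), `groups`,
#'   `bounds_used`, `dropped` (subject ids removed by listwise deletion).
#' @export
minmax_normalize <- function(table, bounds = list(),
                             feature_cols = clinical_feature_columns()) {
  miss <- setdiff(feature_cols, names(table))
  if (length(miss))
    stop_fmt("missing feature column(s): %s", paste(miss, collapse = ", "))
  X <- as.matrix(table[, feature_cols, drop = FALSE])
  keep <- stats::complete.cases(X)
  dropped <- table$subject_id[!keep]
  X <- X[keep, , drop = FALSE]
  if (!nrow(X)) stop_fmt("no complete cases after listwise deletion")
  used <- list()
  for (j in seq_along(feature_cols)) {
    col <- feature_cols[j]
    b <- bounds[[col]]
    if (is.null(b)) {
      b <- if (col %in% SYMPTOM_COLUMNS) c(0, 5) else range(X[, j])
    }
    if (b[2] <= b[1])
      stop_fmt("degenerate bounds for column '%s' (constant column?)", col)
    X[, j] <- (X[, j] - b[1]) / (b[2] - b[1])
    used[[col]] <- b
  }
  if (any(X < -1e-9 | X > 1 + 1e-9))
    stop_fmt("values outside declared bounds after normalization")
  X <- pmin(pmax(X, 0), 1)
  rownames(X) <- table$subject_id[keep]
  structure(list(data = X, groups = table$group[keep], bounds_used = used,
                 dropped = dropped),
            class = "normalized_clinical")
}

#' Partitioning Around Medoids
#'
#' k-medoids clustering on Euclidean dissimilarity, deterministic for
#' fixed input. Tiny instances (at most `exact_limit` candidate medoid
#' sets) are solved exactly by enumeration; larger ones use BUILD + SWAP
#' to a local optimum. SWAP alone can stall in a local optimum even for a
#' handful of points, so exact enumeration where it is affordable keeps
#' the small-sample behavior canonical.
#'
#' @param points n x p numeric matrix, or a `dist` object.
#' @param k number of clusters (`k <= n`; `k = n` returns each point as
#'   its own medoid).
#' @param exact_limit maximum number of medoid subsets enumerated before
#'   falling back to BUILD + SWAP.
#' @return list with `labels` (integer vector) and `medoids` (row indices).
#' @export
pam_cluster <- function(points, k, exact_limit = 150) {
  n <- if (inherits(points, "dist")) attr(points, "Size") else nrow(points)
  if (k > n) stop_fmt("k = %d > n = %d", k, n)
  if (k == n)
    return(list(labels = seq_len(n), medoids = seq_len(n)))
  if (choose(n, k) <= exact_limit) {
    d <- as.matrix(if (inherits(points, "dist")) points else
      stats::dist(points))
    best_cost <- Inf; best <- NULL
    for (med in utils::combn(n, k, simplify = FALSE)) {
      cost <- sum(apply(d[, med, drop = FALSE], 1L, min))
      if (cost < best_cost - 1e-12) { best_cost <- cost; best <- med }
    }
    labels <- apply(d[, best, drop = FALSE], 1L, which.min)
    return(list(labels = as.integer(labels), medoids = best))
  }
  fit <- cluster::pam(points, k = k, metric = "euclidean",
                      keep.diss = FALSE, keep.data = FALSE)
  list(labels = unname(fit$clustering),
       medoids = unname(fit$id.med))
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of defined off-diagonal consensus entries lying strictly
#' inside the ambiguity band `(lower, upper)`. Lower PAC means a more
#' stable partition.
#'
#' @param consensus symmetric consensus matrix (NA = never co-sampled).
#' @param lower,upper ambiguity band.
#' @return PAC in \[0, 1\].
#' @export
pac <- function(consensus, lower = 0.1, upper = 0.9) {
  v <- consensus[upper.tri(consensus)]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v > lower & v < upper)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion,
#' `(SSB/(k-1)) / (SSW/(n-k))`; larger is better separated.
#'
#' @param points n x p matrix.
#' @param labels cluster assignment.
#' @return scalar index.
#' @export
calinski_harabasz <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  ks <- unique(labels)
  k <- length(ks)
  if (k < 2L || k >= n) stop_fmt("need 2 <= k < n")
  grand <- colMeans(points)
  ssb <- 0; ssw <- 0
  for (g in ks) {
    idx <- labels == g
    ctr <- colMeans(points[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * sum((ctr - grand)^2)
    ssw <- ssw + sum(sweep(points[idx, , drop = FALSE], 2, ctr)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Pairwise Jaccard similarity of two partitions
#'
#' Subject pairs co-clustered in both partitions divided by pairs
#' co-clustered in at least one, computed from the contingency table.
#'
#' @param l1,l2 label vectors over the same subjects.
#' @return Jaccard similarity in \[0, 1\] (1 when neither partition
#'   co-clusters any pair).
#' @export
jaccard_partitions <- function(l1, l2) {
  stopifnot(length(l1) == length(l2))
  pair_concordance(l1, l2)$jaccard
}

#' @keywords internal
#' @noRd
pair_concordance <- function(l1, l2) {
  # adjusted Rand and pairwise Jaccard from one contingency table
  n <- length(l1)
  if (n < 2L) return(list(ari = NA_real_, jaccard = NA_real_))
  f1 <- as.integer(factor(l1)); f2 <- as.integer(factor(l2))
  k1 <- max(f1); k2 <- max(f2)
  tab <- matrix(tabulate((f1 - 1L) * k2 + f2, nbins = k1 * k2),
                k1, k2, byrow = TRUE)
  ch2 <- function(x) sum(x * (x - 1) / 2)
  t11 <- ch2(tab)                 # together in both
  t1 <- ch2(rowSums(tab))         # together in partition 1
  t2 <- ch2(colSums(tab))         # together in partition 2
  ntot <- n * (n - 1) / 2
  exp11 <- t1 * t2 / ntot
  maxi <- (t1 + t2) / 2
  ari <- if (maxi == exp11) 1 else (t11 - exp11) / (maxi - exp11)
  jac <- if (t1 + t2 - t11 == 0) 1 else t11 / (t1 + t2 - t11)
  list(ari = ari, jaccard = jac)
}

#' Consensus clustering with PAM
#'
#' Repeatedly subsamples subjects without replacement, optionally embeds
#' the subsample, partitions it with PAM, and aggregates co-assignment
#' frequencies into an n x n consensus matrix (co-assignments divided by
#' co-sampling counts). Final labels come from PAM on the `1 - consensus`
#' dissimilarity. Deterministic given `seed`.
#'
#' @param points n x p normalized feature matrix.
#' @param k number of clusters.
#' @param iterations subsampling iterations.
#' @param subsample fraction of subjects drawn per iteration.
#' @param embedding optional function `matrix -> matrix` applied to each
#'   subsample before PAM (identity by default; an external
#'   dimensionality-reduction step can be plugged in here).
#' @param seed integer seed.
#' @return list of class `cluster_solution`: `k`, `labels`, `medoids`,
#'   `consensus`, `iteration_labels` (list of named label vectors),
#'   `metrics` (filled by [stability_metrics()]), `seed`.
#' @export
consensus_cluster <- function(points, k, iterations = 100, subsample = 0.8,
                              embedding = NULL, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  m <- max(2L, floor(subsample * n))
  if (m <= k) stop_fmt("subsample size %d must exceed k = %d", m, k)
  if (is.null(embedding)) embedding <- identity
  co_count <- matrix(0, n, n)
  co_same <- matrix(0, n, n)
  iter_labels <- vector("list", iterations)
  withr::with_seed(seed, {
    for (it in seq_len(iterations)) {
      idx <- sort(sample.int(n, m))
      emb <- embedding(points[idx, , drop = FALSE])
      lab <- pam_cluster(emb, k)$labels
      iter_labels[[it]] <- stats::setNames(lab, idx)
      same <- outer(lab, lab, "==")
      co_count[idx, idx] <- co_count[idx, idx] + 1
      co_same[idx, idx] <- co_same[idx, idx] + same
    }
  })
  consensus <- co_same / co_count
  consensus[co_count == 0] <- NA
  diag(consensus) <- 1
  undefined <- sum(is.na(consensus[upper.tri(consensus)]))
  if (undefined > 0)
    message(sprintf("%d subject pair(s) never co-sampled; excluded from PAC",
                    undefined))
  dmat <- 1 - consensus
  dmat[is.na(dmat)] <- 0.5  # uninformative midpoint for never co-sampled pairs
  diag(dmat) <- 0
  fit <- pam_cluster(stats::as.dist(dmat), k)
  sol <- structure(list(k = k, labels = fit$labels, medoids = fit$medoids,
                        consensus = consensus, iteration_labels = iter_labels,
                        metrics = NULL, seed = seed),
                   class = "cluster_solution")
  sol$metrics <- stability_metrics(sol, points)
  sol
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: k = %d, n = %d\n", x$k, length(x$labels)))
  if (!is.null(x$metrics))
    cat(sprintf("  PAC %.3f | silhouette %.3f | CH %.1f | ARI %.3f | Jaccard %.3f\n",
                x$metrics$pac, x$metrics$silhouette,
                x$metrics$calinski_harabasz, x$metrics$mean_ari,
                x$metrics$mean_jaccard))
  invisible(x)
}

#' Stability metrics of a consensus solution
#'
#' PAC of the consensus matrix; mean silhouette width and
#' Calinski-Harabasz of the final labels in the normalized feature space;
#' mean pairwise adjusted Rand and Jaccard over iteration partitions
#' restricted to their shared subjects.
#'
#' @param solution a `cluster_solution`.
#' @param points the feature matrix that was clustered.
#' @return list with `pac`, `silhouette`, `calinski_harabasz`, `mean_ari`,
#'   `mean_jaccard`.
#' @export
stability_metrics <- function(solution, points) {
  if (solution$k < 2L) stop_fmt("silhouette undefined for k = 1")
  points <- as.matrix(points)
  sil <- cluster::silhouette(solution$labels, stats::dist(points))
  labs <- solution$iteration_labels
  nit <- length(labs)
  aris <- c(); jacs <- c()
  if (nit >= 2L) {
    pairs <- utils::combn(nit, 2L)
    aris <- numeric(ncol(pairs)); jacs <- numeric(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      l1 <- labs[[pairs[1L, p]]]; l2 <- labs[[pairs[2L, p]]]
      shared <- intersect(names(l1), names(l2))
      if (length(shared) < 2L) { aris[p] <- NA; jacs[p] <- NA; next }
      pc <- pair_concordance(l1[shared], l2[shared])
      aris[p] <- pc$ari; jacs[p] <- pc$jaccard
    }
  }
  list(pac = pac(solution$consensus),
       silhouette = mean(sil[, "sil_width"]),
       calinski_harabasz = calinski_harabasz(points, solution$labels),
       mean_ari = mean(aris, na.rm = TRUE),
       mean_jaccard = mean(jacs, na.rm = TRUE))
}

#' Permutation test for non-random partition structure
#'
#' Null distribution built by independently permuting each feature column
#' (destroys inter-feature structure, preserves marginals); the statistic
#' is the Calinski-Harabasz index of PAM at k. The p-value uses the
#' add-one rule `(1 + #[null >= observed]) / (1 + B)` so p is never 0.
#'
#' @param points n x p matrix.
#' @param k number of clusters.
#' @param B permutations.
#' @param seed integer seed.
#' @return list with `p`, `observed`, `null` (vector of null statistics).
#' @export
permutation_test <- function(points, k, B = 10000, seed = 1L) {
  points <- as.matrix(points)
  stopifnot(B >= 1)
  obs <- calinski_harabasz(points, pam_cluster(points, k)$labels)
  nullv <- withr::with_seed(seed, vapply(seq_len(B), function(b) {
    perm <- apply(points, 2L, sample)
    calinski_harabasz(perm, pam_cluster(perm, k)$labels)
  }, numeric(1)))
  list(p = (1 + sum(nullv >= obs)) / (1 + B), observed = obs, null = nullv)
}

#' Select the number of subtypes by consensus stability
#'
#' Runs [consensus_cluster()] over a range of k and picks the k with
#' minimum PAC. Exact PAC ties are broken toward the largest tied k (the
#' finest maximally stable partition): with hierarchically nested
#' clusters, every merge level of a stable fine partition is itself
#' perfectly stable, so PAC ties at its minimum across several k and a
#' quality-based tie-break would systematically under-split. When even the
#' best PAC exceeds `pac_ceiling` the partition is flagged as unstable
#' (`stable = FALSE`), which is what pure-noise inputs produce. The
#' default ceiling of 0.3 comes from a null calibration: structureless
#' data keeps its best PAC above roughly 0.4 under this consensus design,
#' while genuinely clustered data sits well below 0.1.
#'
#' @param points n x p normalized matrix.
#' @param k_range candidate cluster counts.
#' @param iterations,subsample,embedding passed to [consensus_cluster()].
#' @param pac_ceiling PAC above which no k is considered stable.
#' @param seed integer seed (each k uses a derived seed).
#' @return list with `k` (chosen), `stable`, `table` (per-k metrics
#'   data.frame) and `solutions` (named list of `cluster_solution`s).
#' @export
select_k <- function(points, k_range = 2:6, iterations = 100,
                     subsample = 0.8, embedding = NULL, pac_ceiling = 0.3,
                     seed = 1L) {
  sols <- lapply(k_range, function(k)
    consensus_cluster(points, k, iterations = iterations,
                      subsample = subsample, embedding = embedding,
                      seed = derive_seed(seed, paste0("k", k))))
  names(sols) <- as.character(k_range)
  tab <- do.call(rbind, lapply(sols, function(s)
    data.frame(k = s$k, pac = s$metrics$pac,
               silhouette = s$metrics$silhouette,
               calinski_harabasz = s$metrics$calinski_harabasz,
               mean_ari = s$metrics$mean_ari,
               mean_jaccard = s$metrics$mean_jaccard)))
  rownames(tab) <- NULL
  best <- which(tab$pac == min(tab$pac))
  best <- best[which.max(tab$k[best])]
  list(k = tab$k[best], stable = tab$pac[best] <= pac_ceiling, table = tab,
       solutions = sols)
}

#' Per-subtype clinical profiles and diagnostic composition
#'
#' Mean normalized score per feature per subtype, plus the percentage
#' composition of each subtype by diagnostic group.
#'
#' @param solution a `cluster_solution` (or an integer label vector).
#' @param normalized a `normalized_clinical` object (or a plain matrix).
#' @param groups diagnostic group labels per subject (taken from
#'   `normalized$groups` when available).
#' @return list with `profiles` (k x p matrix of mean normalized scores)
#'   and `composition` (k x groups percentage matrix, rows summing to 100).
#' @export
profile_subtypes <- function(solution, normalized, groups = NULL) {
  labels <- if (inherits(solution, "cluster_solution")) solution$labels
            else as.integer(solution)
  X <- if (inherits(normalized, "normalized_clinical")) normalized$data
       else as.matrix(normalized)
  if (is.null(groups) && inherits(normalized, "normalized_clinical"))
    groups <- normalized$groups
  ks <- sort(unique(labels))
  prof <- t(vapply(ks, function(g)
    colMeans(X[labels == g, , drop = FALSE]), numeric(ncol(X))))
  rownames(prof) <- paste0("subtype_", ks)
  comp <- NULL
  if (!is.null(groups)) {
    tab <- table(labels, groups)
    comp <- 100 * sweep(tab, 1L, rowSums(tab), "/")
    rownames(comp) <- paste0("subtype_", ks)
  }
  list(profiles = prof, composition = comp)
}
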