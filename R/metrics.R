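#' Nodal strength (weighted degree)
#'
#' Strength of ROI i is the sum of the absolute weights of its retained
#' connections, `deg_i = sum_j |A_ij|`.
#'
#' @param g a `connectome_graph`.
#' @return named numeric vector, one value per ROI.
#' @export
nodal_strength <- function(g) {
  stopifnot(inherits(g, "connectome_graph"))
  rowSums(abs(g$weights))
}

#' Weighted local clustering coefficient (Onnela)
#'
#' Geometric-mean formulation on absolute weights rescaled by the graph
#' maximum: with `what = |A| / max|A|`,
#' `C_i = sum_{j,h} (what_ij what_ih what_jh)^(1/3) / (k_i (k_i - 1))`
#' where `k_i` is the number of retained connections of node i. Isolated
#' and degree-1 nodes get 0.
#'
#' @param g a `connectome_graph`.
#' @return named numeric vector in \[0, 1\].
#' @export
local_clustering <- function(g) {
  stopifnot(inherits(g, "connectome_graph"))
  w <- abs(g$weights)
  k <- rowSums(w > 0)
  mx <- max(w)
  out <- stats::setNames(numeric(nrow(w)), rownames(w))
  if (mx == 0) return(out)
  cr <- (w / mx)^(1 / 3)
  tri <- diag(cr %*% cr %*% cr)  # 2 x sum of cube-root triangle products
  ok <- k >= 2
  out[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Canonical feature names for a network set
#'
#' The network-level feature space for n networks has
#' `n(n+1)/2 + 2n` columns: all unordered network pairs including
#' self-pairs (`inter_*`), one within-network mean per network (`intra_*`)
#' and one network degree per network (`nd_*`). For the canonical 6
#' networks this is the 33-feature space.
#'
#' @param networks character vector of network names in fixed order.
#' @return character vector of feature names.
#' @export
feature_names <- function(networks = default_networks()) {
  n <- length(networks)
  inter <- character(0)
  for (i in seq_len(n)) for (j in i:n)
    inter <- c(inter, paste("inter", networks[i], networks[j], sep = "_"))
  c(inter, paste0("intra_", networks), paste0("nd_", networks))
}

#' Canonical name of one inter-network feature
#' @param k,m network names (order-insensitive).
#' @param networks network order.
#' @return e.g. `inter_SM_CER` for the cerebellum-sensorimotor pair.
#' @export
inter_feature_name <- function(k, m, networks = default_networks()) {
  ik <- match(k, networks); im <- match(m, networks)
  if (is.na(ik) || is.na(im)) stop_fmt("unknown network '%s'", if (is.na(ik)) k else m)
  paste("inter", networks[min(ik, im)], networks[max(ik, im)], sep = "_")
}

#' Mean inter-network connectivity (between networks k and m)
#'
#' Mean retained weight over all ordered ROI pairs of the two blocks,
#' `Inter_km = sum_{i in N_k} sum_{j in N_m} A_ij / (|N_k| |N_m|)`.
#' `k = m` is permitted: the diagonal contributes zeros, making the
#' self-pair value `Intra_k (|N_k|-1) / |N_k|`.
#'
#' @param g a `connectome_graph`.
#' @param atlas an [atlas_map()].
#' @param k,m network names.
#' @return scalar mean connectivity.
#' @export
inter_network <- function(g, atlas, k, m) {
  ik <- network_indices(atlas, k)
  im <- network_indices(atlas, m)
  sum(g$weights[ik, im]) / (length(ik) * length(im))
}

#' Mean intra-network connectivity (within network k)
#'
#' Mean retained weight over the `|N_k|(|N_k|-1)/2` unique within-network
#' ROI pairs.
#'
#' @inheritParams inter_network
#' @return scalar mean connectivity.
#' @export
intra_network <- function(g, atlas, k) {
  ik <- network_indices(atlas, k)
  nk <- length(ik)
  if (nk < 2L) stop_fmt("network '%s' has fewer than 2 ROIs", k)
  sub <- g$weights[ik, ik]
  sum(sub[upper.tri(sub)]) / (nk * (nk - 1) / 2)
}

#' Network degree
#'
#' Total integration of network k with the rest of the connectome: the sum
#' of its inter-network connectivity values to the other networks
#' (self-pair excluded).
#'
#' @param inter named vector of inter-network features (from
#'   [feature_names()] naming) or a function of (k, m).
#' @param k network name.
#' @param networks network order.
#' @return scalar network degree.
#' @export
network_degree <- function(inter, k, networks = default_networks()) {
  others <- setdiff(networks, k)
  sum(vapply(others, function(m)
    inter[[inter_feature_name(k, m, networks)]], numeric(1)))
}

#' Per-network averages of nodal metrics
#'
#' Arithmetic mean nodal strength and mean local clustering over the ROIs
#' of each network.
#'
#' @inheritParams inter_network
#' @return data.frame with columns network, mean_strength, mean_clustering.
#' @export
network_averages <- function(g, atlas) {
  s <- nodal_strength(g)
  cc <- local_clustering(g)
  nets <- atlas$networks
  data.frame(
    network = nets,
    mean_strength = vapply(nets, function(k) mean(s[network_indices(atlas, k)]),
                           numeric(1)),
    mean_clustering = vapply(nets, function(k) mean(cc[network_indices(atlas, k)]),
                             numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
graph_features <- function(g, atlas) {
  nets <- atlas$networks
  n <- length(nets)
  vals <- stats::setNames(numeric(0), character(0))
  for (i in seq_len(n)) for (j in i:n)
    vals[paste("inter", nets[i], nets[j], sep = "_")] <-
      inter_network(g, atlas, nets[i], nets[j])
  for (k in nets) vals[paste0("intra_", k)] <- intra_network(g, atlas, k)
  for (k in nets) vals[paste0("nd_", k)] <- network_degree(vals, k, nets)
  vals
}

#' Assemble the network-level feature table
#'
#' One row per subject x condition with the full network-level feature
#' space (33 columns for a 6-network atlas), plus a companion nodal table
#' with per-ROI strength and clustering.
#'
#' @param graphs list of `connectome_graph` objects sharing the atlas.
#' @param atlas an [atlas_map()].
#' @return list with `features` (data.frame: subject_id, group, condition,
#'   feature columns) and `nodal` (long data.frame: subject_id, group,
#'   condition, roi, network, strength, clustering).
#' @export
build_feature_table <- function(graphs, atlas) {
  keys <- vapply(graphs, function(g) paste(g$subject_id, g$condition), "")
  if (anyDuplicated(keys))
    stop_fmt("duplicate (subject, condition): %s", keys[duplicated(keys)][1L])
  feats <- do.call(rbind, lapply(graphs, function(g)
    as.data.frame(as.list(graph_features(g, atlas)))))
  meta <- data.frame(
    subject_id = vapply(graphs, `[[`, "", "subject_id"),
    group = vapply(graphs, `[[`, "", "group"),
    condition = vapply(graphs, `[[`, "", "condition"),
    stringsAsFactors = FALSE)
  nodal <- do.call(rbind, lapply(graphs, function(g) {
    data.frame(subject_id = g$subject_id, group = g$group,
               condition = g$condition, roi = atlas$roi_labels,
               network = unname(atlas$network_of),
               strength = unname(nodal_strength(g)),
               clustering = unname(local_clustering(g)),
               stringsAsFactors = FALSE)
  }))
  rownames(feats) <- rownames(nodal) <- NULL
  list(features = cbind(meta, feats), nodal = nodal)
}

#' Class of a network-level feature
#' @param feature feature name(s).
#' @return `"inter"`, `"intra"` or `"degree"`.
#' @export
feature_class <- function(feature) {
  cls <- rep(NA_character_, length(feature))
  cls[startsWith(feature, "inter_")] <- "inter"
  cls[startsWith(feature, "intra_")] <- "intra"
  cls[startsWith(feature, "nd_")] <- "degree"
  if (anyNA(cls)) stop_fmt("unrecognized feature name '%s'", feature[is.na(cls)][1L])
  cls
}
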