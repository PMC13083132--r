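#' Canonical network order
#'
#' The six canonical large-scale networks, in the fixed order used for all
#' feature indexing: default mode (DMN), fronto-parietal (FP),
#' cingulo-opercular (CO), sensorimotor (SM), occipital (OCC) and
#' cerebellar (CER). Fixing the order keeps feature columns stable across
#' runs and machines.
#'
#' @return character vector of length 6.
#' @export
default_networks <- function() c("DMN", "FP", "CO", "SM", "OCC", "CER")

#' Construct an atlas map
#'
#' An atlas map assigns each region of interest (ROI) to exactly one
#' network. ROI order is preserved and defines the row order of every
#' time-series matrix and connectivity graph downstream.
#'
#' @param roi_labels character vector of unique ROI identifiers.
#' @param network_of character vector, same length, giving each ROI's
#'   network.
#' @param networks optional character vector fixing network order; defaults
#'   to [default_networks()] when all six are present, otherwise
#'   first-appearance order.
#' @return an object of class `atlas_map` with elements `roi_labels`,
#'   `network_of` (named by ROI) and `networks`.
#' @export
atlas_map <- function(roi_labels, network_of, networks = NULL) {
  roi_labels <- as.character(roi_labels)
  network_of <- as.character(network_of)
  if (length(roi_labels) != length(network_of))
    stop_fmt("roi_labels and network_of must have equal length")
  if (anyDuplicated(roi_labels))
    stop_fmt("duplicate ROI label(s): %s",
             paste(unique(roi_labels[duplicated(roi_labels)]), collapse = ", "))
  if (any(is.na(network_of) | network_of == ""))
    stop_fmt("every ROI must have a non-empty network")
  if (is.null(networks)) {
    seen <- unique(network_of)
    networks <- if (setequal(seen, default_networks())) default_networks() else seen
  }
  if (anyDuplicated(networks)) stop_fmt("network list has duplicates")
  if (!all(network_of %in% networks))
    stop_fmt("unknown network(s): %s",
             paste(setdiff(network_of, networks), collapse = ", "))
  names(network_of) <- roi_labels
  structure(list(roi_labels = roi_labels, network_of = network_of,
                 networks = networks),
            class = "atlas_map")
}

#' @export
print.atlas_map <- function(x, ...) {
  cat(sprintf("atlas_map: %d ROIs in %d networks\n",
              length(x$roi_labels), length(x$networks)))
  print(table(factor(x$network_of, levels = x$networks)))
  invisible(x)
}

#' ROI indices of one network
#' @param atlas an [atlas_map()].
#' @param network network name.
#' @return integer vector of ROI positions.
#' @export
network_indices <- function(atlas, network) {
  if (!network %in% atlas$networks) stop_fmt("unknown network '%s'", network)
  which(atlas$network_of == network)
}

#' Read an atlas map from TSV
#'
#' Expects a tab-separated file with header columns `roi_id` and `network`.
#' ROI order follows file order; network order is first-appearance unless
#' all six canonical networks are present, in which case the fixed default
#' order is used.
#'
#' @param path file path.
#' @return an [atlas_map()].
#' @export
read_atlas_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("roi_id", "network") %in% names(df)))
    stop_fmt("atlas file %s must have columns roi_id, network", path)
  atlas_map(df$roi_id, df$network)
}

#' Write an atlas map to TSV
#' @param atlas an [atlas_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_atlas_map <- function(atlas, path) {
  df <- data.frame(roi_id = atlas$roi_labels,
                   network = unname(atlas$network_of),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic 165-ROI atlas
#'
#' A synthetic atlas with 165 ROI labels spread over the six canonical
#' networks in realistic proportions (34 DMN, 21 FP, 32 CO, 33 SM, 27 OCC,
#' 18 CER). Labels are synthetic (`DMN_001`, ...); no anatomical
#' coordinates are implied.
#'
#' @param sizes named integer vector of ROIs per network; names must be the
#'   canonical networks.
#' @return an [atlas_map()].
#' @export
default_atlas <- function(sizes = c(DMN = 34, FP = 21, CO = 32, SM = 33,
                                    OCC = 27, CER = 18)) {
  stopifnot(setequal(names(sizes), default_networks()), all(sizes >= 2))
  sizes <- sizes[default_networks()]
  labels <- unlist(lapply(names(sizes), function(nw)
    sprintf("%s_%03d", nw, seq_len(sizes[[nw]]))), use.names = FALSE)
  atlas_map(labels, rep(names(sizes), sizes), default_networks())
}
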