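#' Canonical nine-network labels
#'
#' The large-scale resting-state networks used to organize cortical and
#' subcortical regions: visual (VIS), somatomotor (SMT), dorsal attention
#' (DAT), salience/ventral attention (SVA), limbic (LIB), control (CON),
#' default mode (DMN), temporal parietal (TMP), and subcortical (SBC).
#'
#' @export
NETWORKS9 <- c("VIS", "SMT", "DAT", "SVA", "LIB", "CON", "DMN", "TMP", "SBC")

#' Construct a parcellation
#'
#' A parcellation fixes the region order shared by every subject and maps
#' each region to exactly one functional network.
#'
#' @param region_id character or integer vector of unique region labels, in
#'   the order used by all connectivity matrices.
#' @param network character vector, same length, giving each region's
#'   network membership.
#' @param region_name optional human-readable names.
#' @return a `parcellation` data frame with columns `region_id`,
#'   `region_name`, `network`.
#' @export
parcellation <- function(region_id, network, region_name = region_id) {
  region_id <- as.character(region_id)
  if (anyDuplicated(region_id))
    stopf("region ids must be unique")
  if (length(network) != length(region_id))
    stopf("'network' must have one entry per region")
  if (anyNA(network))
    stopf("every region must map to a network")
  p <- data.frame(region_id = region_id,
                  region_name = as.character(region_name),
                  network = as.character(network),
                  stringsAsFactors = FALSE)
  class(p) <- c("parcellation", "data.frame")
  p
}

#' Default whole-brain parcellation
#'
#' A 128-region parcellation split across the nine canonical networks,
#' mirroring the whole-brain template used for the reference analyses
#' (Yeo cortical networks plus a subcortical block). Region counts per
#' network are assigned as near-equal contiguous blocks; real analyses
#' should supply their own parcellation table.
#'
#' @param R number of regions (default 128).
#' @param networks network labels (default the nine canonical networks).
#' @return a [parcellation()].
#' @export
default_parcellation <- function(R = 128, networks = NETWORKS9) {
  if (R < length(networks))
    stopf("need at least one region per network")
  sizes <- diff(round(seq(0, R, length.out = length(networks) + 1)))
  parcellation(region_id = sprintf("ROI%03d", seq_len(R)),
               network = rep(networks, times = sizes))
}

#' Read a parcellation TSV
#'
#' Expects tab-separated columns `region_id`, `region_name` (optional) and
#' `network`, one row per region in matrix order.
#'
#' @param path file path.
#' @return a [parcellation()].
#' @export
read_parcellation <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "network")
  if (!all(need %in% names(tab)))
    stopf("parcellation file must have columns: %s", paste(need, collapse = ", "))
  parcellation(tab$region_id, tab$network,
               region_name = tab$region_name %||% tab$region_id)
}

#' Write a parcellation TSV
#' @param parc a [parcellation()].
#' @param path file path.
#' @export
write_parcellation <- function(parc, path) {
  utils::write.table(as.data.frame(parc), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Number of regions / edges in a parcellation
#' @param parc a [parcellation()].
#' @return integer count.
#' @export
n_regions <- function(parc) nrow(parc)

#' @rdname n_regions
#' @export
n_edges <- function(parc) {
  R <- nrow(parc)
  R * (R - 1L) / 2L
}

#' Edge index: map edge position to its region pair
#'
#' Edges enumerate the strict upper triangle row-major: (1,2), (1,3), ...,
#' (1,R), (2,3), ..., (R-1,R). This order is the vectorization convention
#' used throughout the package.
#'
#' @param R number of regions.
#' @return an E x 2 integer matrix with columns `i`, `j` (i < j).
#' @export
edge_pairs <- function(R) {
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L)
  j <- unlist(lapply(seq_len(R - 1L), function(a) (a + 1L):R), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Network membership of each edge's endpoints
#' @param parc a [parcellation()].
#' @return an E x 2 character matrix of network labels.
#' @export
edge_networks <- function(parc) {
  ep <- edge_pairs(nrow(parc))
  cbind(parc$network[ep[, 1L]], parc$network[ep[, 2L]])
}

#' Human-readable edge labels ("regionA|regionB")
#' @param parc a [parcellation()].
#' @return character vector of length E.
#' @export
edge_labels <- function(parc) {
  ep <- edge_pairs(nrow(parc))
  paste(parc$region_id[ep[, 1L]], parc$region_id[ep[, 2L]], sep = "|")
}

# ordered network levels of a parcellation: canonical order if the labels
# are a subset of NETWORKS9, otherwise order of first appearance
network_levels <- function(parc) {
  u <- unique(parc$network)
  if (all(u %in% NETWORKS9)) NETWORKS9[NETWORKS9 %in% u] else u
}
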