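# Canonical network vocabulary. Base networks in fixed aggregation order;
# TPN is a derived group (DAN u FPN), inserted before DMN when requested.
BASE_NETWORKS <- c("SCN", "LIM", "SMN", "VIS", "VAN", "DAN", "FPN", "DMN")
NETWORK_ORDER_WITH_TPN <- c("SCN", "LIM", "SMN", "VIS", "VAN", "DAN", "FPN", "TPN", "DMN")

# Default ROI counts per network. Seven counts follow the 246-ROI
# Brainnetome-to-Yeo grouping (DMN 36, DAN 30, FPN 26, VAN 22, VIS 34,
# SMN 33, subcortical 39); the limbic count of 26 is the remainder to 246.
DEFAULT_NETWORK_SIZES <- c(
  SCN = 39, LIM = 26, SMN = 33, VIS = 34,
  VAN = 22, DAN = 30, FPN = 26, DMN = 36
)

#' Build a ROI-to-network parcellation
#'
#' Assigns `n_roi` regions to the eight canonical large-scale networks
#' (subcortical SCN, limbic LIM, somatomotor SMN, visual VIS, ventral
#' attention VAN, dorsal attention DAN, frontoparietal FPN, default mode
#' DMN) in contiguous index blocks, and derives the task-positive network
#' (TPN) as the union of DAN and FPN. The default sizes reproduce the
#' 246-ROI grouping used throughout the package, under which |TPN| = 56.
#'
#' @param n_roi total number of ROIs (default 246).
#' @param network_sizes named integer vector with one entry per base
#'   network; must sum to `n_roi`.
#' @return an object of class `parcellation`: a list with `roi_labels`,
#'   `network_of` (character vector, one base network per ROI) and
#'   `derived_groups` (list with `TPN` member indices).
#' @export
make_parcellation <- function(n_roi = 246, network_sizes = DEFAULT_NETWORK_SIZES) {
  if (!is.numeric(n_roi) || length(n_roi) != 1L || n_roi < 1)
    stop("n_roi must be a positive integer")
  nm <- names(network_sizes)
  unknown <- setdiff(nm, BASE_NETWORKS)
  if (length(unknown))
    stop("unknown network name(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(BASE_NETWORKS, nm)
  if (length(missing))
    stop("missing network size(s) for: ", paste(missing, collapse = ", "))
  sizes <- network_sizes[BASE_NETWORKS]
  if (any(sizes < 1)) stop("every network needs at least one ROI")
  if (sum(sizes) != n_roi)
    stop(sprintf("network sizes sum to %d, not n_roi = %d", sum(sizes), n_roi))
  network_of <- rep(BASE_NETWORKS, times = sizes)
  labels <- sprintf("ROI%03d", seq_len(n_roi))
  names(network_of) <- labels
  tpn <- which(network_of %in% c("DAN", "FPN"))
  structure(
    list(roi_labels = labels, network_of = network_of,
         derived_groups = list(TPN = tpn)),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  tab <- table(factor(x$network_of, levels = BASE_NETWORKS))
  cat(sprintf("<parcellation> %d ROIs; TPN = %d\n", length(x$roi_labels),
              length(x$derived_groups$TPN)))
  print(tab)
  invisible(x)
}

# Indices of the member ROIs of a (base or derived) network.
network_members <- function(parc, network) {
  if (network == "TPN") return(parc$derived_groups$TPN)
  which(parc$network_of == network)
}

#' Read / write a parcellation as two-column TSV (roi_label, network)
#' @param parc a `parcellation`.
#' @param path file path.
#' @export
write_parcellation <- function(parc, path) {
  write.table(
    data.frame(roi = parc$roi_labels, network = unname(parc$network_of)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("roi", "network"),
                   colClasses = "character")
  unknown <- setdiff(unique(df$network), BASE_NETWORKS)
  if (length(unknown))
    stop("unknown network name(s) in file: ", paste(unknown, collapse = ", "))
  network_of <- df$network
  names(network_of) <- df$roi
  tpn <- which(network_of %in% c("DAN", "FPN"))
  structure(
    list(roi_labels = df$roi, network_of = network_of,
         derived_groups = list(TPN = tpn)),
    class = "parcellation"
  )
}
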