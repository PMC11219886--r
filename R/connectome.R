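# Functional-connectivity algebra: parcellation, Fisher-z matrices, and the
# canonical edge vectorization shared by every downstream stage.
#
# Edges are the unordered node pairs (i < j) of a symmetric zero-diagonal
# matrix, vectorized in row-major upper-triangle order:
#   (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n).
# For a symmetric matrix this equals `m[lower.tri(m)]` in R's column-major
# storage, which is what the implementation uses.

#' Canonical large-scale network labels
#'
#' The ten resting-state networks used to partition nodes: default mode
#' (DMN), visual (VIS), frontoparietal (FPN), dorsal/ventral attention
#' (DAN/VAN), salience (SAN), cingulo-opercular (CON), auditory (AUD),
#' sensorimotor (SMN) and subcortical (SUB).
#' @export
NETWORKS <- c("DMN", "VIS", "FPN", "DAN", "VAN", "SAN", "CON", "AUD", "SMN", "SUB")

#' Construct a parcellation (node -> network assignment)
#'
#' @param networks character vector, one label per node, drawn from
#'   [NETWORKS]; the default partition of 227 nodes is produced by
#'   [default_parcellation()].
#' @param node_names optional character vector of node names.
#' @return Object of class `"parcellation"`: a data frame with columns
#'   `node_id` (0-based, contiguous), `network` (factor over [NETWORKS]) and
#'   optionally `name`.
#' @export
parcellation <- function(networks, node_names = NULL) {
  networks <- as.character(networks)
  if (length(networks) == 0L) stop("empty_parcellation: no nodes")
  bad <- which(!networks %in% NETWORKS)
  if (length(bad))
    stop("unknown_network: label '", networks[bad[1L]], "' at node ", bad[1L],
         " (canonical labels: ", paste(NETWORKS, collapse = ","), ")")
  p <- data.frame(node_id = seq_along(networks) - 1L,
                  network = factor(networks, levels = NETWORKS))
  if (!is.null(node_names)) {
    stopifnot(length(node_names) == length(networks))
    p$name <- as.character(node_names)
  }
  class(p) <- c("parcellation", "data.frame")
  p
}

#' Default 227-node parcellation
#'
#' Assigns `n_nodes` nodes to the ten canonical networks, contiguously in
#' node order. The default block sizes for 227 nodes (DMN 58, VIS 31, FPN 24,
#' DAN 11, VAN 9, SAN 18, CON 14, AUD 13, SMN 33, SUB 16) approximate the
#' relative network sizes of widely used functional atlases; for other node
#' counts the sizes are rescaled by largest remainder with a floor of two
#' nodes per network, so within-network edges always exist.
#'
#' @param n_nodes node count (default 227).
#' @param network_sizes optional named integer vector over [NETWORKS] summing
#'   to `n_nodes`.
#' @return A [parcellation()].
#' @export
default_parcellation <- function(n_nodes = 227, network_sizes = NULL) {
  if (is.null(network_sizes)) network_sizes <- default_network_sizes(n_nodes)
  stopifnot(setequal(names(network_sizes), NETWORKS))
  network_sizes <- network_sizes[NETWORKS]
  if (sum(network_sizes) != n_nodes)
    stop("bad_network_sizes: sizes sum to ", sum(network_sizes),
         ", expected ", n_nodes)
  if (any(network_sizes <= 0)) stop("bad_network_sizes: all sizes must be > 0")
  parcellation(rep(NETWORKS, times = network_sizes))
}

#' @rdname default_parcellation
#' @export
default_network_sizes <- function(n_nodes = 227) {
  base <- c(DMN = 58, VIS = 31, FPN = 24, DAN = 11, VAN = 9,
            SAN = 18, CON = 14, AUD = 13, SMN = 33, SUB = 16)
  if (n_nodes == 227) return(base)
  if (n_nodes < 20) stop("bad_n_nodes: need at least 2 nodes per network")
  # largest-remainder apportionment with a floor of 2
  quota <- base / sum(base) * (n_nodes - 2 * length(base))
  sizes <- floor(quota)
  rem <- n_nodes - 2 * length(base) - sum(sizes)
  if (rem > 0) {
    ord <- order(quota - sizes, decreasing = TRUE)
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1
  }
  out <- sizes + 2
  storage.mode(out) <- "integer"
  out
}

#' Number of edges of an n-node connectome
#' @param n_nodes node count.
#' @return `n_nodes * (n_nodes - 1) / 2`.
#' @export
n_edges <- function(n_nodes) as.integer(n_nodes * (n_nodes - 1) / 2)

# --- edge-index algebra (1-based edge indices over the i<j row-major order) ---

#' Map node pairs to edge indices and back
#'
#' `edge_index(i, j, n)` gives the position of the unordered pair (i, j) in
#' the canonical edge vector of an `n`-node connectome; `edge_endpoints(k, n)`
#' is its inverse. Both are vectorized; nodes are 1-based.
#'
#' @param i,j node indices (1-based; order irrelevant, `i != j`).
#' @param k edge indices (1-based).
#' @param n number of nodes.
#' @return Integer vector of edge indices, or a two-column matrix `i`, `j`
#'   with `i < j`.
#' @export
edge_index <- function(i, j, n) {
  a <- pmin(i, j); b <- pmax(i, j)
  if (any(a < 1L | b > n | a == b)) stop("bad_edge: endpoints out of range")
  as.integer((a - 1) * n - a * (a - 1) / 2 + (b - a))
}

#' @rdname edge_index
#' @export
edge_endpoints <- function(k, n) {
  E <- n_edges(n)
  k <- as.integer(k)
  if (any(k < 1L | k > E)) stop("bad_edge_index: out of range 1..", E)
  ends <- cumsum((n - 1):1)      # last edge index of each i-block
  i <- findInterval(k - 1L, c(0L, ends), rightmost.closed = FALSE)
  j <- k - c(0L, ends)[i] + i
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Fisher z-transform of correlations
#'
#' `atanh(r)` with the correlation clipped to |r| <= 0.999999 first, so
#' degenerate (perfectly correlated) inputs stay finite.
#' @param r correlations in `[-1, 1]`.
#' @return z-values.
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -0.999999), 0.999999))

#' Functional connectivity matrix from node time series
#'
#' Pearson-correlates every pair of node time series and Fisher
#' z-transforms the result. The diagonal is stored as 0 and excluded from all
#' downstream computation.
#'
#' @param ts numeric matrix, nodes x timepoints, no missing values, at least
#'   two timepoints; every node series must have nonzero variance.
#' @return Symmetric nodes x nodes Fisher-z matrix with zero diagonal.
#' @examples
#' ts <- matrix(rnorm(4 * 50), 4, 50)
#' z <- compute_fc(ts)
#' @export
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (anyNA(ts)) stop("missing_values: time series contain NA")
  if (ncol(ts) < 2L) stop("too_few_timepoints: need >= 2 timepoints")
  v <- apply(ts, 1L, stats::var)
  if (any(v == 0))
    stop("zero_variance_node: node ", which(v == 0)[1L], " has constant series")
  z <- fisher_z(stats::cor(t(ts)))
  z <- (z + t(z)) / 2        # kill rounding asymmetry
  diag(z) <- 0
  z
}

#' Vectorize / devectorize a connectivity matrix
#'
#' `vectorize_fc` extracts the canonical upper-triangle (i < j, row-major)
#' edge vector of a symmetric zero-diagonal matrix; `devectorize_fc` is its
#' exact inverse. For 227 nodes the edge vector has length 25651.
#'
#' @param z symmetric numeric matrix (diagonal ignored).
#' @param v edge vector whose length is a triangular number.
#' @return A numeric vector of length `n(n-1)/2`, or the reconstructed
#'   symmetric matrix with zero diagonal.
#' @export
vectorize_fc <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop("not_square: matrix must be square")
  if (max(abs(z - t(z))) > 1e-12) stop("not_symmetric: |z - t(z)| exceeds 1e-12")
  z[lower.tri(z)]    # column-major lower triangle == row-major upper triangle
}

#' @rdname vectorize_fc
#' @export
devectorize_fc <- function(v) {
  E <- length(v)
  n <- (1 + sqrt(1 + 8 * E)) / 2
  if (abs(n - round(n)) > 1e-9)
    stop("not_triangular: length ", E, " is not n(n-1)/2 for integer n")
  n <- as.integer(round(n))
  z <- matrix(0, n, n)
  z[lower.tri(z)] <- v
  z + t(z)
}

#' Network-pair labels of edges
#'
#' Maps each edge to the unordered pair of its endpoints' network labels.
#' With ten networks there are 55 possible pairs (10 within-network + 45
#' between-network), labelled `"A-B"` with A before B in the canonical
#' [NETWORKS] order.
#'
#' @param p a [parcellation()].
#' @param k optional edge indices; default all edges.
#' @return Factor of pair labels over the 55 levels of
#'   [all_network_pairs()].
#' @export
edge_network_pairs <- function(p, k = NULL) {
  stopifnot(inherits(p, "parcellation"))
  n <- nrow(p)
  if (is.null(k)) k <- seq_len(n_edges(n))
  ij <- edge_endpoints(k, n)
  li <- as.integer(p$network)[ij[, "i"]]
  lj <- as.integer(p$network)[ij[, "j"]]
  a <- pmin(li, lj); b <- pmax(li, lj)
  factor(paste(NETWORKS[a], NETWORKS[b], sep = "-"),
         levels = all_network_pairs())
}

#' @rdname edge_network_pairs
#' @export
edge_network_pair <- function(k, p) as.character(edge_network_pairs(p, k))

#' All 55 unordered network-pair labels
#' @return Character vector of the 55 `"A-B"` labels in canonical order.
#' @export
all_network_pairs <- function() {
  m <- length(NETWORKS)
  unlist(lapply(seq_len(m), function(a)
    paste(NETWORKS[a], NETWORKS[a:m], sep = "-")))
}
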