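# Multi-level characterization of a predictive connectome: where its edges
# live (network-pair counts), how much each pair/network/region contributes
# to the brain-behavior association, and how consistent edge counts and
# contributions are.
#
# "Normalized" always means divide-by-total so a distribution sums to 1, and
# all variances are population variances (divide by the count) -- stated
# here because the printed values depend on these conventions.

.mask_idx <- function(mask) {
  if (inherits(mask, "cpm"))
    return(sort(unique(c(mask$consensus$positive, mask$consensus$negative))))
  if (is.list(mask))
    return(sort(unique(c(mask$positive %||% integer(0),
                         mask$negative %||% integer(0)))))
  if (is.logical(mask)) return(which(mask))
  sort(unique(as.integer(mask)))
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Network-pair edge counts and shares of a connectome mask
#'
#' Counts the mask's edges by unordered network pair (all 55 pairs, zeros
#' included), normalizes the counts to shares summing to 1, and reports the
#' population variance of the 55 shares -- a concentration measure (high
#' variance = edges piled into few pairs).
#'
#' @param mask edge indices, a logical vector, a selection/consensus list, or
#'   a fitted [cpm()] (its consensus mask is used); must be non-empty.
#' @param p a [parcellation()].
#' @return List with `table` (data frame: `pair`, `edge_count`,
#'   `normalized_edge_share`) and `share_variance`.
#' @export
pair_edge_profile <- function(mask, p) {
  idx <- .mask_idx(mask)
  if (!length(idx)) stop("empty_mask: no edges to profile")
  lab <- edge_network_pairs(p, idx)
  cnt <- table(lab)
  share <- as.numeric(cnt) / length(idx)
  list(table = data.frame(pair = names(cnt), edge_count = as.integer(cnt),
                          normalized_edge_share = share,
                          stringsAsFactors = FALSE),
       share_variance = pop_var(share))
}

#' Network-pair contributions to the brain-behavior association
#'
#' For every network pair holding at least one mask edge, the contribution is
#' the absolute Pearson correlation between behavior and the per-subject sum
#' of that pair's mask-edge strengths; contributions are then normalized to
#' sum to 1 over the contributing pairs, and the population variance of the
#' normalized values is reported. Absolute correlation makes positive- and
#' negative-tail edges comparable.
#'
#' @param x subjects x edges matrix.
#' @param y behavior vector.
#' @param mask as in [pair_edge_profile()].
#' @param p a [parcellation()].
#' @return List with `table` (data frame: `pair`, `edge_count`,
#'   `contribution_r`, `normalized_contribution`) over contributing pairs,
#'   and `contribution_variance`.
#' @export
pair_contribution <- function(x, y, mask, p) {
  X <- as.matrix(x)
  if (nrow(X) < 3L) stop("too_few_subjects: need >= 3")
  if (stats::sd(y) == 0) stop("constant_behavior: y has zero variance")
  idx <- .mask_idx(mask)
  if (!length(idx)) stop("empty_mask: no edges")
  lab <- edge_network_pairs(p, idx)
  pairs <- names(which(table(lab) > 0))
  contr <- vapply(pairs, function(q) {
    e <- idx[lab == q]
    s <- rowSums(X[, e, drop = FALSE])
    if (stats::sd(s) == 0) 0 else abs(stats::cor(s, y))
  }, numeric(1))
  norm <- if (sum(contr) > 0) contr / sum(contr) else contr
  list(table = data.frame(pair = pairs,
                          edge_count = as.integer(table(lab)[pairs]),
                          contribution_r = unname(contr),
                          normalized_contribution = unname(norm),
                          stringsAsFactors = FALSE),
       contribution_variance = pop_var(unname(norm)))
}

#' Large-scale network endpoint shares and contributions
#'
#' Per network: its share of mask-edge endpoints (each edge contributes two
#' endpoints, so a within-network edge counts twice for its network), and its
#' contribution |r| computed from the summed strengths of all mask edges
#' touching the network. Shares sum to 1 over the ten networks.
#'
#' @inheritParams pair_contribution
#' @param y optional behavior; when omitted only shares are computed.
#' @return Data frame with `network`, `endpoint_count`, `endpoint_share`, and
#'   (when `y` is given) `contribution_r` and `normalized_contribution`;
#'   attribute `share_variance` holds the population variance of the shares.
#' @export
network_shares <- function(mask, p, x = NULL, y = NULL) {
  idx <- .mask_idx(mask)
  if (!length(idx)) stop("empty_mask: no edges")
  ij <- edge_endpoints(idx, nrow(p))
  net <- as.integer(p$network)
  cnt <- tabulate(c(net[ij[, "i"]], net[ij[, "j"]]), nbins = length(NETWORKS))
  out <- data.frame(network = NETWORKS, endpoint_count = cnt,
                    endpoint_share = cnt / (2 * length(idx)),
                    stringsAsFactors = FALSE)
  attr(out, "share_variance") <- pop_var(out$endpoint_share)
  if (!is.null(y)) {
    X <- as.matrix(x)
    contr <- vapply(seq_along(NETWORKS), function(k) {
      touch <- idx[net[ij[, "i"]] == k | net[ij[, "j"]] == k]
      if (!length(touch)) return(0)
      s <- rowSums(X[, touch, drop = FALSE])
      if (stats::sd(s) == 0) 0 else abs(stats::cor(s, y))
    }, numeric(1))
    out$contribution_r <- contr
    out$normalized_contribution <- if (sum(contr) > 0) contr / sum(contr) else contr
    attr(out, "contribution_variance") <-
      pop_var(out$normalized_contribution[out$endpoint_count > 0])
  }
  out
}

#' Regional degree and contribution profile
#'
#' Per node: its degree in the mask (number of incident mask edges) and its
#' contribution |r| (absolute correlation of the summed strengths of its
#' incident mask edges with behavior; 0 for isolated nodes), plus the
#' similarity of the two profiles, `similarity_r = cor(degree,
#' contribution)` over all nodes.
#'
#' @inheritParams pair_contribution
#' @return List with `table` (data frame: `node_id`, `network`,
#'   `regional_degree`, `regional_contribution`) and `similarity_r`.
#' @export
regional_profile <- function(x, y, mask, p) {
  X <- as.matrix(x)
  if (nrow(X) < 3L) stop("too_few_subjects: need >= 3")
  idx <- .mask_idx(mask)
  if (!length(idx)) stop("empty_mask: no edges")
  n <- nrow(p)
  ij <- edge_endpoints(idx, n)
  deg <- tabulate(c(ij[, "i"], ij[, "j"]), nbins = n)
  contr <- numeric(n)
  for (v in which(deg > 0)) {
    inc <- idx[ij[, "i"] == v | ij[, "j"] == v]
    s <- rowSums(X[, inc, drop = FALSE])
    contr[v] <- if (stats::sd(s) == 0) 0 else abs(stats::cor(s, y))
  }
  sim <- if (stats::sd(deg) == 0 || stats::sd(contr) == 0) NA_real_
         else stats::cor(deg, contr)
  list(table = data.frame(node_id = p$node_id, network = p$network,
                          regional_degree = deg,
                          regional_contribution = contr),
       similarity_r = sim)
}

#' Full multi-level characterization of a predictive connectome
#'
#' Bundles [pair_edge_profile()], [pair_contribution()], [network_shares()]
#' and [regional_profile()] into one report.
#'
#' @param fit a fitted [cpm()] (or any mask accepted by
#'   [pair_edge_profile()]).
#' @param x subjects x edges matrix.
#' @param y behavior vector.
#' @param p a [parcellation()]; defaults to the one stored in `fit` when
#'   present.
#' @return Object of class `"connectome_profile"` with components `pairs`,
#'   `pair_contributions`, `networks`, `regions`, the four concentration
#'   variances, `similarity_r`, and the consensus edge count.
#' @export
characterize_connectome <- function(fit, x, y, p = NULL) {
  if (is.null(p) && inherits(fit, "cpm")) p <- fit$parcellation
  if (is.null(p)) stop("missing_parcellation: supply p")
  idx <- .mask_idx(fit)
  pe <- pair_edge_profile(idx, p)
  pc <- pair_contribution(x, y, idx, p)
  ns <- network_shares(idx, p, x, y)
  rp <- regional_profile(x, y, idx, p)
  structure(list(
    pairs = pe$table, pair_contributions = pc$table, networks = ns,
    regions = rp$table,
    variances = c(pair_edge_share = pe$share_variance,
                  pair_contribution = pc$contribution_variance,
                  network_share = attr(ns, "share_variance"),
                  network_contribution = attr(ns, "contribution_variance")),
    similarity_r = rp$similarity_r,
    n_edges_in_mask = length(idx)),
    class = "connectome_profile")
}

#' @export
print.connectome_profile <- function(x, ...) {
  cat(sprintf("Connectome characterization: %d mask edges\n", x$n_edges_in_mask))
  top <- x$pairs[order(-x$pairs$edge_count), ][seq_len(min(5, nrow(x$pairs))), ]
  top <- top[top$edge_count > 0, , drop = FALSE]
  cat("  top network pairs by edge count:\n")
  for (r in seq_len(nrow(top)))
    cat(sprintf("    %-9s %3d edges (share %.2f)\n", top$pair[r],
                top$edge_count[r], top$normalized_edge_share[r]))
  cat("  concentration variances: ",
      paste(sprintf("%s=%.3g", names(x$variances), x$variances), collapse = "  "),
      "\n", sep = "")
  cat(sprintf("  regional degree vs contribution similarity r = %.3f\n",
              x$similarity_r))
  invisible(x)
}
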