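# Three-group comparison of connectome-restricted connectivity, plus the
# summary-statistic Welch t utilities used for demographics-table contrasts.
#
# Subject-level network-pair strength is the MEAN Fisher-z over the pair's
# consensus edges (not the sum), so strengths are comparable across pairs
# with different edge counts. Pairs are tested by classical one-way
# fixed-effects ANOVA, corrected across pairs (BH-FDR by default); post-hoc
# Welch t contrasts are run only for pairs surviving correction.

#' Subject-level network-pair strengths
#'
#' For each network pair with at least one mask edge, each subject's strength
#' is the mean Fisher-z over that pair's mask edges.
#'
#' @param x subjects x edges matrix.
#' @param mask edge indices / selection list / fitted [cpm()].
#' @param p a [parcellation()].
#' @return Subjects x pairs numeric matrix, columns named by network pair.
#' @export
pair_strengths <- function(x, mask, p) {
  X <- as.matrix(x)
  idx <- .mask_idx(mask)
  if (!length(idx)) stop("empty_mask: no edges")
  lab <- edge_network_pairs(p, idx)
  pairs <- names(which(table(lab) > 0))
  out <- vapply(pairs, function(q)
    rowMeans(X[, idx[lab == q], drop = FALSE]), numeric(nrow(X)))
  colnames(out) <- pairs
  out
}

#' One network pair's strength for one subject
#'
#' @param z the subject's symmetric Fisher-z matrix.
#' @param mask edge indices / selection list / fitted [cpm()].
#' @param pair network-pair label, e.g. `"DMN-DMN"`.
#' @param p a [parcellation()].
#' @return Mean Fisher-z over the pair's mask edges.
#' @export
pair_strength <- function(z, mask, pair, p) {
  idx <- .mask_idx(mask)
  lab <- edge_network_pairs(p, idx)
  e <- idx[as.character(lab) == pair]
  if (!length(e)) stop("empty_pair: no mask edges in pair ", pair)
  mean(vectorize_fc(z)[e])
}

#' One-way fixed-effects ANOVA across groups
#'
#' Classical (equal-variance) one-way ANOVA via [stats::oneway.test()]. The
#' fully degenerate case (zero between- and within-group variance) is
#' reported as `F = 0, p = 1` rather than `0/0`.
#'
#' @param values numeric vector.
#' @param groups group labels, same length; at least 2 groups of >= 2.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_across_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("too_few_groups: need >= 2 groups")
  if (any(table(groups) < 2L)) stop("too_few_subjects: every group needs >= 2")
  k <- nlevels(groups); N <- length(values)
  res <- suppressWarnings(tryCatch(
    stats::oneway.test(values ~ groups, var.equal = TRUE),
    error = function(e) NULL))
  if (is.null(res) || !is.finite(res$statistic)) {
    return(list(F = 0, df1 = k - 1L, df2 = N - k, p = 1))
  }
  list(F = unname(res$statistic), df1 = unname(res$parameter[1L]),
       df2 = unname(res$parameter[2L]), p = unname(res$p.value))
}

#' Multiple-comparison correction
#'
#' Benjamini-Hochberg q-values (default) or Bonferroni, via
#' [stats::p.adjust()].
#'
#' @param pvalues p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Corrected values, same length, each >= the raw p.
#' @export
correct_multiple <- function(pvalues, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("bad_pvalues: values outside [0, 1]")
  stats::p.adjust(pvalues, method = method)
}

#' Two-sample t contrast with effect size
#'
#' Welch unequal-variance t test by default (pooled-variance optional), with
#' Cohen's d. Two d variants are reported because the standardizer differs
#' between conventions: `cohen_d` uses the pooled SD, `d_tn` is `t / sqrt(N)`.
#' Identical constant samples give `t = 0, p = 1`.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param pooled use the pooled-variance (Student) t instead of Welch.
#' @return List with `t`, `df`, `p` (two-sided), `cohen_d`, `d_tn`, `n`.
#' @export
posthoc_t <- function(a, b, pooled = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("too_few_subjects: need >= 2 per group")
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) {
    d <- 0
    res <- list(statistic = 0, parameter = na + nb - 2, p.value = 1)
    if (mean(a) != mean(b)) stop("degenerate_samples: zero variance, unequal means")
  } else {
    d <- (mean(a) - mean(b)) / sp
    res <- stats::t.test(a, b, var.equal = pooled)
  }
  t_val <- unname(res$statistic)
  list(t = t_val, df = unname(res$parameter), p = unname(res$p.value),
       cohen_d = d, d_tn = t_val / sqrt(na + nb), n = na + nb)
}

#' Welch t from summary statistics
#'
#' The unequal-variance t statistic and Welch-Satterthwaite degrees of
#' freedom computed directly from group means, SDs and sizes -- e.g. for
#' re-deriving contrasts from a published demographics table:
#' \deqn{t = \frac{\bar x_A - \bar x_B}{\sqrt{s_A^2/n_A + s_B^2/n_B}}.}
#'
#' @param mean_a,sd_a,n_a first group's mean, SD, size.
#' @param mean_b,sd_b,n_b second group's mean, SD, size.
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' # REM% on a manipulation night, early- vs late-night deprivation
#' welch_t_from_summary(24.41, 6.56, 41, 15.18, 5.31, 36)
#' @export
welch_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (sd_a <= 0 || sd_b <= 0) stop("bad_sd: SDs must be > 0")
  if (n_a < 2 || n_b < 2) stop("bad_n: group sizes must be >= 2")
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  t_val <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t_val, df = df, p = 2 * stats::pt(-abs(t_val), df))
}

#' Per-edge ANOVA within a network pair
#'
#' One-way ANOVA across groups for every mask edge of one network pair, with
#' multiple-comparison correction within the pair.
#'
#' @param x subjects x edges matrix.
#' @param groups group labels.
#' @param mask edge indices / selection list / fitted [cpm()].
#' @param pair network-pair label.
#' @param p a [parcellation()].
#' @param correction `"BH"` or `"bonferroni"`.
#' @return Data frame, one row per edge: `edge`, `node_i`, `node_j`, `F`,
#'   `p`, `p_corrected`.
#' @export
edge_level_anova <- function(x, groups, mask, pair, p, correction = "BH") {
  X <- as.matrix(x)
  idx <- .mask_idx(mask)
  lab <- edge_network_pairs(p, idx)
  e <- idx[as.character(lab) == pair]
  if (!length(e)) stop("empty_pair: no mask edges in pair ", pair)
  res <- lapply(e, function(k) anova_across_groups(X[, k], groups))
  ij <- edge_endpoints(e, nrow(p))
  out <- data.frame(edge = e, node_i = ij[, "i"], node_j = ij[, "j"],
                    F = vapply(res, `[[`, 0, "F"),
                    p = vapply(res, `[[`, 0, "p"))
  out$p_corrected <- correct_multiple(out$p, correction)
  out
}

#' Compare connectome strengths across study groups
#'
#' The group-level stage of the pipeline: per-subject network-pair strengths
#' restricted to a consensus connectome, one-way ANOVA per pair across the
#' three groups, correction across pairs, then (gatekept on surviving
#' correction) post-hoc Welch contrasts for the three group pairings and an
#' edge-level ANOVA follow-up within each significant pair.
#'
#' @param x subjects x edges matrix, or a [generate_cohort()] result.
#' @param groups group labels (taken from the cohort when `x` is one).
#' @param mask edge indices / selection list / fitted [cpm()].
#' @param p a [parcellation()] (taken from the cohort when `x` is one).
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @param q_threshold corrected significance threshold (default 0.05).
#' @return Object of class `"group_comparison"`: `anova` (per-pair data
#'   frame with `F`, `df1`, `df2`, `p`, `p_corrected`, `significant`),
#'   `posthoc` (named list per significant pair of the three contrasts),
#'   `edges` (named list per significant pair of [edge_level_anova()]
#'   tables), `strengths` (the subjects x pairs matrix), and the settings.
#' @export
compare_groups <- function(x, groups = NULL, mask, p = NULL,
                           correction = c("BH", "bonferroni"),
                           q_threshold = 0.05) {
  correction <- match.arg(correction)
  if (inherits(x, "rem_cohort")) {
    if (is.null(groups)) groups <- x$behavior$group
    if (is.null(p)) p <- x$parcellation
    x <- x$edges
  }
  if (is.null(groups) || is.null(p))
    stop("missing_argument: groups and p are required with a plain matrix")
  X <- as.matrix(x)
  # canonical study-group ordering when the labels allow it (locale-stable)
  groups <- if (all(groups %in% GROUPS))
    factor(groups, levels = intersect(GROUPS, unique(groups)))
  else factor(groups)
  S <- pair_strengths(X, mask, p)

  res <- lapply(colnames(S), function(q) anova_across_groups(S[, q], groups))
  tab <- data.frame(pair = colnames(S),
                    n_edges = vapply(colnames(S), function(q) {
                      idx <- .mask_idx(mask)
                      sum(as.character(edge_network_pairs(p, idx)) == q)
                    }, 0L),
                    F = vapply(res, `[[`, 0, "F"),
                    df1 = vapply(res, `[[`, 0, "df1"),
                    df2 = vapply(res, `[[`, 0, "df2"),
                    p = vapply(res, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  tab$p_corrected <- correct_multiple(tab$p, correction)
  tab$significant <- tab$p_corrected < q_threshold

  posthoc <- list(); edges <- list()
  lev <- levels(groups)
  for (q in tab$pair[tab$significant]) {
    contrasts <- list()
    for (aa in seq_len(length(lev) - 1L)) for (bb in (aa + 1L):length(lev)) {
      key <- paste(lev[aa], "vs", lev[bb])
      contrasts[[key]] <- posthoc_t(S[groups == lev[aa], q],
                                    S[groups == lev[bb], q])
    }
    posthoc[[q]] <- contrasts
    edges[[q]] <- edge_level_anova(X, groups, mask, q, p, correction)
  }

  structure(list(anova = tab, posthoc = posthoc, edges = edges,
                 strengths = S, correction = correction,
                 q_threshold = q_threshold, groups = groups),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison over %d network pairs (%s correction, q < %g)\n",
              nrow(x$anova), x$correction, x$q_threshold))
  tab <- x$anova[order(x$anova$p), ]
  for (r in seq_len(nrow(tab))) {
    cat(sprintf("  %-9s F(%d,%d) = %6.2f, p = %.3g, corrected = %.3g%s\n",
                tab$pair[r], tab$df1[r], tab$df2[r], tab$F[r], tab$p[r],
                tab$p_corrected[r], if (tab$significant[r]) "  *" else ""))
  }
  for (q in names(x$posthoc)) {
    cat(sprintf("  post-hoc (%s):\n", q))
    for (key in names(x$posthoc[[q]])) {
      ph <- x$posthoc[[q]][[key]]
      cat(sprintf("    %-22s t = %+.2f, p = %.3g, d = %+.2f\n",
                  key, ph$t, ph$p, ph$cohen_d))
    }
    sig_e <- sum(x$edges[[q]]$p_corrected < x$q_threshold)
    cat(sprintf("    edge-level: %d of %d edges significant after correction\n",
                sig_e, nrow(x$edges[[q]])))
  }
  invisible(x)
}
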