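# Connectome-based predictive modeling (CPM).
#
# Protocol: within each leave-one-out fold, every edge is Pearson-correlated
# with behavior over the n-1 training subjects; edges with r > 0 and
# two-sided p < alpha form the positive mask, r < 0 analogously the negative
# mask. Each training subject's positive (negative) strength is the sum of
# its z-values over the mask; a linear model of behavior on the strength is
# fit on the training subjects only and applied to the held-out subject's
# strength computed under the same (training-derived) mask. Significance of
# the observed-vs-predicted correlation is assessed by permuting behavior
# and re-running the entire pipeline, selection included.
#
# The per-fold correlations are computed by downdating full-sample cross
# products (leave-one-out sums), so a fold never sees the held-out subject;
# the no-leakage property is asserted in the test suite.

# Build the X-dependent part of the LOOCV engine once; the returned closure
# re-runs the full pipeline for any behavior vector (used verbatim by the
# permutation test, where only y changes).
.cpm_engine <- function(X, alpha) {
  n <- nrow(X); E <- ncol(X)
  m <- n - 1L                      # training-set size
  dfree <- m - 2L
  tcrit <- stats::qt(1 - alpha / 2, dfree)
  rcrit <- sqrt(tcrit^2 / (tcrit^2 + dfree))   # |r| > rcrit  <=>  p < alpha
  Sx <- colSums(X)
  Sxx <- colSums(X * X)
  SxM <- matrix(Sx, n, E, byrow = TRUE) - X        # per-fold training sums
  SxxM <- matrix(Sxx, n, E, byrow = TRUE) - X * X
  dxx <- m * SxxM - SxM * SxM
  dxx[dxx < 0] <- 0
  sq_dxx <- sqrt(dxx)

  rows_of <- function(lin) ((lin - 1L) %% n) + 1L
  cols_of <- function(lin) ((lin - 1L) %/% n) + 1L

  function(y, want_masks = FALSE) {
    Sy <- sum(y); Syy <- sum(y * y)
    sy <- Sy - y                      # length-n vectors recycle down columns
    dyy <- m * (Syy - y * y) - sy * sy
    dyy[dyy < 0] <- 0
    Sxy <- as.vector(crossprod(X, y))
    num <- m * (matrix(Sxy, n, E, byrow = TRUE) - X * y) - SxM * sy
    r <- num / (sq_dxx * sqrt(dyy))
    r[!is.finite(r)] <- 0

    # per-fold masks, extracted in one pass over the selection matrix
    lin_p <- which(r > rcrit)
    lin_n <- which(r < -rcrit)
    mask_p <- split(cols_of(lin_p), factor(rows_of(lin_p), levels = seq_len(n)))
    mask_n <- split(cols_of(lin_n), factor(rows_of(lin_n), levels = seq_len(n)))

    pred <- matrix(NA_real_, n, 3L,
                   dimnames = list(NULL, c("positive", "negative", "combined")))
    n_empty <- 0L
    for (i in seq_len(n)) {
      ip <- mask_p[[i]]; im <- mask_n[[i]]
      yi <- y[i]
      my <- (Sy - yi) / m
      has_p <- length(ip) > 0L; has_n <- length(im) > 0L

      # closed-form simple OLS on the n-1 training subjects; all sums are
      # full-sample sums minus the held-out subject's contribution
      p1 <- function(f) {
        fi <- f[i]
        sf <- sum(f) - fi
        sff <- sum(f * f) - fi * fi
        sfy <- sum(f * y) - fi * yi
        vf <- sff - sf * sf / m
        if (!is.finite(vf) || vf <= 1e-300) return(my)
        b <- (sfy - sf * (Sy - yi) / m) / vf
        my + b * (fi - sf / m)
      }
      fp <- if (has_p) rowSums(X[, ip, drop = FALSE]) else NULL
      fn <- if (has_n) rowSums(X[, im, drop = FALSE]) else NULL
      pred[i, 1L] <- if (has_p) p1(fp) else my
      pred[i, 2L] <- if (has_n) p1(fn) else my
      if (has_p && has_n) {
        # two-feature OLS via centered 2x2 normal equations
        mfp <- (sum(fp) - fp[i]) / m; mfn <- (sum(fn) - fn[i]) / m
        cp <- fp - mfp; cn <- fn - mfn; cy <- y - my
        a11 <- sum(cp * cp) - cp[i]^2
        a22 <- sum(cn * cn) - cn[i]^2
        a12 <- sum(cp * cn) - cp[i] * cn[i]
        b1 <- sum(cp * cy) - cp[i] * cy[i]
        b2 <- sum(cn * cy) - cn[i] * cy[i]
        det <- a11 * a22 - a12 * a12
        pred[i, 3L] <- if (!is.finite(det) || abs(det) <= 1e-12 * max(a11 * a22, 1e-300))
          pred[i, 1L]
        else {
          s1 <- (a22 * b1 - a12 * b2) / det
          s2 <- (a11 * b2 - a12 * b1) / det
          my + s1 * (fp[i] - mfp) + s2 * (fn[i] - mfn)
        }
      } else if (has_p) pred[i, 3L] <- pred[i, 1L]
        else if (has_n) pred[i, 3L] <- pred[i, 2L]
        else pred[i, 3L] <- my
      if (!has_p && !has_n) n_empty <- n_empty + 1L
    }
    list(pred = pred,
         masks_pos = if (want_masks) lapply(mask_p, as.integer) else NULL,
         masks_neg = if (want_masks) lapply(mask_n, as.integer) else NULL,
         n_empty = n_empty)
  }
}

# correlation of cross-validated predictions with observed behavior;
# a constant prediction vector (all folds empty-masked) counts as r = 0
.pred_cor <- function(pred, y) {
  apply(pred, 2L, function(p) {
    if (stats::sd(p) == 0) 0 else stats::cor(p, y)
  })
}

#' Fit a connectome-based predictive model
#'
#' Predicts a behavioral measure (here REM sleep duration in minutes) from a
#' subjects x edges matrix of Fisher-z connectivity values, using per-fold
#' edge selection, summed positive/negative edge strengths as features,
#' leave-one-out cross-validated linear models, and a one-tailed permutation
#' test on the observed-vs-predicted Pearson correlation. Three models are
#' fit and reported: positive-strength, negative-strength, and a combined
#' two-feature model; the positive model is the conventional headline.
#'
#' @param x subjects x edges numeric matrix, or a [generate_cohort()] result
#'   (in which case `y` defaults to REM duration).
#' @param y behavior vector, one value per subject, nonconstant.
#' @param alpha per-edge two-sided p-value threshold for selection
#'   (default 0.01).
#' @param n_perm number of behavior permutations (default 1000; must be at
#'   least 100 when `permute = TRUE`).
#' @param consensus_fraction fraction of folds in which an edge must be
#'   selected (with the same sign) to enter the consensus connectome
#'   (default 1, i.e. the intersection over folds).
#' @param seed integer seed for the permutation stream (optional).
#' @param permute run the permutation test (default `TRUE`); set `FALSE` for
#'   a fast fit without significance.
#' @param ... passed between methods.
#' @return Object of class `"cpm"` with components `predictions`
#'   (subjects x 3 cross-validated predictions), `r_obs`, `p_perm` (one-tailed,
#'   add-one permutation p per model; `NA` without permutation), `fold_masks`
#'   (per-fold positive/negative edge-index lists), `consensus` (edge indices
#'   by sign), `n_empty_folds`, `full_fit` (full-sample selection and
#'   coefficients, used by [predict.cpm()]), and the call/configuration.
#' @examples
#' cfg <- cohort_config(n_per_group = c(FS = 6, early_dep = 6, late_dep = 6),
#'                      n_nodes = 30, n_planted = 8, beta = 0.3, seed = 2)
#' coh <- generate_cohort(cfg)
#' fit <- cpm(coh, permute = FALSE)
#' fit
#' @references Shen X, Finn ES, Scheinost D, et al. Using connectome-based
#'   predictive modeling to predict individual behavior from brain
#'   connectivity. Nature Protocols 12, 506-518 (2017).
#' @export
cpm <- function(x, ...) UseMethod("cpm")

#' @rdname cpm
#' @export
cpm.rem_cohort <- function(x, y = x$behavior$rem_duration_min, ...) {
  fit <- cpm.default(x$edges, y, ...)
  fit$parcellation <- x$parcellation
  fit
}

#' @rdname cpm
#' @export
cpm.default <- function(x, y, alpha = 0.01, n_perm = 1000,
                        consensus_fraction = 1, seed = NULL,
                        permute = TRUE, ...) {
  X <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length_mismatch: length(y) != nrow(x)")
  if (n < 10L) stop("too_few_subjects: leave-one-out CPM needs n >= 10")
  if (anyNA(X) || anyNA(y)) stop("missing_values: x and y must be complete")
  if (stats::sd(y) == 0) stop("constant_behavior: y has zero variance")
  if (!(alpha > 0 && alpha < 1)) stop("bad_alpha: need 0 < alpha < 1")
  if (!(consensus_fraction > 0 && consensus_fraction <= 1))
    stop("bad_consensus_fraction: need 0 < fraction <= 1")
  if (permute && n_perm < 100L)
    stop("bad_n_perm: permutation test needs n_perm >= 100")

  engine <- .cpm_engine(X, alpha)
  obs <- engine(y, want_masks = TRUE)
  r_obs <- .pred_cor(obs$pred, y)

  p_perm <- c(positive = NA_real_, negative = NA_real_, combined = NA_real_)
  if (permute) {
    if (!is.null(seed)) set.seed(seed)
    perm_r <- matrix(0, n_perm, 3L)
    for (b in seq_len(n_perm)) {
      yp <- y[sample.int(n)]
      perm_r[b, ] <- .pred_cor(engine(yp)$pred, yp)
    }
    p_perm[] <- (1 + colSums(perm_r >= rep(r_obs, each = n_perm))) / (n_perm + 1)
  }

  full_sel <- select_edges(X, y, alpha)
  full_fit <- list(selection = full_sel,
                   positive = .ols_feature_fit(X, y, full_sel$positive),
                   negative = .ols_feature_fit(X, y, full_sel$negative),
                   combined = .ols_feature_fit2(X, y, full_sel$positive,
                                                full_sel$negative))

  fit <- structure(list(
    call = match.call(), n = n, n_edges = ncol(X),
    alpha = alpha, n_perm = if (permute) n_perm else 0L,
    consensus_fraction = consensus_fraction,
    predictions = obs$pred, observed = y, r_obs = r_obs, p_perm = p_perm,
    fold_masks = list(positive = obs$masks_pos, negative = obs$masks_neg),
    n_empty_folds = obs$n_empty, full_fit = full_fit, seed = seed),
    class = "cpm")
  fit$consensus <- consensus_connectome(fit, consensus_fraction)
  fit
}

# coefficients of behavior ~ summed strength over `idx` (full sample)
.ols_feature_fit <- function(X, y, idx) {
  if (!length(idx)) return(list(coef = c(intercept = mean(y), slope = 0),
                                edges = integer(0)))
  f <- rowSums(X[, idx, drop = FALSE])
  b <- stats::cov(f, y) / stats::var(f)
  list(coef = c(intercept = mean(y) - b * mean(f), slope = b), edges = idx)
}

.ols_feature_fit2 <- function(X, y, ip, im) {
  if (!length(ip) || !length(im))
    return(list(coef = NULL, edges = list(positive = ip, negative = im)))
  fp <- rowSums(X[, ip, drop = FALSE])
  fn <- rowSums(X[, im, drop = FALSE])
  cf <- tryCatch(qr.coef(qr(cbind(1, fp, fn)), y), error = function(e) NULL)
  list(coef = if (is.null(cf)) NULL
       else c(intercept = cf[1L], pos_slope = cf[2L], neg_slope = cf[3L]),
       edges = list(positive = ip, negative = im))
}

#' Select behavior-correlated edges
#'
#' Full-sample CPM edge selection: an edge enters the positive mask iff its
#' Pearson correlation with behavior is positive with two-sided p below
#' `alpha`, and the negative mask analogously. The two masks are disjoint by
#' construction.
#'
#' @param x subjects x edges matrix (at least 3 subjects).
#' @param y behavior vector, nonconstant.
#' @param alpha per-edge two-sided p threshold.
#' @return List with `positive` and `negative` (integer edge indices), and
#'   the per-edge `r` and `p` vectors.
#' @export
select_edges <- function(x, y, alpha = 0.01) {
  X <- as.matrix(x)
  n <- nrow(X)
  if (n < 3L) stop("too_few_subjects: selection needs n >= 3")
  if (stats::sd(y) == 0) stop("constant_behavior: y has zero variance")
  r <- suppressWarnings(as.vector(stats::cor(X, y)))
  dfree <- n - 2L
  tt <- abs(r) * sqrt(dfree / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-tt, dfree)
  p[!is.finite(r)] <- 1
  r[!is.finite(r)] <- 0
  list(positive = which(r > 0 & p < alpha),
       negative = which(r < 0 & p < alpha),
       r = r, p = p)
}

#' Summed edge strengths under a mask
#'
#' The CPM features: sums of a subject's Fisher-z edge values over the
#' positive and negative masks separately.
#'
#' @param x edge vector (one subject) or subjects x edges matrix.
#' @param mask list with `positive`/`negative` edge indices (as produced by
#'   [select_edges()] or [consensus_connectome()]).
#' @return For a vector, `c(pos_sum, neg_sum)`; for a matrix, a subjects x 2
#'   matrix.
#' @export
strength_features <- function(x, mask) {
  stopifnot(is.list(mask))
  ip <- mask$positive %||% integer(0)
  im <- mask$negative %||% integer(0)
  if (is.matrix(x)) {
    cbind(pos_sum = if (length(ip)) rowSums(x[, ip, drop = FALSE]) else rep(0, nrow(x)),
          neg_sum = if (length(im)) rowSums(x[, im, drop = FALSE]) else rep(0, nrow(x)))
  } else {
    if (length(x) > 0 && max(c(ip, im, 0)) > length(x))
      stop("bad_mask: edge index beyond edge vector length")
    c(pos_sum = sum(x[ip]), neg_sum = sum(x[im]))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Consensus connectome across folds
#'
#' Merges the per-fold selection masks of a fitted CPM: an edge enters the
#' consensus iff it was selected with the same sign in at least `fraction`
#' of the cross-validation folds. `fraction = 1` is the intersection;
#' as `fraction` approaches 0 the union is recovered.
#'
#' @param fit a [cpm()] fit with fold masks.
#' @param fraction required fraction of folds, in (0, 1].
#' @return List with `positive` and `negative` integer edge-index vectors,
#'   plus per-edge selection counts as attributes.
#' @export
consensus_connectome <- function(fit, fraction = 1) {
  stopifnot(inherits(fit, "cpm"))
  if (!(fraction > 0 && fraction <= 1))
    stop("bad_consensus_fraction: need 0 < fraction <= 1")
  n <- fit$n
  count_of <- function(masks) {
    cnt <- integer(fit$n_edges)
    for (m in masks) cnt[m] <- cnt[m] + 1L
    cnt
  }
  cp <- count_of(fit$fold_masks$positive)
  cn <- count_of(fit$fold_masks$negative)
  need <- fraction * n - 1e-9      # tolerate fraction = k/n exactly
  structure(list(positive = which(cp >= need), negative = which(cn >= need)),
            counts_pos = cp, counts_neg = cn)
}

# ------------------------------ S3 methods -------------------------------

#' @export
print.cpm <- function(x, ...) {
  cat(sprintf("Connectome-based predictive model: %d subjects, %d edges\n",
              x$n, x$n_edges))
  cat(sprintf("  selection alpha %.3g | LOOCV | %s\n", x$alpha,
              if (x$n_perm > 0) sprintf("%d permutations", x$n_perm)
              else "no permutation test"))
  for (m in colnames(x$predictions)) {
    cat(sprintf("  %-9s model: r(obs, pred) = %+.3f%s\n", m, x$r_obs[m],
                if (!is.na(x$p_perm[m]))
                  sprintf(", one-tailed perm p = %.4g", x$p_perm[m]) else ""))
  }
  cat(sprintf("  consensus connectome (fraction %.2f): %d positive, %d negative edges\n",
              x$consensus_fraction, length(x$consensus$positive),
              length(x$consensus$negative)))
  if (x$n_empty_folds > 0)
    cat(sprintf("  note: %d fold(s) had empty masks and predicted the training mean\n",
                x$n_empty_folds))
  invisible(x)
}

#' @export
summary.cpm <- function(object, ...) {
  sel_sizes_p <- lengths(object$fold_masks$positive)
  sel_sizes_n <- lengths(object$fold_masks$negative)
  out <- list(fit = object,
              fold_mask_sizes = list(
                positive = summary(sel_sizes_p), negative = summary(sel_sizes_n)),
              coef = coef(object))
  class(out) <- "summary.cpm"
  out
}

#' @export
print.summary.cpm <- function(x, ...) {
  print(x$fit)
  cat("  per-fold selected edges (positive): ")
  print(x$fold_mask_sizes$positive)
  cat("  per-fold selected edges (negative): ")
  print(x$fold_mask_sizes$negative)
  cat("  full-sample model coefficients:\n")
  print(x$coef)
  invisible(x)
}

#' @export
coef.cpm <- function(object, ...) {
  list(positive = object$full_fit$positive$coef,
       negative = object$full_fit$negative$coef,
       combined = object$full_fit$combined$coef)
}

#' @export
fitted.cpm <- function(object, model = "positive", ...) {
  object$predictions[, model]
}

#' @export
residuals.cpm <- function(object, model = "positive", ...) {
  object$observed - object$predictions[, model]
}

#' Predict behavior for new subjects
#'
#' Applies the full-sample model (selection and coefficients estimated on all
#' training subjects) to new edge vectors. Note this is out-of-sample
#' application of an already-fitted model; the cross-validated predictions
#' for the training subjects themselves are in `fit$predictions`.
#'
#' @param object a [cpm()] fit.
#' @param newdata subjects x edges matrix with the same edge ordering.
#' @param model `"positive"`, `"negative"`, or `"combined"`.
#' @param ... unused.
#' @return Numeric vector of predicted behavior.
#' @export
predict.cpm <- function(object, newdata, model = c("positive", "negative", "combined"),
                        ...) {
  model <- match.arg(model)
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_edges)
    stop("length_mismatch: newdata has ", ncol(X), " edges, model expects ",
         object$n_edges)
  ff <- object$full_fit
  if (model == "combined") {
    if (is.null(ff$combined$coef))
      stop("empty_mask: combined model unavailable (one tail selected no edges)")
    fp <- rowSums(X[, ff$selection$positive, drop = FALSE])
    fn <- rowSums(X[, ff$selection$negative, drop = FALSE])
    cf <- ff$combined$coef
    return(unname(cf[1L] + cf[2L] * fp + cf[3L] * fn))
  }
  sub <- ff[[model]]
  f <- if (length(sub$edges)) rowSums(X[, sub$edges, drop = FALSE]) else rep(0, nrow(X))
  unname(sub$coef["intercept"] + sub$coef["slope"] * f)
}

#' @export
plot.cpm <- function(x, model = "positive", ...) {
  p <- x$predictions[, model]
  graphics::plot(p, x$observed,
                 xlab = "cross-validated prediction",
                 ylab = "observed behavior",
                 main = sprintf("CPM %s model: r = %.3f%s", model, x$r_obs[model],
                                if (!is.na(x$p_perm[model]))
                                  sprintf(", perm p = %.3g", x$p_perm[model]) else ""),
                 ...)
  if (stats::sd(p) > 0) graphics::abline(stats::lm(x$observed ~ p), lty = 2)
  invisible(x)
}

#' Permutation test for an existing CPM configuration
#'
#' Convenience wrapper: runs [cpm()] with a permutation test and returns the
#' one-tailed p-values. The full pipeline (per-fold selection, fitting,
#' prediction) is re-run for every permuted behavior vector, and
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams cpm.default
#' @return Named vector of one-tailed permutation p-values for the positive,
#'   negative and combined models.
#' @export
cpm_permutation_test <- function(x, y, alpha = 0.01, n_perm = 1000, seed = NULL) {
  fit <- cpm.default(x, y, alpha = alpha, n_perm = n_perm, seed = seed,
                     permute = TRUE)
  fit$p_perm
}
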