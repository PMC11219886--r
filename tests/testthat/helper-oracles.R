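# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: selection via
# cor.test per edge, per-fold refits via lm(), counts via explicit loops.

# full CPM leave-one-out pipeline, the slow obvious way
oracle_cpm_loocv <- function(X, y, alpha) {
  n <- nrow(X); E <- ncol(X)
  pred <- matrix(NA_real_, n, 3)
  masks_pos <- vector("list", n)
  masks_neg <- vector("list", n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    r <- numeric(E); p <- numeric(E)
    for (e in seq_len(E)) {
      ct <- suppressWarnings(stats::cor.test(Xtr[, e], ytr))
      r[e] <- unname(ct$estimate); p[e] <- ct$p.value
    }
    ip <- which(r > 0 & p < alpha)
    im <- which(r < 0 & p < alpha)
    masks_pos[[i]] <- ip; masks_neg[[i]] <- im
    pred1 <- function(idx) {
      if (!length(idx)) return(mean(ytr))
      f <- rowSums(X[, idx, drop = FALSE])
      d <- data.frame(yy = ytr, ff = f[-i])
      m <- stats::lm(yy ~ ff, data = d)
      unname(stats::predict(m, newdata = data.frame(ff = f[i])))
    }
    pred[i, 1] <- pred1(ip)
    pred[i, 2] <- pred1(im)
    if (length(ip) && length(im)) {
      fp <- rowSums(X[, ip, drop = FALSE])
      fn <- rowSums(X[, im, drop = FALSE])
      d <- data.frame(yy = ytr, fp = fp[-i], fn = fn[-i])
      m <- stats::lm(yy ~ fp + fn, data = d)
      pred[i, 3] <- unname(stats::predict(m, newdata = data.frame(fp = fp[i], fn = fn[i])))
    } else {
      pred[i, 3] <- if (length(ip)) pred[i, 1] else pred[i, 2]
    }
  }
  list(pred = pred, masks_pos = masks_pos, masks_neg = masks_neg)
}

# element-by-element Pearson + Fisher-z matrix
oracle_fc <- function(ts) {
  n <- nrow(ts)
  z <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    r <- stats::cor(ts[i, ], ts[j, ])
    r <- min(max(r, -0.999999), 0.999999)
    z[i, j] <- atanh(r)
  }
  z
}

# network-pair edge counts by explicit double loop over node pairs
oracle_pair_counts <- function(mask_idx, parc) {
  n <- nrow(parc)
  lev <- levels(parc$network)
  counts <- setNames(integer(length(all_network_pairs())), all_network_pairs())
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    k <- k + 1L
    if (k %in% mask_idx) {
      ab <- sort(c(as.integer(parc$network[i]), as.integer(parc$network[j])))
      key <- paste(lev[ab[1]], lev[ab[2]], sep = "-")
      counts[key] <- counts[key] + 1L
    }
  }
  counts
}

# per-node degree by explicit loop
oracle_degree <- function(mask_idx, n_nodes) {
  deg <- integer(n_nodes)
  k <- 0L
  for (i in seq_len(n_nodes - 1L)) for (j in (i + 1L):n_nodes) {
    k <- k + 1L
    if (k %in% mask_idx) { deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L }
  }
  deg
}

# a structurally plausible random hypnogram for property tests
random_hypnogram <- function(n_ep = sample(60:200, 1), subject_id = "rx") {
  stages <- c(rep("W", sample(1:8, 1)),
              sample(c("N1", "N2", "N3", "R", "W"), n_ep,
                     replace = TRUE, prob = c(.08, .45, .2, .2, .07)))
  hypnogram(stages[seq_len(n_ep)], lights_off = "23:00",
            subject_id = subject_id)
}

# the reduced-scale study configuration used by the heavier simulation tests:
# analyzed sample size of the reference design (33/41/36), ~1000 edges
study_config <- function(beta, edge_noise_sd, seed, dmn_group_delta = 0,
                         n_per_group = c(FS = 33, early_dep = 41, late_dep = 36)) {
  cohort_config(n_per_group = n_per_group, n_nodes = 46, n_planted = 40,
                beta = beta, edge_noise_sd = edge_noise_sd,
                dmn_group_delta = dmn_group_delta, seed = seed)
}

# Null-cohort permutation p-values (positive model), computed once per test
# run and shared by the calibration and uniformity checks.
null_perm_pvalues <- local({
  cache <- NULL
  function(n_rep = 200, n_perm = 199) {
    if (!is.null(cache)) return(cache)
    ps <- vapply(seq_len(n_rep), function(s) {
      coh <- generate_cohort(study_config(beta = 0, edge_noise_sd = 0.1,
                                          seed = 5000 + s))
      fit <- cpm(coh, n_perm = n_perm, seed = s)
      fit$p_perm[["positive"]]
    }, numeric(1))
    cache <<- ps
    ps
  }
})
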