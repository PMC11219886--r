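# Connectome-based predictive modeling: selection, features, LOOCV,
# permutation, consensus.

test_that("edge selection matches a brute-force correlation scan", {
  # printed 5-subject x 4-edge fixture
  X <- matrix(c(1.0, 2.1, 2.9, 4.2, 5.1,    # tracks behavior
                0.3, -0.1, 0.2, 0.0, 0.1,   # noise
                5.0, 4.1, 3.1, 1.9, 1.2,    # anti-tracks behavior
                1.0, 1.1, 0.9, 1.0, 1.05),  # near-constant
              nrow = 5)
  y <- c(1, 2, 3, 4, 5)
  sel <- select_edges(X, y, alpha = 0.01)
  r_ref <- apply(X, 2, function(e) cor.test(e, y)$estimate)
  p_ref <- apply(X, 2, function(e) cor.test(e, y)$p.value)
  expect_identical(sel$positive, which(r_ref > 0 & p_ref < 0.01))
  expect_identical(sel$negative, which(r_ref < 0 & p_ref < 0.01))
  expect_equal(sel$r, unname(r_ref), tolerance = 1e-12)
  expect_equal(sel$p, unname(p_ref), tolerance = 1e-12)
  expect_length(intersect(sel$positive, sel$negative), 0)

  # noiseless copy of an edge is selected with p ~ 0
  sel2 <- select_edges(X, X[, 1], alpha = 0.01)
  expect_true(1 %in% sel2$positive)
  expect_lt(sel2$p[1], 1e-12)
  expect_error(select_edges(X, rep(1, 5)), "constant_behavior")
})

test_that("selection count is calibrated under the null", {
  set.seed(77)
  E <- 5000; n <- 30; alpha <- 0.01
  counts <- replicate(50, {
    X <- matrix(rnorm(n * E), n, E)
    y <- rnorm(n)
    sel <- select_edges(X, y, alpha)
    length(sel$positive) + length(sel$negative)
  })
  # mean count ~ Binomial(E, alpha) mean with two-tail selection
  expect_lt(abs(mean(counts) - alpha * E), 4 * sqrt(alpha * E / 50))
})

test_that("strength features sum masked edges", {
  x <- c(0.5, -0.2, 0.3, 0.1)
  expect_equal(strength_features(x, list(positive = integer(0), negative = integer(0))),
               c(pos_sum = 0, neg_sum = 0))
  expect_equal(strength_features(x, list(positive = 1L, negative = integer(0)))[["pos_sum"]],
               0.5)
  set.seed(3)
  X <- matrix(rnorm(6 * 10), 6, 10)
  mask <- list(positive = c(2L, 5L, 9L), negative = c(1L, 10L))
  f <- strength_features(X, mask)
  expect_equal(f[, "pos_sum"], rowSums(X[, mask$positive]))
  expect_equal(f[, "neg_sum"], rowSums(X[, mask$negative]))
})

test_that("LOOCV predictions and per-fold masks equal the brute-force oracle", {
  set.seed(12)
  n <- 12; nodes <- 20; E <- n_edges(nodes)
  X <- matrix(rnorm(n * E, 0, 0.2), n, E)
  planted <- c(4L, 50L, 101L)
  y <- rnorm(n, 50, 10)
  X[, planted] <- X[, planted] + 0.15 * as.vector(scale(y))
  fit <- cpm(X, y, alpha = 0.05, permute = FALSE)
  oracle <- oracle_cpm_loocv(X, y, alpha = 0.05)
  expect_equal(unname(fit$predictions), oracle$pred, tolerance = 1e-8)
  for (i in seq_len(n)) {
    expect_identical(fit$fold_masks$positive[[i]], oracle$masks_pos[[i]])
    expect_identical(fit$fold_masks$negative[[i]], oracle$masks_neg[[i]])
  }
  expect_equal(fit$r_obs[["positive"]], cor(oracle$pred[, 1], y), tolerance = 1e-8)
})

test_that("a perfect linear signal is predicted with r = 1", {
  set.seed(8)
  n <- 14; E <- 10
  X <- matrix(rnorm(n * E), n, E)
  y <- 2 + 3 * X[, 3]   # behavior IS one edge's strength, no noise
  # stringent alpha: the exact edge has p = 0 and is always selected, while
  # null edges cannot sneak in and perturb the perfect fit
  fit <- cpm(X, y, alpha = 1e-6, permute = FALSE)
  expect_true(all(vapply(fit$fold_masks$positive, identical, TRUE, 3L)))
  expect_equal(fit$r_obs[["positive"]], 1, tolerance = 1e-9)
  expect_equal(unname(fit$predictions[, "positive"]), y, tolerance = 1e-9)
})

test_that("no information leaks from the held-out subject", {
  set.seed(19)
  n <- 15; E <- 100
  X <- matrix(rnorm(n * E), n, E)
  y <- rnorm(n) + 0.5 * X[, 1]
  fit <- cpm(X, y, alpha = 0.1, permute = FALSE)
  i <- 6L
  y2 <- y; y2[i] <- y2[i] + 1000   # wreck the held-out behavior value
  fit2 <- cpm(X, y2, alpha = 0.1, permute = FALSE)
  expect_identical(fit$fold_masks$positive[[i]], fit2$fold_masks$positive[[i]])
  expect_identical(fit$fold_masks$negative[[i]], fit2$fold_masks$negative[[i]])
  expect_equal(fit$predictions[i, ], fit2$predictions[i, ], tolerance = 1e-9)
})

test_that("empty-mask folds predict the training mean", {
  set.seed(30)
  n <- 12; E <- 20
  X <- matrix(rnorm(n * E), n, E)
  y <- rnorm(n)
  fit <- cpm(X, y, alpha = 1e-8, permute = FALSE)   # nothing survives selection
  expect_equal(fit$n_empty_folds, n)
  for (i in seq_len(n))
    expect_equal(unname(fit$predictions[i, "positive"]), mean(y[-i]),
                 tolerance = 1e-12)
  # training-mean predictions are an affine decreasing function of the
  # held-out value, so the observed-vs-predicted correlation is exactly -1 --
  # the extreme case of the well-known negative bias of LOOCV under the null
  expect_equal(fit$r_obs[["positive"]], -1, tolerance = 1e-12)
})

test_that("prediction quality is monotone in the planted effect size", {
  betas <- c(0, 0.05, 0.1, 0.2)
  mean_r <- sapply(betas, function(b) {
    mean(sapply(1:20, function(s) {
      cfg <- cohort_config(n_per_group = c(FS = 12, early_dep = 12, late_dep = 12),
                           n_nodes = 30, n_planted = 12, beta = b,
                           edge_noise_sd = 0.1, seed = 700 + s)
      coh <- generate_cohort(cfg)
      cpm(coh, permute = FALSE)$r_obs[["positive"]]
    }))
  })
  expect_true(all(diff(mean_r) > 0))
  expect_lt(mean_r[1], 0.05)          # null at/below zero (LOOCV bias)
  expect_gt(mean_r[4], 0.8)           # strong signal clearly recovered
})

test_that("permutation p hits the floor on strong signal and is seed-stable", {
  cfg <- cohort_config(n_per_group = c(FS = 12, early_dep = 12, late_dep = 12),
                       n_nodes = 30, n_planted = 12, beta = 0.2,
                       edge_noise_sd = 0.1, seed = 44)
  coh <- generate_cohort(cfg)
  fit <- cpm(coh, n_perm = 199, seed = 10)
  expect_equal(fit$p_perm[["positive"]], 1 / 200)
  fit2 <- cpm(coh, n_perm = 199, seed = 10)
  expect_identical(fit$p_perm, fit2$p_perm)
  expect_true(all(fit$p_perm >= 1 / 200 & fit$p_perm <= 1))
})

test_that("null permutation p-values are uniform (KS)", {
  ps <- null_perm_pvalues()
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("consensus mask interpolates between intersection and union", {
  set.seed(55)
  n <- 12; E <- 80
  X <- matrix(rnorm(n * E), n, E)
  y <- rnorm(n) + 0.8 * X[, 5]
  fit <- cpm(X, y, alpha = 0.2, permute = FALSE)
  strict <- consensus_connectome(fit, 1)
  loose <- consensus_connectome(fit, 1e-9)
  union_pos <- sort(unique(unlist(fit$fold_masks$positive)))
  inter_pos <- Reduce(intersect, fit$fold_masks$positive)
  expect_identical(loose$positive, union_pos)
  expect_identical(strict$positive, sort(inter_pos))
  expect_true(all(strict$positive %in% loose$positive))
  expect_error(consensus_connectome(fit, 0), "bad_consensus_fraction")
})

test_that("cpm rejects degenerate input and small samples", {
  X <- matrix(rnorm(8 * 10), 8, 10)
  expect_error(cpm(X, rnorm(8)), "too_few_subjects")
  X2 <- matrix(rnorm(12 * 10), 12, 10)
  expect_error(cpm(X2, rep(2, 12)), "constant_behavior")
  expect_error(cpm(X2, rnorm(11)), "length_mismatch")
  expect_error(cpm(X2, rnorm(12), n_perm = 10), "bad_n_perm")
})

test_that("cpm methods expose the fit coherently", {
  cfg <- cohort_config(n_per_group = c(FS = 8, early_dep = 8, late_dep = 8),
                       n_nodes = 30, n_planted = 8, beta = 0.3, seed = 3)
  coh <- generate_cohort(cfg)
  fit <- cpm(coh, permute = FALSE)
  expect_s3_class(fit, "cpm")
  expect_output(print(fit), "Connectome-based predictive model")
  expect_output(print(summary(fit)), "per-fold selected edges")
  expect_named(coef(fit), c("positive", "negative", "combined"))
  expect_length(fitted(fit), 24)
  expect_equal(residuals(fit), coh$behavior$rem_duration_min - fitted(fit))

  # out-of-sample predict: applying the full model to the training matrix
  # correlates strongly with behavior under strong planted signal
  pr <- predict(fit, coh$edges, model = "positive")
  expect_length(pr, 24)
  expect_gt(cor(pr, coh$behavior$rem_duration_min), 0.9)
  expect_error(predict(fit, coh$edges[, 1:10]), "length_mismatch")

  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f)); unlink(f)
})
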