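# Group-level comparisons: ANOVA, correction, post-hoc contrasts, and the
# summary-statistic Welch t utilities.

test_that("pair strengths are mask-restricted means", {
  p <- default_parcellation(30)
  z <- devectorize_fc(rep(0, n_edges(30)))
  dmn <- which(p$network == "DMN")
  e1 <- edge_index(dmn[1], dmn[2], 30)
  e2 <- edge_index(dmn[3], dmn[4], 30)
  v <- rep(0, n_edges(30)); v[e1] <- 0.2; v[e2] <- 0.6
  z <- devectorize_fc(v)
  expect_equal(pair_strength(z, c(e1, e2), "DMN-DMN", p), 0.4)
  expect_equal(pair_strength(z, e1, "DMN-DMN", p), 0.2)
  expect_error(pair_strength(z, e1, "VIS-VIS", p), "empty_pair")

  set.seed(2)
  X <- matrix(rnorm(8 * n_edges(30)), 8)
  S <- pair_strengths(X, c(e1, e2), p)
  expect_equal(unname(S[, "DMN-DMN"]), rowMeans(X[, c(e1, e2)]))
})

test_that("one-way ANOVA agrees with aov and handles degeneracy", {
  set.seed(5)
  vals <- rnorm(30); grp <- rep(c("a", "b", "c"), 10)
  res <- anova_across_groups(vals, grp)
  ref <- summary(aov(vals ~ factor(grp)))[[1]]
  expect_equal(res$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 27)

  # all-identical data: F reported as 0, p as 1
  dg <- anova_across_groups(rep(1, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(dg$F, 0)
  expect_equal(dg$p, 1)
  expect_error(anova_across_groups(1:5, c("a", "a", "a", "a", "b")),
               "too_few_subjects")
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(6)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  res <- anova_across_groups(c(a, b), rep(c("g1", "g2"), c(12, 15)))
  tt <- posthoc_t(a, b, pooled = TRUE)
  expect_equal(res$F, tt$t^2, tolerance = 1e-9)
})

test_that("ANOVA type-I error is calibrated under the null", {
  set.seed(61)
  rej <- mean(replicate(200, {
    v <- rnorm(45)
    anova_across_groups(v, rep(c("a", "b", "c"), each = 15))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.05)
})

test_that("multiple-comparison correction follows BH and Bonferroni exactly", {
  expect_equal(correct_multiple(0.03, "BH"), 0.03)
  expect_equal(correct_multiple(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))   # hand-applied BH: min_k>=i p_k * m / k
  expect_equal(correct_multiple(rep(0.001, 32), "bonferroni")[1], 0.032)
  p <- runif(20)
  expect_true(all(correct_multiple(p, "BH") >= p))
  expect_error(correct_multiple(c(0.5, 1.2)), "bad_pvalues")
})

test_that("posthoc t handles identical, separated and jittered samples", {
  same <- posthoc_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0); expect_equal(same$p, 1); expect_equal(same$cohen_d, 0)

  set.seed(8)
  a <- rnorm(6, 0, 1e-3); b <- 1 + rnorm(6, 0, 1e-3)
  sep <- posthoc_t(a, b)
  expect_gt(abs(sep$cohen_d), 50)
  expect_lt(sep$p, 1e-6)
})

test_that("Welch t from raw samples equals the summary-statistic formula", {
  set.seed(9)
  for (rep in 1:10) {
    a <- rnorm(sample(5:30, 1), 10, 3)
    b <- rnorm(sample(5:30, 1), 12, 5)
    raw <- posthoc_t(a, b)
    summ <- welch_t_from_summary(mean(a), sd(a), length(a),
                                 mean(b), sd(b), length(b))
    expect_equal(raw$t, summ$t, tolerance = 1e-12)
    expect_equal(raw$df, summ$df, tolerance = 1e-12)
    expect_equal(raw$p, summ$p, tolerance = 1e-12)
  }
})

test_that("summary-statistic t follows the closed-form scaling laws", {
  expect_equal(welch_t_from_summary(5, 1, 10, 5, 2, 12)$t, 0)
  t1 <- welch_t_from_summary(24.41, 6.56, 41, 15.18, 5.31, 36)$t
  t2 <- welch_t_from_summary(24.41, 6.56, 82, 15.18, 5.31, 72)$t
  expect_equal(t2 / t1, sqrt(2), tolerance = 1e-12)
  expect_error(welch_t_from_summary(1, 0, 5, 2, 1, 5), "bad_sd")

  # simulated-group means agree with the closed form applied to the
  # population parameters (averaged over replicates)
  set.seed(10)
  tsim <- mean(replicate(500, {
    a <- rnorm(41, 24.41, 6.56); b <- rnorm(36, 15.18, 5.31)
    posthoc_t(a, b)$t
  }))
  tform <- welch_t_from_summary(24.41, 6.56, 41, 15.18, 5.31, 36)$t
  expect_lt(abs(tsim - tform) / tform, 0.05)
})

test_that("edge-level ANOVA ranks group-shifted edges above unshifted", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(500 + s)
    p <- default_parcellation(60)
    grp <- rep(c("FS", "early_dep", "late_dep"), each = 12)
    X <- matrix(rnorm(36 * n_edges(60), 0, 0.1), 36)
    dmn <- which(p$network == "DMN")
    mask <- edge_index(rep(dmn[1], 6), dmn[2:7], 60)
    shifted <- mask[1:3]
    X[grp == "late_dep", shifted] <- X[grp == "late_dep", shifted] - 0.2
    tab <- edge_level_anova(X, grp, mask, "DMN-DMN", p)
    expect_equal(nrow(tab), 6)
    expect_true(all(tab$p_corrected >= tab$p))
    top3 <- tab$edge[order(-tab$F)][1:3]
    if (setequal(top3, shifted)) hits <- hits + 1L
  }
  expect_gte(hits, 18)   # >= 90% of seeds

  # single-edge pair: corrected p equals raw p
  set.seed(99)
  p <- default_parcellation(30)
  dmn <- which(p$network == "DMN")
  one <- edge_index(dmn[1], dmn[2], 30)
  X <- matrix(rnorm(30 * n_edges(30)), 30)
  tab1 <- edge_level_anova(X, rep(c("a", "b", "c"), 10), one, "DMN-DMN", p)
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$p_corrected, tab1$p)
})

test_that("compare_groups gatekeeps post-hoc tests on corrected significance", {
  cfg <- cohort_config(n_per_group = c(FS = 12, early_dep = 12, late_dep = 12),
                       n_nodes = 30, n_planted = 12, beta = 0.02,
                       edge_noise_sd = 0.1, dmn_group_delta = 0.4, seed = 77)
  coh <- generate_cohort(cfg)
  mask <- coh$planted_edges
  res <- compare_groups(coh, mask = mask)
  expect_s3_class(res, "group_comparison")
  expect_true(all(res$anova$df1 == 2))
  expect_true(all(res$anova$df2 == 33))
  expect_equal(sort(names(res$posthoc)), sort(res$anova$pair[res$anova$significant]))
  # strong planted DMN deficit in late_dep must surface
  expect_true("DMN-DMN" %in% res$anova$pair[res$anova$significant])
  ph <- res$posthoc[["DMN-DMN"]]
  expect_named(ph, c("FS vs early_dep", "FS vs late_dep", "early_dep vs late_dep"))
  expect_output(print(res), "Group comparison")
})
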