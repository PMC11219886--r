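# Multi-level characterization of a connectome mask.

make_profile_fixture <- function(seed = 1, n_nodes = 30, n_sub = 20) {
  set.seed(seed)
  p <- default_parcellation(n_nodes)
  X <- matrix(rnorm(n_sub * n_edges(n_nodes), 0, 0.2), n_sub)
  y <- rnorm(n_sub)
  list(p = p, X = X, y = y)
}

test_that("single-edge masks give the degenerate profiles exactly", {
  fx <- make_profile_fixture()
  dmn <- which(fx$p$network == "DMN")
  vis <- which(fx$p$network == "VIS")
  e_dd <- edge_index(dmn[1], dmn[2], 30)
  e_dv <- edge_index(dmn[1], vis[1], 30)

  pe <- pair_edge_profile(e_dd, fx$p)
  expect_equal(nrow(pe$table), 55)
  expect_equal(pe$table$normalized_edge_share[pe$table$pair == "DMN-DMN"], 1)
  expect_equal(sum(pe$table$normalized_edge_share), 1)
  one_hot <- c(1, rep(0, 54))
  expect_equal(pe$share_variance, mean((one_hot - mean(one_hot))^2))

  ns <- network_shares(e_dv, fx$p)
  expect_equal(ns$endpoint_share[ns$network == "DMN"], 0.5)
  expect_equal(ns$endpoint_share[ns$network == "VIS"], 0.5)
  ns2 <- network_shares(e_dd, fx$p)
  expect_equal(ns2$endpoint_share[ns2$network == "DMN"], 1)

  pc <- pair_contribution(fx$X, fx$y, e_dd, fx$p)
  expect_equal(nrow(pc$table), 1)
  expect_equal(pc$table$normalized_contribution, 1)
  expect_equal(pc$contribution_variance, 0)

  expect_error(pair_edge_profile(integer(0), fx$p), "empty_mask")
})

test_that("uniform all-edge mask reproduces combinatorial pair sizes", {
  fx <- make_profile_fixture()
  all_e <- seq_len(n_edges(30))
  pe <- pair_edge_profile(all_e, fx$p)
  expect_equal(sum(pe$table$edge_count), n_edges(30))
  expect_equal(sum(pe$table$normalized_edge_share), 1, tolerance = 1e-9)
  sz <- table(fx$p$network)
  expect_equal(pe$table$edge_count[pe$table$pair == "DMN-DMN"],
               as.integer(choose(sz[["DMN"]], 2)))
  expect_equal(pe$table$edge_count[pe$table$pair == "DMN-VIS"],
               as.integer(sz[["DMN"]] * sz[["VIS"]]))
})

test_that("conservation identities hold on random masks", {
  fx <- make_profile_fixture(seed = 4)
  set.seed(9)
  for (rep in 1:100) {
    mask <- sample(n_edges(30), sample(5:80, 1))
    pe <- pair_edge_profile(mask, fx$p)
    expect_equal(sum(pe$table$normalized_edge_share), 1, tolerance = 1e-9)
    expect_equal(sum(pe$table$edge_count), length(mask))
    ns <- network_shares(mask, fx$p)
    expect_equal(sum(ns$endpoint_share), 1, tolerance = 1e-9)
    rp <- regional_profile(fx$X, fx$y, mask, fx$p)
    expect_equal(sum(rp$table$regional_degree), 2 * length(mask))
  }
})

test_that("profiles match brute-force enumeration oracles", {
  fx <- make_profile_fixture(seed = 6)
  set.seed(10)
  mask <- sample(n_edges(30), 25)
  pe <- pair_edge_profile(mask, fx$p)
  cnt <- oracle_pair_counts(mask, fx$p)
  expect_equal(pe$table$edge_count, unname(as.integer(cnt)))
  rp <- regional_profile(fx$X, fx$y, mask, fx$p)
  expect_equal(rp$table$regional_degree, oracle_degree(mask, 30))
})

test_that("star mask gives hub degree k and spoke degree 1", {
  fx <- make_profile_fixture(seed = 7)
  hub <- 3L; spokes <- c(1L, 2L, 8L, 15L, 22L)
  mask <- edge_index(rep(hub, 5), spokes, 30)
  rp <- regional_profile(fx$X, fx$y, mask, fx$p)
  expect_equal(rp$table$regional_degree[hub], 5L)
  expect_equal(rp$table$regional_degree[spokes], rep(1L, 5))
  expect_equal(sum(rp$table$regional_degree), 10L)
  expect_equal(rp$table$regional_contribution[rp$table$regional_degree == 0],
               rep(0, sum(rp$table$regional_degree == 0)))
})

test_that("contributions separate planted from null pairs and respect symmetry", {
  sep <- 0L; sym_ok <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    p <- default_parcellation(60)
    n_sub <- 40
    y <- rnorm(n_sub)
    X <- matrix(rnorm(n_sub * n_edges(60), 0, 0.1), n_sub)
    dmn <- which(p$network == "DMN"); vis <- which(p$network == "VIS")
    smn <- which(p$network == "SMN")
    e_dmn <- edge_index(dmn[1:3], dmn[4:6], 60)           # planted DMN-DMN
    e_vis <- edge_index(vis[1:3], vis[4:6], 60)           # planted VIS-VIS
    e_null <- edge_index(smn[1:3], smn[4:6], 60)          # no signal
    X[, c(e_dmn, e_vis)] <- X[, c(e_dmn, e_vis)] + 0.1 * scale(y)[, 1]
    mask <- c(e_dmn, e_vis, e_null)
    pc <- pair_contribution(X, y, mask, p)
    cd <- pc$table$contribution_r[pc$table$pair == "DMN-DMN"]
    cv <- pc$table$contribution_r[pc$table$pair == "VIS-VIS"]
    cn <- pc$table$contribution_r[pc$table$pair == "SMN-SMN"]
    if (cd > cn && cv > cn) sep <- sep + 1L
    if (abs(cd - cv) < 0.35) sym_ok <- sym_ok + 1L
  }
  expect_gte(sep, 19)        # planted beats null in >= 95% of seeds
  expect_gte(sym_ok, 18)     # equal-beta pairs contribute comparably
})

test_that("regional tables are node-permutation equivariant", {
  fx <- make_profile_fixture(seed = 12, n_nodes = 20)
  set.seed(13)
  mask <- sample(n_edges(20), 12)
  rp <- regional_profile(fx$X, fx$y, mask, fx$p)

  perm <- sample(20)          # node relabeling: new id of old node v is match(v, perm)
  # rebuild edges under permuted node order
  Z <- lapply(seq_len(nrow(fx$X)), function(s) devectorize_fc(fx$X[s, ]))
  Xp <- t(vapply(Z, function(z) vectorize_fc(z[perm, perm]), numeric(n_edges(20))))
  pp <- parcellation(as.character(fx$p$network)[perm])
  ij <- edge_endpoints(mask, 20)
  new_i <- match(ij[, "i"], perm); new_j <- match(ij[, "j"], perm)
  mask_p <- edge_index(new_i, new_j, 20)
  rp_p <- regional_profile(Xp, fx$y, mask_p, pp)
  expect_equal(rp_p$table$regional_degree, rp$table$regional_degree[perm])
  expect_equal(rp_p$table$regional_contribution,
               rp$table$regional_contribution[perm], tolerance = 1e-10)
})

test_that("characterize_connectome bundles all levels from a cpm fit", {
  cfg <- cohort_config(n_per_group = c(FS = 10, early_dep = 10, late_dep = 10),
                       n_nodes = 30, n_planted = 12, beta = 0.25, seed = 21)
  coh <- generate_cohort(cfg)
  fit <- cpm(coh, permute = FALSE)
  prof <- characterize_connectome(fit, coh$edges, coh$behavior$rem_duration_min)
  expect_s3_class(prof, "connectome_profile")
  expect_equal(nrow(prof$pairs), 55)
  expect_equal(nrow(prof$networks), 10)
  expect_equal(nrow(prof$regions), 30)
  expect_equal(sum(prof$pairs$normalized_edge_share), 1, tolerance = 1e-9)
  expect_equal(sum(prof$regions$regional_degree), 2 * prof$n_edges_in_mask)
  expect_length(prof$variances, 4)
  expect_output(print(prof), "Connectome characterization")
  # planted pairs dominate the edge-count profile under strong signal
  top <- prof$pairs$pair[order(-prof$pairs$edge_count)][1:4]
  expect_setequal(top, c("DMN-DMN", "DMN-VIS", "VIS-SUB", "CON-CON"))
})
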