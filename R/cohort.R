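# Synthetic split-night cohort generator.
#
# Emulates the study design the analysis pipeline assumes: three groups on
# fixed in-bed schedules (full sleep 23:00-08:00; early-night deprivation
# sleeps 03:00-07:30; late-night deprivation sleeps 23:00-03:30), hypnograms
# organized in ~90-min NREM/REM cycles whose REM fraction ramps up across the
# night, group-specific REM-duration distributions, and Fisher-z edge vectors
# in which a planted edge set carries a linear dependence on (standardized)
# REM duration plus independent Gaussian noise.

GROUPS <- c("FS", "early_dep", "late_dep")

SCHEDULES <- list(
  FS        = c(lights_off = "23:00", lights_on = "08:00"),
  early_dep = c(lights_off = "03:00", lights_on = "07:30"),
  late_dep  = c(lights_off = "23:00", lights_on = "03:30"))

#' Configuration of a synthetic split-night cohort
#'
#' All knobs of the generator, validated. Defaults mirror the reference study
#' design: group sizes 36/41/36 (full sleep / early-deprivation /
#' late-deprivation), 227 nodes over ten networks, 230-timepoint series, and
#' per-group REM-duration laws back-computed from group-level total sleep
#' time and REM percentage (approximations; see the package vignette).
#'
#' @param n_per_group named counts for `FS`, `early_dep`, `late_dep`.
#' @param rem_mean_sd named list; per group a `c(mean, sd)` of REM duration
#'   in minutes.
#' @param n_nodes number of connectome nodes.
#' @param network_sizes optional named node counts per network (see
#'   [default_network_sizes()]).
#' @param planted_edges optional integer vector of edge indices carrying the
#'   behavior signal; by default `n_planted` edges are drawn evenly from the
#'   DMN-DMN, DMN-VIS, SUB-VIS and CON-CON network pairs.
#' @param n_planted number of planted edges when `planted_edges` is `NULL`.
#' @param beta per-SD effect of REM duration on planted edge z-values.
#' @param edge_noise_sd residual SD of every edge z-value.
#' @param rho_within,rho_between baseline correlation level of
#'   within-/between-network edges (Fisher-z transformed to form the mean
#'   edge vector); requires `0 <= rho_between <= rho_within < 1`.
#' @param n_timepoints length of realized node time series.
#' @param dmn_group_delta reduction of the planted DMN-DMN edge means in the
#'   late-deprivation group (models a group-level connectivity deficit).
#' @param sl_mean_min,waso_mean_min per-group mean sleep latency and
#'   wake-after-sleep-onset, minutes.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return Object of class `"cohort_config"` (a validated list).
#' @export
cohort_config <- function(n_per_group = c(FS = 36, early_dep = 41, late_dep = 36),
                          rem_mean_sd = list(FS = c(102.2, 28.6),
                                             early_dep = c(61.3, 16.5),
                                             late_dep = c(38.2, 13.4)),
                          n_nodes = 227,
                          network_sizes = NULL,
                          planted_edges = NULL,
                          n_planted = 40,
                          beta = 0.1,
                          edge_noise_sd = 0.1,
                          rho_within = 0.25,
                          rho_between = 0.08,
                          n_timepoints = 230,
                          dmn_group_delta = 0,
                          sl_mean_min = c(FS = 8, early_dep = 5, late_dep = 10),
                          waso_mean_min = c(FS = 23, early_dep = 6.5, late_dep = 10),
                          seed = 1L) {
  stopifnot(setequal(names(n_per_group), GROUPS),
            setequal(names(rem_mean_sd), GROUPS))
  n_per_group <- n_per_group[GROUPS]
  if (any(n_per_group <= 0)) stop("bad_config: group counts must be > 0")
  for (g in GROUPS) {
    ms <- rem_mean_sd[[g]]
    if (length(ms) != 2L || ms[1] <= 0 || ms[2] <= 0)
      stop("bad_config: rem_mean_sd$", g, " must be c(mean > 0, sd > 0)")
  }
  if (!(rho_between >= 0 && rho_between <= rho_within && rho_within < 1))
    stop("bad_config: need 0 <= rho_between <= rho_within < 1")
  if (edge_noise_sd <= 0) stop("bad_config: edge_noise_sd must be > 0")
  if (n_timepoints < 2) stop("bad_config: n_timepoints must be >= 2")
  if (is.null(network_sizes)) network_sizes <- default_network_sizes(n_nodes)
  if (sum(network_sizes) != n_nodes)
    stop("bad_config: network_sizes must sum to n_nodes")
  if (!is.null(planted_edges)) {
    planted_edges <- as.integer(planted_edges)
    if (anyDuplicated(planted_edges))
      stop("bad_config: planted_edges must be distinct")
    if (any(planted_edges < 1L | planted_edges > n_edges(n_nodes)))
      stop("bad_config: planted edge outside the ", n_edges(n_nodes),
           "-edge range for ", n_nodes, " nodes")
  }
  structure(list(
    n_per_group = n_per_group, rem_mean_sd = rem_mean_sd, n_nodes = n_nodes,
    network_sizes = network_sizes, planted_edges = planted_edges,
    n_planted = as.integer(n_planted), beta = beta,
    edge_noise_sd = edge_noise_sd, rho_within = rho_within,
    rho_between = rho_between, n_timepoints = as.integer(n_timepoints),
    dmn_group_delta = dmn_group_delta, sl_mean_min = sl_mean_min[GROUPS],
    waso_mean_min = waso_mean_min[GROUPS], seed = as.integer(seed)),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  groups: FS=%d early_dep=%d late_dep=%d  | nodes: %d (%d edges)\n",
              x$n_per_group["FS"], x$n_per_group["early_dep"],
              x$n_per_group["late_dep"], x$n_nodes, n_edges(x$n_nodes)))
  cat(sprintf("  planted edges: %s | beta=%g | noise sd=%g | dmn delta=%g | seed=%d\n",
              if (is.null(x$planted_edges)) paste0(x$n_planted, " (auto)")
              else length(x$planted_edges),
              x$beta, x$edge_noise_sd, x$dmn_group_delta, x$seed))
  invisible(x)
}

# REM propensity ramps with circadian time, not time since each subject's own
# sleep onset: the cycle index is anchored to hours elapsed since 23:00, so a
# subject who starts sleeping at 03:00 enters the night in REM-rich cycles.
# Per cycle the REM fraction rises linearly 10% -> 35% over cycles 1..5.
rem_fraction_at <- function(hours_since_2300) {
  cyc <- floor(hours_since_2300 / 1.5) + 1
  pmin(0.10 + 0.0625 * (cyc - 1), 0.35)
}

#' Generate one night's hypnogram for a study group
#'
#' Simulates a 30-s-epoch stage sequence spanning exactly the group's in-bed
#' window: an initial wake run (sleep latency), sleep organized in ~90-min
#' cycles (N1/N2/N3 then REM, deep NREM front-loaded), a REM fraction that
#' rises across the night, brief awakenings after onset, and occasionally a
#' terminal wake run. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param group one of `"FS"`, `"early_dep"`, `"late_dep"`.
#' @param config a [cohort_config()].
#' @param subject_id identifier for the resulting hypnogram.
#' @return A [hypnogram()] spanning 540 min (1080 epochs) for `FS` and
#'   270 min (540 epochs) for the two deprivation groups.
#' @export
generate_hypnogram <- function(group, config = cohort_config(),
                               subject_id = "s001") {
  if (length(group) != 1L || !group %in% GROUPS)
    stop("unknown_group: '", paste(group, collapse = ","),
         "' (expected one of ", paste(GROUPS, collapse = ", "), ")")
  sch <- SCHEDULES[[group]]
  span <- minutes_after(sch["lights_off"], sch["lights_on"])
  n_ep <- as.integer(span * 2)                       # 30-s epochs
  offset_h <- minutes_after("23:00", sch["lights_off"]) / 60

  sl_ep <- 1L + stats::rpois(1L, max(config$sl_mean_min[[group]] * 2 - 1, 0))
  sl_ep <- min(sl_ep, n_ep - 2L)
  stages <- rep("W", sl_ep)

  cyc_count <- 0L
  while (length(stages) < n_ep) {
    cyc_count <- cyc_count + 1L
    hours_now <- offset_h + length(stages) * 0.5 / 60
    frac <- rem_fraction_at(hours_now) * stats::runif(1, 0.75, 1.25)
    len <- max(round(stats::rnorm(1, 180, 20)), 60)
    rem <- round(len * min(frac, 0.5))
    nrem <- len - rem
    n1 <- round(0.08 * nrem)
    n3 <- round(max(0.45 - 0.12 * (cyc_count - 1), 0.05) * nrem)
    n2 <- nrem - n1 - n3
    block <- c(rep("N1", n1), rep("N2", ceiling(n2 / 2)), rep("N3", n3),
               rep("N2", floor(n2 / 2)), rep("R", rem))
    stages <- c(stages, block)
  }
  stages <- stages[seq_len(n_ep)]

  # brief awakenings after onset
  nw <- stats::rpois(1L, config$waso_mean_min[[group]] * 2)
  eligible <- which(stages != "W")
  eligible <- eligible[eligible > sl_ep + 10L & eligible < n_ep - 10L]
  if (nw > 0 && length(eligible))
    stages[sample(eligible, min(nw, length(eligible)))] <- "W"

  # occasional terminal wake (waking before lights-on)
  if (stats::runif(1) < 0.6) {
    tw <- stats::rpois(1L, 4)
    if (tw > 0) stages[(n_ep - min(tw, 20L) + 1L):n_ep] <- "W"
  }

  hypnogram(stages, lights_off = unname(sch["lights_off"]),
            epoch_length_s = 30, subject_id = subject_id)
}

# Retarget a hypnogram's REM duration to `target_min` (to within one epoch)
# by converting randomly chosen REM epochs to N2 (excess) or NREM epochs to
# REM (deficit). Wake epochs are untouched, so TST, SL, WASO are preserved.
reconcile_rem <- function(h, target_min) {
  target_ep <- as.integer(round(target_min * 2))
  s <- h$stages
  rem_idx <- which(s == "R")
  sleep_ep <- sum(s != "W")
  target_ep <- max(1L, min(target_ep, as.integer(floor(sleep_ep * 0.6))))
  d <- target_ep - length(rem_idx)
  if (d < 0) {
    s[sample(rem_idx, -d)] <- "N2"
  } else if (d > 0) {
    pool <- which(s %in% c("N2", "N1", "N3"))
    # prefer converting N2; fall back to N1/N3 ordering implicit in pool
    pool <- pool[order(s[pool] != "N2")]
    take <- pool[seq_len(min(d, length(pool)))]
    s[take] <- "R"
  }
  hypnogram(s, lights_off = h$lights_off, epoch_length_s = h$epoch_length_s,
            subject_id = h$subject_id)
}

# default planted-edge placement: n_planted edges split evenly over the
# DMN-DMN, DMN-VIS, SUB-VIS and CON-CON network pairs; on small
# parcellations where a pair cannot host its quota, the surplus spills over
# to the remaining pairs (DMN-DMN first, which is always largest)
default_planted_edges <- function(parc, n_planted) {
  pairs <- c("DMN-DMN", "DMN-VIS", "VIS-SUB", "CON-CON")
  lab <- edge_network_pairs(parc)
  avail <- lapply(pairs, function(q) which(lab == q))
  cap <- lengths(avail)
  if (sum(cap) < n_planted)
    stop("bad_config: the DMN-DMN/DMN-VIS/VIS-SUB/CON-CON pairs hold only ",
         sum(cap), " edges; cannot plant ", n_planted)
  per <- rep(n_planted %/% 4L, 4L)
  extra <- n_planted %% 4L
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  # spill any over-quota remainder into pairs with spare capacity
  while (any(per > cap)) {
    over <- sum(pmax(per - cap, 0))
    per <- pmin(per, cap)
    room <- which(per < cap)
    for (q in room) {
      take <- min(cap[q] - per[q], over)
      per[q] <- per[q] + take
      over <- over - take
      if (over == 0) break
    }
  }
  out <- integer(0)
  for (q in seq_along(pairs)) if (per[q] > 0)
    out <- c(out, sample(avail[[q]], per[q]))
  sort(out)
}

#' Generate a synthetic split-night cohort
#'
#' Draws the full cohort: per-subject hypnograms on the group schedules,
#' REM durations from the configured per-group normal laws (reconciled into
#' each hypnogram by REM-epoch resampling, so recorded behavior and
#' hypnogram-derived behavior agree to within one epoch), and per-subject
#' Fisher-z edge vectors
#' \deqn{z_e = baseline_e + \beta\,\tilde b\,[e \in planted] + \epsilon_e,}
#' where the baseline is `atanh(rho_within)` or `atanh(rho_between)` by
#' network membership, \eqn{\tilde b} is the cohort-standardized REM
#' duration, and \eqn{\epsilon_e} is independent Gaussian noise. A nonzero
#' `dmn_group_delta` additionally lowers the planted DMN-DMN edge means for
#' late-deprivation subjects. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return Object of class `"rem_cohort"`: list with `behavior` (data frame:
#'   `subject_id`, `group`, `rem_duration_min`, `rem_proportion_pct`),
#'   `hypnograms` (named list), `edges` (subjects x edges matrix of Fisher-z
#'   values), `parcellation`, `planted_edges`, and the `config` echo.
#' @examples
#' cfg <- cohort_config(n_per_group = c(FS = 4, early_dep = 4, late_dep = 4),
#'                      n_nodes = 30, n_planted = 8, seed = 7)
#' coh <- generate_cohort(cfg)
#' coh$behavior
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  parc <- default_parcellation(config$n_nodes, config$network_sizes)
  planted <- config$planted_edges
  if (is.null(planted)) planted <- default_planted_edges(parc, config$n_planted)

  groups <- rep(GROUPS, times = config$n_per_group)
  n_sub <- length(groups)
  ids <- sprintf("s%03d", seq_len(n_sub))

  hyps <- vector("list", n_sub)
  rem_min <- numeric(n_sub)
  rem_pct <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    h <- generate_hypnogram(groups[s], config, subject_id = ids[s])
    ms <- config$rem_mean_sd[[groups[s]]]
    drawn <- stats::rnorm(1, ms[1], ms[2])
    h <- reconcile_rem(h, drawn)
    m <- rem_metrics(h)
    hyps[[s]] <- h
    rem_min[s] <- m$rem_duration_min
    rem_pct[s] <- m$rem_proportion_pct
  }
  names(hyps) <- ids

  E <- n_edges(config$n_nodes)
  pair_lab <- edge_network_pairs(parc)
  within <- sub("-.*", "", as.character(pair_lab)) ==
            sub(".*-", "", as.character(pair_lab))
  baseline <- ifelse(within, atanh(config$rho_within), atanh(config$rho_between))

  b_std <- as.vector(scale(rem_min))
  X <- matrix(stats::rnorm(n_sub * E, 0, config$edge_noise_sd), n_sub, E)
  X <- sweep(X, 2L, baseline, "+")
  X[, planted] <- X[, planted] + config$beta * b_std
  if (config$dmn_group_delta != 0) {
    dmn_planted <- planted[pair_lab[planted] == "DMN-DMN"]
    late <- groups == "late_dep"
    if (length(dmn_planted) && any(late))
      X[late, dmn_planted] <- X[late, dmn_planted] - config$dmn_group_delta
  }

  behavior <- data.frame(subject_id = ids, group = groups,
                         rem_duration_min = rem_min,
                         rem_proportion_pct = rem_pct,
                         stringsAsFactors = FALSE)
  structure(list(behavior = behavior, hypnograms = hyps, edges = X,
                 parcellation = parc, planted_edges = planted,
                 config = config),
            class = "rem_cohort")
}

#' @export
print.rem_cohort <- function(x, ...) {
  tab <- table(factor(x$behavior$group, levels = GROUPS))
  cat(sprintf("Synthetic REM cohort: %d subjects (FS=%d early_dep=%d late_dep=%d)\n",
              nrow(x$behavior), tab["FS"], tab["early_dep"], tab["late_dep"]))
  cat(sprintf("  %d nodes, %d edges, %d planted | seed %d\n",
              x$config$n_nodes, ncol(x$edges), length(x$planted_edges),
              x$config$seed))
  agg <- stats::aggregate(rem_duration_min ~ group, x$behavior, mean)
  cat("  mean REM duration (min): ",
      paste(sprintf("%s=%.1f", agg$group, agg$rem_duration_min), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Per-subject connectivity matrix from a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param subject subject id or row index.
#' @return The subject's symmetric Fisher-z matrix.
#' @export
cohort_fc_matrix <- function(cohort, subject) {
  stopifnot(inherits(cohort, "rem_cohort"))
  i <- if (is.character(subject)) match(subject, cohort$behavior$subject_id)
       else as.integer(subject)
  if (is.na(i) || i < 1L || i > nrow(cohort$edges))
    stop("unknown_subject: ", subject)
  devectorize_fc(cohort$edges[i, ])
}

#' Realize node time series with a target connectivity
#'
#' Samples `n_timepoints` draws from a zero-mean multivariate normal law
#' whose correlation matrix is the back-transform (`tanh`) of a target
#' Fisher-z matrix, so that [compute_fc()] on the output recovers the target
#' up to sampling error. A target whose correlation matrix is not positive
#' definite is repaired by eigenvalue clipping (reported via a message).
#'
#' @param target symmetric Fisher-z matrix (diagonal ignored).
#' @param n_timepoints series length; `n_timepoints < n_nodes + 1` triggers a
#'   warning (downstream correlation matrices will be rank-deficient) but is
#'   allowed.
#' @return Numeric matrix, nodes x `n_timepoints`.
#' @export
realize_timeseries <- function(target, n_timepoints = 230) {
  target <- as.matrix(target)
  n <- nrow(target)
  stopifnot(n == ncol(target))
  if (n_timepoints < n + 1)
    warning("short_series: n_timepoints < n_nodes + 1; sample correlation ",
            "matrix will be rank-deficient")
  R <- tanh(target)
  diag(R) <- 1
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(eg$values) < 1e-8) {
    message("realize_timeseries: target correlation not positive definite; ",
            "clipping eigenvalues at 1e-6")
    vals <- pmax(eg$values, 1e-6)
    R <- eg$vectors %*% (vals * t(eg$vectors))
    R <- stats::cov2cor(R)
    eg <- eigen(R, symmetric = TRUE)
  }
  A <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  A %*% matrix(stats::rnorm(n * n_timepoints), n, n_timepoints)
}
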