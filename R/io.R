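# File formats and the pipeline driver.
#
# All on-disk formats are plain text and diffable:
#   hypnogram TSV   : '# key=value' metadata lines, then 'epoch_index<TAB>stage'
#                     with 0-based contiguous indices;
#   parcellation TSV: 'node_id<TAB>network', 0-based contiguous node ids;
#   FC matrix CSV   : dense n x n, no header, row order = node order;
#   behavior CSV    : subject_id, group, rem_duration_min[, rem_proportion_pct].
# Readers are strict (named errors carrying line numbers) but tolerate CRLF
# line endings, sub-tolerance matrix asymmetry, and stray whitespace in group
# labels.

#' Write / read a hypnogram TSV
#'
#' The format round-trips exactly: metadata (`subject_id`, `lights_off`,
#' `epoch_length_s`) as `# key=value` comment lines, a header row, then one
#' `epoch_index<TAB>stage` row per epoch with contiguous 0-based indices.
#'
#' @param h a [hypnogram()].
#' @param path file path.
#' @return `read_hypnogram` returns a [hypnogram()]; `write_hypnogram`
#'   returns `path` invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# subject_id=", h$subject_id),
               paste0("# lights_off=", h$lights_off),
               paste0("# epoch_length_s=", format(h$epoch_length_s)),
               "epoch_index\tstage",
               paste(seq_along(h$stages) - 1L, h$stages, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  meta_ln <- grep("^#", lines)
  meta <- list()
  for (ln in meta_ln) {
    kv <- sub("^#\\s*", "", lines[ln])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0)
      stop("bad_metadata: line ", ln, " is not '# key=value'")
    meta[[substr(kv, 1L, eq - 1L)]] <- substring(kv, eq + 1L)
  }
  for (key in c("subject_id", "lights_off", "epoch_length_s"))
    if (is.null(meta[[key]]))
      stop("missing_metadata: required key '", key, "' not found in ", path)
  body <- setdiff(seq_along(lines), meta_ln)
  body <- body[nzchar(lines[body])]
  if (!length(body) || lines[body[1L]] != "epoch_index\tstage")
    stop("bad_header: expected 'epoch_index\\tstage' at line ",
         if (length(body)) body[1L] else 1L)
  rows <- body[-1L]
  if (!length(rows)) stop("empty_hypnogram: no epochs in ", path)
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("bad_row: line ", rows[bad[1L]], " does not have two tab-separated fields")
  idx <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  stage <- vapply(parts, `[[`, "", 2L)
  if (anyNA(idx) || !identical(idx, seq_along(idx) - 1L)) {
    off <- which(is.na(idx) | idx != seq_along(idx) - 1L)[1L]
    stop("bad_epoch_index: non-contiguous or non-numeric epoch_index at line ",
         rows[off])
  }
  bad_stage <- which(!stage %in% SLEEP_STAGES)
  if (length(bad_stage))
    stop("unknown_stage: symbol '", stage[bad_stage[1L]], "' at line ",
         rows[bad_stage[1L]])
  hypnogram(stage, lights_off = meta$lights_off,
            epoch_length_s = as.numeric(meta$epoch_length_s),
            subject_id = meta$subject_id)
}

#' Write / read a dense connectivity matrix CSV
#'
#' No header, one row per node. On read the matrix must be square and
#' numeric; asymmetry below `1e-6` is silently repaired by symmetrizing
#' `(z + t(z))/2` (reported via a message), larger asymmetry is rejected.
#'
#' @param z symmetric numeric matrix.
#' @param path file path.
#' @param n_expected optional node count to enforce (e.g. from the
#'   parcellation).
#' @return `read_matrix` returns the symmetric matrix with zero diagonal.
#' @export
write_matrix <- function(z, path) {
  utils::write.table(format(z, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, n_expected = NULL) {
  z <- tryCatch(as.matrix(utils::read.csv(path, header = FALSE)),
                warning = function(w) stop("bad_matrix: ", conditionMessage(w)))
  if (!is.numeric(z)) stop("bad_matrix: non-numeric cell in ", path)
  if (nrow(z) != ncol(z))
    stop("bad_matrix: ", nrow(z), " x ", ncol(z), " is not square")
  if (!is.null(n_expected) && nrow(z) != n_expected)
    stop("dimension_mismatch: matrix is ", nrow(z), " x ", ncol(z),
         ", parcellation expects ", n_expected)
  asym <- max(abs(z - t(z)))
  if (asym >= 1e-6)
    stop("asymmetric_matrix: max |z - t(z)| = ", format(asym), " exceeds 1e-6")
  if (asym > 0) message("read_matrix: symmetrized (max asymmetry ", format(asym), ")")
  z <- (z + t(z)) / 2
  diag(z) <- 0
  dimnames(z) <- NULL
  z
}

#' Write / read the behavior table CSV
#'
#' Required columns: `subject_id`, `group`, `rem_duration_min`. Group labels
#' are whitespace-trimmed on read and must be one of `FS`, `early_dep`,
#' `late_dep`; duplicate subject ids are rejected.
#'
#' @param behavior data frame.
#' @param path file path.
#' @return `read_behavior` returns the validated data frame.
#' @export
write_behavior <- function(behavior, path) {
  utils::write.csv(behavior, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "rem_duration_min")
  miss <- setdiff(need, names(b))
  if (length(miss))
    stop("missing_column: behavior table lacks ", paste(miss, collapse = ", "))
  raw <- b$group
  b$group <- trimws(b$group)
  if (any(raw != b$group))
    message("read_behavior: trimmed whitespace in ", sum(raw != b$group),
            " group label(s)")
  bad <- which(!b$group %in% GROUPS)
  if (length(bad))
    stop("unknown_group: label '", raw[bad[1L]], "' in row ", bad[1L])
  dup <- which(duplicated(b$subject_id))
  if (length(dup))
    stop("duplicate_subject: '", b$subject_id[dup[1L]], "' appears twice")
  if (!is.numeric(b$rem_duration_min))
    stop("bad_behavior: rem_duration_min must be numeric")
  b
}

#' Write / read a parcellation TSV
#'
#' Columns `node_id` (0-based contiguous) and `network`.
#' @param p a [parcellation()].
#' @param path file path.
#' @return `read_parcellation` returns a [parcellation()].
#' @export
write_parcellation <- function(p, path) {
  utils::write.table(data.frame(node_id = p$node_id, network = p$network),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node_id", "network") %in% names(d)))
    stop("missing_column: parcellation needs node_id and network")
  if (!identical(as.integer(d$node_id), seq_len(nrow(d)) - 1L))
    stop("bad_node_id: node_id must be 0-based and contiguous")
  parcellation(d$network)
}

#' Write a synthetic cohort to disk
#'
#' Emits the full artifact set: `behavior.csv`, `parcellation.tsv`, one
#' hypnogram TSV per subject under `hypnograms/`, one FC matrix CSV per
#' subject under `fc/`, optionally realized time series under `timeseries/`,
#' and a `manifest.json` echoing the configuration, seed and file paths.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param emit_timeseries also write per-subject node time series realized
#'   from each FC matrix.
#' @return The manifest as a list, invisibly.
#' @export
write_cohort <- function(cohort, dir, emit_timeseries = FALSE) {
  stopifnot(inherits(cohort, "rem_cohort"))
  dir.create(file.path(dir, "hypnograms"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fc"), showWarnings = FALSE)
  write_behavior(cohort$behavior, file.path(dir, "behavior.csv"))
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  ids <- cohort$behavior$subject_id
  hyp_paths <- file.path("hypnograms", paste0(ids, ".tsv"))
  fc_paths <- file.path("fc", paste0(ids, ".csv"))
  for (s in seq_along(ids)) {
    write_hypnogram(cohort$hypnograms[[s]], file.path(dir, hyp_paths[s]))
    write_matrix(cohort_fc_matrix(cohort, s), file.path(dir, fc_paths[s]))
  }
  if (emit_timeseries) {
    dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
    for (s in seq_along(ids)) {
      ts <- realize_timeseries(cohort_fc_matrix(cohort, s),
                               cohort$config$n_timepoints)
      write_matrix_plain(ts, file.path(dir, "timeseries", paste0(ids[s], ".csv")))
    }
  }
  cfg <- cohort$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("remcpm")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "planted_edges")],
    planted_edges = cohort$planted_edges,
    files = list(behavior = "behavior.csv", parcellation = "parcellation.tsv",
                 hypnograms = hyp_paths, fc = fc_paths))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# rectangular (non-symmetric) CSV, used for time series
write_matrix_plain <- function(m, path) {
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Binds the stages end to end: simulate (or load) a cohort, score sleep
#' parameters, fit the CPM, characterize the consensus connectome, and
#' compare groups -- writing one JSON/CSV artifact per stage plus a manifest,
#' all embedding the seed and configuration for provenance. Rerunning with
#' the same configuration and seed reproduces the artifacts byte for byte.
#'
#' @param out_dir output directory.
#' @param config a [cohort_config()] (or a path to a YAML file of
#'   `cohort_config` arguments).
#' @param cpm_args list of arguments passed to [cpm()] (e.g. `alpha`,
#'   `n_perm`, `seed`).
#' @param correction multiple-comparison method for the group stage.
#' @param split clock time for the early/late-night segment analysis of
#'   full-sleep hypnograms (default `"03:30"`).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(out_dir, config = cohort_config(),
                         cpm_args = list(n_perm = 1000),
                         correction = "BH", split = "03:30") {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    config <- do.call(cohort_config, args)
  }
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  cohort <- generate_cohort(config)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  paths$cohort <- file.path(out_dir, "cohort")

  # sleep scoring, with early/late segmentation for full-night subjects
  tab <- sleep_summary_table(cohort$hypnograms, cohort$behavior$group)
  utils::write.csv(tab$subjects, file.path(out_dir, "sleep_parameters.csv"),
                   row.names = FALSE)
  paths$sleep <- file.path(out_dir, "sleep_parameters.csv")
  fs <- which(cohort$behavior$group == "FS")
  seg <- lapply(cohort$hypnograms[fs], function(h) {
    s <- segment_hypnogram(h, split)
    c(early = rem_metrics(s$early)$rem_proportion_pct,
      late = rem_metrics(s$late)$rem_proportion_pct)
  })
  seg <- do.call(rbind, seg)

  if (is.null(cpm_args$seed)) cpm_args$seed <- config$seed
  fit <- do.call(cpm, c(list(cohort), cpm_args))
  cpm_json <- list(
    seed = cpm_args$seed, alpha = fit$alpha, n_perm = fit$n_perm,
    n_subjects = fit$n, n_edges = fit$n_edges,
    r_obs = as.list(fit$r_obs), p_perm = as.list(fit$p_perm),
    n_empty_folds = fit$n_empty_folds,
    consensus = fit$consensus[c("positive", "negative")],
    config_echo = cohort$config[c("n_per_group", "n_nodes", "beta",
                                  "edge_noise_sd", "seed")])
  jsonlite::write_json(cpm_json, file.path(out_dir, "cpm_result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$cpm <- file.path(out_dir, "cpm_result.json")

  y <- cohort$behavior$rem_duration_min
  prof <- characterize_connectome(fit, cohort$edges, y)
  jsonlite::write_json(
    list(seed = config$seed,
         n_edges_in_mask = prof$n_edges_in_mask,
         variances = as.list(prof$variances),
         similarity_r = prof$similarity_r,
         pairs = prof$pairs, pair_contributions = prof$pair_contributions,
         networks = prof$networks, regions = prof$regions,
         split_night = list(split = split,
                            mean_early_rem_pct = mean(seg[, "early"], na.rm = TRUE),
                            mean_late_rem_pct = mean(seg[, "late"], na.rm = TRUE))),
    file.path(out_dir, "characterization.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$characterization <- file.path(out_dir, "characterization.json")

  gc_res <- compare_groups(cohort, mask = fit, correction = correction)
  jsonlite::write_json(
    list(seed = config$seed, correction = correction,
         anova = gc_res$anova,
         posthoc = gc_res$posthoc,
         edge_level = gc_res$edges),
    file.path(out_dir, "group_comparison.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$groups <- file.path(out_dir, "group_comparison.json")

  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("remcpm")),
         seed = config$seed, artifacts = paths),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- file.path(out_dir, "manifest.json")
  invisible(paths)
}
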