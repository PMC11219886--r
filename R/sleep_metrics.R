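# Polysomnographic sleep parameters from hypnograms.
#
# Scoring conventions (stated because the literature varies):
#   * sleep onset  = first epoch of any non-wake stage;
#   * SL           = lights-off to sleep onset;
#   * WASO         = wake strictly between sleep onset and the last sleep
#                    epoch (terminal wake excluded, so TIB decomposes exactly
#                    as TIB = SL + TST + WASO + terminal wake);
#   * SE           = TST / time in bed (lights-off to lights-on).

#' Score standard sleep parameters from a hypnogram
#'
#' Computes the usual polysomnographic summary of one night: total sleep time
#' (TST), sleep latency (SL), wake after sleep onset (WASO), sleep efficiency
#' (SE), the percentage of TST spent in each stage, and REM duration.
#'
#' An all-wake night yields `tst_min = 0` with the latency, WASO and
#' percentage fields reported as `NA` (undefined, not zero).
#'
#' @param h a [hypnogram()].
#' @return An object of class `"sleep_parameters"`: a list with fields
#'   `tst_min`, `sl_min`, `waso_min`, `terminal_wake_min`, `tib_min`,
#'   `se_frac`, `pct_n1`, `pct_n2`, `pct_n3`, `pct_rem`, `rem_duration_min`.
#' @examples
#' h <- hypnogram(c("W", "W", "N1", "N2", "W", "N2", "N3", "R", "R", "W"))
#' score_sleep_parameters(h)
#' @export
score_sleep_parameters <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  ep_min <- h$epoch_length_s / 60
  s <- h$stages
  n <- length(s)
  asleep <- s != "W"
  tib <- n * ep_min
  tst <- sum(asleep) * ep_min

  if (tst == 0) {
    out <- list(tst_min = 0, sl_min = NA_real_, waso_min = NA_real_,
                terminal_wake_min = NA_real_, tib_min = tib, se_frac = 0,
                pct_n1 = NA_real_, pct_n2 = NA_real_, pct_n3 = NA_real_,
                pct_rem = NA_real_, rem_duration_min = NA_real_,
                subject_id = h$subject_id)
    return(structure(out, class = "sleep_parameters"))
  }

  onset <- which(asleep)[1L]
  last  <- max(which(asleep))
  sl    <- (onset - 1L) * ep_min
  waso  <- sum(s[onset:last] == "W") * ep_min
  term  <- (n - last) * ep_min
  mins  <- function(stage) sum(s == stage) * ep_min

  out <- list(
    tst_min = tst, sl_min = sl, waso_min = waso, terminal_wake_min = term,
    tib_min = tib, se_frac = tst / tib,
    pct_n1 = mins("N1") / tst * 100, pct_n2 = mins("N2") / tst * 100,
    pct_n3 = mins("N3") / tst * 100, pct_rem = mins("R") / tst * 100,
    rem_duration_min = mins("R"), subject_id = h$subject_id)
  structure(out, class = "sleep_parameters")
}

#' @export
print.sleep_parameters <- function(x, ...) {
  cat(sprintf("Sleep parameters (%s):\n", x$subject_id))
  cat(sprintf("  TIB %.1f min | TST %.1f | SL %.1f | WASO %.1f | terminal wake %.1f | SE %.3f\n",
              x$tib_min, x$tst_min, x$sl_min, x$waso_min,
              x$terminal_wake_min, x$se_frac))
  cat(sprintf("  %% of TST: N1 %.1f | N2 %.1f | N3 %.1f | REM %.1f  (REM %.1f min)\n",
              x$pct_n1, x$pct_n2, x$pct_n3, x$pct_rem, x$rem_duration_min))
  invisible(x)
}

#' @export
as.data.frame.sleep_parameters <- function(x, ...) {
  as.data.frame(x[setdiff(names(x), "subject_id")],
                row.names = x$subject_id)
}

#' REM duration and proportion
#'
#' The two behavioral metrics of interest for brain-behavior modelling:
#' minutes of REM sleep and REM as a percentage of total sleep time.
#'
#' @param h a [hypnogram()].
#' @return A list with `rem_duration_min` and `rem_proportion_pct`; both `NA`
#'   when the night contains no sleep.
#' @export
rem_metrics <- function(h) {
  p <- score_sleep_parameters(h)
  if (p$tst_min == 0)
    return(list(rem_duration_min = NA_real_, rem_proportion_pct = NA_real_))
  list(rem_duration_min = p$rem_duration_min,
       rem_proportion_pct = p$rem_duration_min / p$tst_min * 100)
}

#' Split a hypnogram at a clock time
#'
#' Segments one night into an early and a late part at `split_clock` (e.g.
#' `"03:30"` to separate the NREM-dominant from the REM-dominant half of a
#' 23:00-08:00 full night). The split is snapped to the nearest epoch
#' boundary; concatenating the two segments reproduces the input, and every
#' duration metric is additive across the split.
#'
#' @param h a [hypnogram()].
#' @param split_clock clock time `"HH:MM"` strictly inside the recording
#'   window.
#' @return A list with components `early` and `late`, both hypnograms; the
#'   late segment's `lights_off` is the (snapped) split time.
#' @export
segment_hypnogram <- function(h, split_clock) {
  stopifnot(inherits(h, "hypnogram"))
  off_min <- minutes_after(h$lights_off, split_clock)
  span <- hypnogram_span_min(h)
  if (off_min <= 0 || off_min >= span)
    stop("split_outside_window: split at ", split_clock,
         " does not fall strictly inside the ", span, "-min recording")
  ep_min <- h$epoch_length_s / 60
  k <- round(off_min / ep_min)
  if (abs(k * ep_min - off_min) > 1e-9)
    message("segment_hypnogram: split snapped to epoch boundary at ",
            min_to_clock(clock_to_min(h$lights_off) + k * ep_min))
  if (k <= 0 || k >= length(h$stages))
    stop("split_outside_window: split leaves an empty segment")
  early <- hypnogram(h$stages[seq_len(k)], lights_off = h$lights_off,
                     epoch_length_s = h$epoch_length_s,
                     subject_id = h$subject_id)
  late <- hypnogram(h$stages[(k + 1L):length(h$stages)],
                    lights_off = min_to_clock(clock_to_min(h$lights_off) + k * ep_min),
                    epoch_length_s = h$epoch_length_s,
                    subject_id = h$subject_id)
  list(early = early, late = late)
}

#' Per-subject and per-group sleep summary table
#'
#' Scores a list of hypnograms and, when group labels are supplied, appends a
#' mean +/- SD summary per group in the style of a demographics table.
#'
#' @param hypnograms list of [hypnogram()] objects.
#' @param groups optional character vector of group labels, one per hypnogram.
#' @return A list with `subjects` (one row per recording) and, if `groups`
#'   was given, `groups` (mean and SD of each parameter by group).
#' @export
sleep_summary_table <- function(hypnograms, groups = NULL) {
  rows <- lapply(hypnograms, function(h) as.data.frame(score_sleep_parameters(h)))
  subj <- do.call(rbind, rows)
  subj <- cbind(subject_id = vapply(hypnograms, `[[`, "", "subject_id"), subj)
  rownames(subj) <- NULL
  out <- list(subjects = subj)
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(subj))
    num <- subj[, vapply(subj, is.numeric, TRUE), drop = FALSE]
    agg_m <- stats::aggregate(num, list(group = groups), mean, na.rm = TRUE)
    agg_s <- stats::aggregate(num, list(group = groups), stats::sd, na.rm = TRUE)
    out$groups <- list(mean = agg_m, sd = agg_s)
  }
  out
}
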