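# Hypnogram representation and clock arithmetic.
#
# A hypnogram is the epoch-by-epoch sequence of manually scored sleep stages
# over one night, on the AASM alphabet {W, N1, N2, N3, R} at a fixed epoch
# length (30 s by convention). Recordings span lights-off to lights-on; the
# night wraps past midnight, so clock offsets are taken modulo 24 h relative
# to an anchor earlier in the evening.

#' AASM sleep-stage alphabet
#'
#' Wake, the three NREM stages, and REM. Any other symbol in a hypnogram is
#' rejected at construction / parse time.
#' @export
SLEEP_STAGES <- c("W", "N1", "N2", "N3", "R")

clock_to_min <- function(x) {
  if (length(x) != 1L || is.na(x) || !grepl("^[0-9]{1,2}:[0-9]{2}$", x))
    stop("bad_clock_time: expected 'HH:MM', got '", paste(x, collapse = ","), "'")
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1L]])
  if (p[1L] > 23L || p[2L] > 59L)
    stop("bad_clock_time: '", x, "' is not a valid time of day")
  p[1L] * 60L + p[2L]
}

min_to_clock <- function(m) {
  m <- as.integer(round(m)) %% 1440L
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

# minutes from clock time `anchor` forward to clock time `x` (0..1439)
minutes_after <- function(anchor, x) {
  (clock_to_min(x) - clock_to_min(anchor)) %% 1440L
}

#' Construct a hypnogram
#'
#' @param stages character vector of sleep stages, one per epoch, drawn from
#'   [SLEEP_STAGES]. The sequence spans the whole in-bed window (lights-off to
#'   lights-on).
#' @param lights_off clock time `"HH:MM"` at which the recording starts.
#' @param epoch_length_s epoch duration in seconds (default 30).
#' @param subject_id identifier carried through scoring and file output.
#'
#' @return An object of class `"hypnogram"`: a list with fields `subject_id`,
#'   `lights_off`, `epoch_length_s` and `stages`.
#' @examples
#' h <- hypnogram(c("W", "W", "N1", "N2", "N2", "N3", "R", "R"))
#' score_sleep_parameters(h)
#' @seealso [score_sleep_parameters()], [segment_hypnogram()], [rem_metrics()]
#' @export
hypnogram <- function(stages, lights_off = "23:00", epoch_length_s = 30,
                      subject_id = "s001") {
  stages <- as.character(stages)
  if (length(stages) == 0L)
    stop("empty_hypnogram: stage sequence must be non-empty")
  bad <- which(!stages %in% SLEEP_STAGES)
  if (length(bad))
    stop("unknown_stage: symbol '", stages[bad[1L]], "' at epoch ", bad[1L],
         " (alphabet is ", paste(SLEEP_STAGES, collapse = ","), ")")
  if (!is.numeric(epoch_length_s) || epoch_length_s <= 0)
    stop("bad_epoch_length: epoch_length_s must be > 0")
  clock_to_min(lights_off) # validates format
  structure(
    list(subject_id = as.character(subject_id),
         lights_off = lights_off,
         epoch_length_s = as.numeric(epoch_length_s),
         stages = stages),
    class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x$stages)
  span <- n * x$epoch_length_s / 60
  cat(sprintf("Hypnogram '%s': %d epochs of %gs (%.1f min), lights off %s\n",
              x$subject_id, n, x$epoch_length_s, span, x$lights_off))
  tab <- table(factor(x$stages, levels = SLEEP_STAGES))
  cat("  epochs by stage: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.hypnogram <- function(x, ...) {
  # conventional depth ordering: wake on top, REM between wake and N1
  depth <- c(W = 4, R = 3, N1 = 2, N2 = 1, N3 = 0)
  y <- depth[x$stages]
  t_min <- (seq_along(y) - 1L) * x$epoch_length_s / 60
  graphics::plot(t_min, y, type = "s", yaxt = "n",
                 xlab = "minutes since lights-off", ylab = "",
                 main = paste("Hypnogram", x$subject_id), ...)
  graphics::axis(2, at = unname(depth), labels = names(depth), las = 1)
  invisible(x)
}

# in-bed span in minutes
hypnogram_span_min <- function(h) length(h$stages) * h$epoch_length_s / 60
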