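#' Detect grasp actions in the force trace
#'
#' An action is a span where the force exceeds a fraction of the recording's
#' maximum force. Spans separated by sub-threshold gaps shorter than
#' `merge_gap_ms` are merged (hysteresis against sensor noise at the
#' threshold) and spans shorter than `min_duration_ms` are discarded; grasps
#' last about one second, so sub-200 ms excursions are noise.
#'
#' Sample spans are half-open: a span `[onset, offset)` covers samples
#' `onset .. offset - 1` (1-based), so `offset - onset` is its length.
#'
#' @param rec a `recording`.
#' @param force_threshold_fraction detection threshold as a fraction of
#'   `max(force)`.
#' @param merge_gap_ms sub-threshold gaps shorter than this are bridged.
#' @param min_duration_ms spans shorter than this are dropped.
#' @return Data frame with columns `action`, `onset`, `offset`; zero rows
#'   when the force never exceeds the threshold (an all-rest recording is not
#'   an error).
#' @export
detect_actions <- function(rec, force_threshold_fraction = 0.05,
                           merge_gap_ms = 100, min_duration_ms = 200) {
  stopifnot(inherits(rec, "recording"))
  force <- rec$force
  empty <- data.frame(action = integer(0), onset = integer(0),
                      offset = integer(0))
  if (max(force) <= 0) return(empty)
  thr <- force_threshold_fraction * max(force)
  active <- force > thr
  if (!any(active)) return(empty)

  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  onset <- starts[on]
  offset <- ends[on] + 1L          # half-open

  # merge across short sub-threshold gaps
  max_gap <- round(merge_gap_ms * rec$fs / 1000)
  if (length(onset) > 1) {
    keep_onset <- onset[1]
    merged_on <- integer(0); merged_off <- integer(0)
    for (i in seq_len(length(onset) - 1)) {
      if (onset[i + 1] - offset[i] < max_gap) next
      merged_on <- c(merged_on, keep_onset)
      merged_off <- c(merged_off, offset[i])
      keep_onset <- onset[i + 1]
    }
    merged_on <- c(merged_on, keep_onset)
    merged_off <- c(merged_off, offset[length(offset)])
    onset <- merged_on; offset <- merged_off
  }

  min_len <- round(min_duration_ms * rec$fs / 1000)
  long_enough <- (offset - onset) >= min_len
  onset <- onset[long_enough]; offset <- offset[long_enough]
  data.frame(action = seq_along(onset), onset = onset, offset = offset)
}

#' Trim segments: keep one quarter of the action length on each flank
#'
#' For an action span of length `T2`, the kept span extends the action by
#' `T1 = T3 = floor(T2 / 4)` samples of relaxation on each side, discarding
#' the rest of the relaxation phase. Flanks are clipped at the recording
#' boundaries; when the flanks of adjacent actions would overlap, they are
#' truncated at the midpoint between the two actions.
#'
#' @param spans data frame from [detect_actions()] (columns `action`,
#'   `onset`, `offset`, optionally `level`), ordered and within bounds.
#' @param rec the `recording` the spans index into.
#' @return Data frame of class `action_segments` with columns `action`,
#'   `onset`, `offset`, `kept_start`, `kept_end` (half-open), and `level`
#'   when supplied.
#' @export
trim_segments <- function(spans, rec) {
  stopifnot(inherits(rec, "recording"))
  n <- nrow(spans)
  out <- spans[, intersect(c("action", "onset", "offset", "level"),
                           names(spans)), drop = FALSE]
  if (n == 0) {
    out$kept_start <- integer(0); out$kept_end <- integer(0)
    class(out) <- c("action_segments", "data.frame")
    return(out)
  }
  if (is.unsorted(spans$onset))
    stop("action spans must be ordered by onset", call. = FALSE)
  len <- nrow(rec$emg)
  t2 <- spans$offset - spans$onset
  flank <- t2 %/% 4L
  ks <- pmax(1L, spans$onset - flank)
  ke <- pmin(len + 1L, spans$offset + flank)
  if (n > 1) {
    mid <- (spans$offset[-n] + spans$onset[-1]) %/% 2L
    ke[-n] <- pmin(ke[-n], mid)
    ks[-1] <- pmax(ks[-1], mid)
  }
  out$kept_start <- as.integer(ks)
  out$kept_end <- as.integer(ke)
  class(out) <- c("action_segments", "data.frame")
  out
}

# overlap fraction between detected and ground-truth half-open spans,
# relative to the truth span; used to score detection against the simulator
span_overlap <- function(onset, offset, true_onset, true_offset) {
  inter <- pmax(0L, pmin(offset, true_offset) - pmax(onset, true_onset))
  inter / (true_offset - true_onset)
}
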