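#' Time-domain sEMG features
#'
#' The four classical time-domain descriptors of a windowed sEMG signal
#' `x[1..N]` (uV):
#'
#' * **VAR** (variance, power-density proxy): `(1/N) * sum(x^2)`.
#' * **ZC** (zero crossings): number of adjacent pairs with a sign change,
#'   `x[j] * x[j-1] < 0`, whose amplitude difference also exceeds a guard
#'   threshold `|x[j] - x[j-1]| > threshold` so baseline noise does not
#'   register; carries frequency information.
#' * **IEMG** (integrated EMG): `sum(|x|)`, a power/effort measure.
#' * **WAMP** (Willison amplitude): number of adjacent pairs with
#'   `|x[j] - x[j-1]| > threshold`, reflecting contraction level.
#'
#' Default thresholds are 30 uV for ZC and 150 uV for WAMP, chosen for
#' amplifier noise and gain typical of conditioned forearm sEMG.
#'
#' @param window numeric vector of sEMG samples (uV).
#' @param threshold guard threshold in uV (ZC, WAMP).
#' @return `var_feature`: uV^2; `iemg_feature`: uV (summed absolute
#'   amplitude); `zc_feature`, `wamp_feature`: integer counts in
#'   `0 .. length(window) - 1`.
#' @name td_features
NULL

#' @rdname td_features
#' @export
var_feature <- function(window) {
  stopifnot(length(window) >= 1)
  sum(window^2) / length(window)
}

#' @rdname td_features
#' @export
zc_feature <- function(window, threshold = 30) {
  stopifnot(length(window) >= 2, threshold >= 0)
  n <- length(window)
  d <- window[-1] - window[-n]
  sum(window[-1] * window[-n] < 0 & abs(d) > threshold)
}

#' @rdname td_features
#' @export
iemg_feature <- function(window) {
  stopifnot(length(window) >= 1)
  sum(abs(window))
}

#' @rdname td_features
#' @export
wamp_feature <- function(window, threshold = 150) {
  stopifnot(length(window) >= 2, threshold >= 0)
  sum(abs(diff(window)) > threshold)
}

# canonical feature letters and their single-sample extractors
FEATURE_ORDER <- c("V", "I", "W", "Z")

#' Sliding-window configuration
#'
#' @param fs sampling rate in Hz.
#' @param window_ms window length in milliseconds; at 1 kHz the default
#'   200 ms window is `N = 200` samples.
#' @param overlap_fraction fractional overlap of consecutive windows; 0.5
#'   gives a step of `N/2` (100 samples at the defaults).
#' @return List with integer fields `N` and `step`.
#' @export
window_config <- function(fs, window_ms = 200, overlap_fraction = 0.5) {
  N <- as.integer(round(window_ms * fs / 1000))
  step <- as.integer(round(N * (1 - overlap_fraction)))
  if (N < 2) stop("window length must be >= 2 samples", call. = FALSE)
  if (step < 1 || step > N)
    stop("window step must be in 1..N", call. = FALSE)
  list(N = N, step = step)
}

#' Extract a per-window feature table from segmented actions
#'
#' Slides a window of `wcfg$N` samples with step `wcfg$step` over each
#' segment's kept span and evaluates the requested features on every channel.
#' Windows never straddle segment boundaries (trailing partial windows are
#' dropped), so trimmed-away relaxation data cannot leak into action
#' windows. The regression target of each window is the mean force over the
#' same samples.
#'
#' @param rec a `recording`.
#' @param segments an `action_segments` data frame from [trim_segments()].
#' @param wcfg a [window_config()].
#' @param features feature letters, subset of `c("V","I","W","Z")`.
#' @param channels channel labels to extract from (default all).
#' @param zc_threshold,wamp_threshold guard thresholds in uV.
#' @return A `feature_table`: data frame with one column per
#'   (channel, feature) pair named `<channel>_<feature>` (e.g. `P1_V`), plus
#'   `force` (mean window force, N), `segment_id` and `action_id`. Segments
#'   shorter than one window are skipped with a warning.
#' @export
extract_features <- function(rec, segments, wcfg,
                             features = FEATURE_ORDER,
                             channels = rec$channel_labels,
                             zc_threshold = 30, wamp_threshold = 150) {
  stopifnot(inherits(rec, "recording"))
  features <- match.arg(features, FEATURE_ORDER, several.ok = TRUE)
  features <- FEATURE_ORDER[FEATURE_ORDER %in% features]
  if (!all(channels %in% rec$channel_labels))
    stop("unknown channel label(s): ",
         paste(setdiff(channels, rec$channel_labels), collapse = ", "),
         call. = FALSE)

  feat_fun <- list(
    V = function(w) var_feature(w),
    I = function(w) iemg_feature(w),
    W = function(w) wamp_feature(w, wamp_threshold),
    Z = function(w) zc_feature(w, zc_threshold))

  col_names <- as.vector(t(outer(channels, features, paste, sep = "_")))
  rows <- vector("list", nrow(segments))
  for (s in seq_len(nrow(segments))) {
    ks <- segments$kept_start[s]; ke <- segments$kept_end[s]
    L <- ke - ks
    if (L < wcfg$N) {
      warning("segment ", segments$action[s], " shorter than one window (",
              L, " < ", wcfg$N, " samples); skipped", call. = FALSE)
      next
    }
    starts <- seq.int(ks, ke - wcfg$N, by = wcfg$step)
    vals <- matrix(0, nrow = length(starts), ncol = length(col_names),
                   dimnames = list(NULL, col_names))
    target <- numeric(length(starts))
    for (w in seq_along(starts)) {
      idx <- starts[w]:(starts[w] + wcfg$N - 1L)
      target[w] <- mean(rec$force[idx])
      k <- 0L
      for (ch in channels) {
        x <- rec$emg[idx, ch]
        for (f in features) {
          k <- k + 1L
          vals[w, k] <- feat_fun[[f]](x)
        }
      }
    }
    df <- as.data.frame(vals)
    df$force <- target
    df$segment_id <- s
    df$action_id <- segments$action[s]
    rows[[s]] <- df
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    df <- as.data.frame(matrix(numeric(0), ncol = length(col_names),
                               dimnames = list(NULL, col_names)))
    df$force <- numeric(0); df$segment_id <- integer(0)
    df$action_id <- integer(0)
    df
  }
  rownames(out) <- NULL
  structure(out, class = c("feature_table", "data.frame"),
            channels = channels, features = features)
}
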