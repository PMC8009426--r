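#' Construct a synchronized sEMG + force recording
#'
#' @param fs sampling rate in Hz.
#' @param emg numeric matrix of EMG voltages in uV, one column per channel.
#' @param force numeric vector of grasp force in N, same length as the EMG.
#' @param channel_labels channel names; default `P1..Pn`, matching the
#'   conventional labeling of the six forearm measurement positions
#'   (P1 extensor carpi ulnaris ... P6 extensor digitorum).
#' @return An object of class `recording`.
#' @export
recording <- function(fs, emg, force,
                      channel_labels = paste0("P", seq_len(ncol(emg)))) {
  emg <- as.matrix(emg)
  force <- as.numeric(force)
  if (nrow(emg) != length(force))
    stop("emg and force must have the same number of samples", call. = FALSE)
  if (nrow(emg) < 1) stop("recording must contain at least one sample",
                          call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (length(channel_labels) != ncol(emg))
    stop("channel_labels must name every EMG column", call. = FALSE)
  colnames(emg) <- channel_labels
  structure(list(fs = fs, emg = emg, force = force,
                 channel_labels = channel_labels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("sEMG recording:", ncol(x$emg), "channels x", nrow(x$emg),
      "samples @", x$fs, "Hz\n")
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat(sprintf("  force: %.1f-%.1f N\n", min(x$force), max(x$force)))
  acts <- attr(x, "actions")
  if (!is.null(acts)) cat("  ground truth:", nrow(acts), "planted actions\n")
  invisible(x)
}

# full-precision numeric formatting: %.17g round-trips IEEE doubles exactly
fmt_full <- function(x) sprintf("%.17g", x)

#' Write a recording to a delimited text file
#'
#' Writes one header row (`time, <channels>, force`) and one row per sample;
#' EMG in uV, force in N, time in seconds. Numbers are written with full
#' round-trip precision so `read_recording(write_recording(...))` is
#' bit-exact. A JSON sidecar (`<path>.json`) stores the sampling rate,
#' channel labels and, when present, the simulator's ground truth (action
#' spans, levels, channel gains).
#'
#' @param rec a `recording`.
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sidecar = TRUE) {
  stopifnot(inherits(rec, "recording"))
  n <- nrow(rec$emg)
  cols <- c(list(fmt_full((seq_len(n) - 1) / rec$fs)),
            lapply(seq_len(ncol(rec$emg)), function(j) fmt_full(rec$emg[, j])),
            list(fmt_full(rec$force)))
  lines <- c(paste(c("time", rec$channel_labels, "force"), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  if (sidecar) {
    meta <- list(fs = rec$fs, channel_labels = rec$channel_labels)
    acts <- attr(rec, "actions")
    if (!is.null(acts)) meta$actions <- acts
    gains <- attr(rec, "channel_gains")
    if (!is.null(gains)) meta$channel_gains <- gains
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a recording from a delimited text file
#'
#' Expects the layout written by [write_recording()]: header
#' `time, <channels>, force`, one numeric row per sample. Ragged rows and
#' non-finite cells are rejected with the offending row number. If the JSON
#' sidecar written alongside exists it supplies the sampling rate, labels and
#' ground-truth annotations; otherwise the sampling rate is inferred from the
#' time column.
#'
#' @param path CSV path.
#' @return A `recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path,
                               call. = FALSE)
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) > 1) {
    bad <- which(nf[-1] != nf[1])[1]   # data-row numbering, header excluded
    stop("ragged row in ", path, ": data row ", bad, " has ", nf[bad + 1],
         " fields, expected ", nf[1], call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric", check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("cannot parse ", path, ": ",
                               conditionMessage(w), call. = FALSE))
  if (ncol(df) < 3)
    stop("recording file needs time, >=1 EMG channel and force columns",
         call. = FALSE)
  bad_cell <- which(!stats::complete.cases(df) |
                      !apply(is.finite(as.matrix(df)), 1, all))
  if (length(bad_cell))
    stop("non-finite value in ", path, " at data row ", bad_cell[1],
         call. = FALSE)
  labels <- names(df)[-c(1, ncol(df))]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fs <- meta$fs
    if (!is.null(meta$channel_labels)) labels <- meta$channel_labels
  } else {
    meta <- NULL
    fs <- 1 / stats::median(diff(df[[1]]))
  }
  rec <- recording(fs = fs, emg = as.matrix(df[-c(1, ncol(df))]),
                   force = df[[ncol(df)]], channel_labels = labels)
  if (!is.null(meta$actions)) attr(rec, "actions") <- meta$actions
  if (!is.null(meta$channel_gains))
    attr(rec, "channel_gains") <- meta$channel_gains
  rec
}

#' Write / read per-trial estimation results
#'
#' A trial-results table has one row per (measurement-position set, feature
#' set, repeat) with the three evaluation metrics: `mps`, `fs`, `repeat`,
#' `nrms`, `nmae`, `cc`. Metrics are written with full round-trip precision;
#' `read_results(write_results(x))` is lossless.
#'
#' @param results data frame with columns `mps`, `fs`, `repeat`, `nrms`,
#'   `nmae`, `cc`.
#' @param path CSV path.
#' @return `write_results`: `path` invisibly; `read_results`: the validated
#'   data frame.
#' @export
write_results <- function(results, path) {
  need <- c("mps", "fs", "repeat", "nrms", "nmae", "cc")
  if (!all(need %in% names(results)))
    stop("results must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lines <- paste(need, collapse = ",")
  if (nrow(results) > 0) {
    lines <- c(lines, paste(results$mps, results$fs, results[["repeat"]],
                            fmt_full(results$nrms), fmt_full(results$nmae),
                            fmt_full(results$cc), sep = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(mps = "character", fs = "character",
                                       "repeat" = "integer",
                                       nrms = "numeric", nmae = "numeric",
                                       cc = "numeric"))
  key <- paste(df$mps, df$fs, df[["repeat"]], sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (mps, fs, repeat) keys in ", path, ": ",
         key[duplicated(key)][1], call. = FALSE)
  df
}

#' Run configuration for the estimation pipeline
#'
#' Collects every tunable of the analysis: the 200 ms / 50% overlap feature
#' window, the 30 uV zero-crossing and 150 uV Willison-amplitude thresholds,
#' the 4/5 vs 1/5 action-wise split repeated 10 times, the GRNN spread
#' policy, and the 0.05 significance level of the selection stage.
#'
#' @param window_ms feature window length in milliseconds.
#' @param overlap_fraction fractional overlap of consecutive windows,
#'   in (0, 1).
#' @param zc_threshold amplitude-difference guard for the zero-crossing
#'   count, uV.
#' @param wamp_threshold Willison-amplitude threshold, uV.
#' @param train_fraction fraction of actions used for training, in (0, 1).
#' @param n_repeats number of random split repetitions per data set.
#' @param grnn_spread Gaussian kernel spread sigma, or `"auto"` to select it
#'   per training fold on an inner action-wise hold-out.
#' @param spread_grid candidate sigma grid used when `grnn_spread = "auto"`
#'   (logarithmic, standardized-feature units).
#' @param alpha significance level for ANOVA and Tukey HSD.
#' @param force_threshold_fraction onset-detection threshold as a fraction of
#'   the recording's maximum force.
#' @param seed master seed; every random draw in the pipeline derives from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(window_ms = 200,
                       overlap_fraction = 0.5,
                       zc_threshold = 30,
                       wamp_threshold = 150,
                       train_fraction = 0.8,
                       n_repeats = 10,
                       grnn_spread = "auto",
                       spread_grid = 10^seq(-2, 1, length.out = 7),
                       alpha = 0.05,
                       force_threshold_fraction = 0.05,
                       seed = 1L) {
  cfg <- list(window_ms = window_ms, overlap_fraction = overlap_fraction,
              zc_threshold = zc_threshold, wamp_threshold = wamp_threshold,
              train_fraction = train_fraction,
              n_repeats = as.integer(n_repeats), grnn_spread = grnn_spread,
              spread_grid = spread_grid, alpha = alpha,
              force_threshold_fraction = force_threshold_fraction,
              seed = as.integer(seed))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  fail <- function(field, why)
    stop("invalid run configuration: field '", field, "' ", why,
         call. = FALSE)
  if (cfg$overlap_fraction <= 0 || cfg$overlap_fraction >= 1)
    fail("overlap_fraction", "must be in (0, 1)")
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    fail("train_fraction", "must be in (0, 1)")
  if (cfg$zc_threshold < 0) fail("zc_threshold", "must be >= 0")
  if (cfg$wamp_threshold < 0) fail("wamp_threshold", "must be >= 0")
  if (cfg$n_repeats < 1) fail("n_repeats", "must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) fail("alpha", "must be in (0, 1)")
  if (is.character(cfg$grnn_spread)) {
    if (!identical(cfg$grnn_spread, "auto"))
      fail("grnn_spread", "must be a positive number or \"auto\"")
    if (length(cfg$spread_grid) < 1 || any(cfg$spread_grid <= 0))
      fail("spread_grid", "must be a non-empty grid of positive values")
  } else if (!is.numeric(cfg$grnn_spread) || cfg$grnn_spread <= 0) {
    fail("grnn_spread", "must be a positive number or \"auto\"")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML, with optional overrides
#'
#' Any field of [run_config()] may appear in the YAML file; fields passed in
#' `...` override the file.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @param ... named overrides.
#' @return A `run_config`.
#' @export
read_run_config <- function(path = NULL, ...) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown run configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param cfg a `run_config` to serialize.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
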