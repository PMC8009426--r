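#' Pipeline stages: simulate, extract, trials, select, report
#'
#' The full analysis is a chain of file-backed stages under one output
#' directory, each re-creatable on its own:
#'
#' 1. `stage_simulate` — write `recording.csv` (+ JSON ground-truth sidecar)
#'    from a [sim_config()].
#' 2. `stage_extract` — segment the recording, trim relaxation flanks, and
#'    write the windowed `features.csv` and `segments.csv`.
#' 3. `stage_trials` — run the GRNN over the requested (MPS, FS)
#'    specifications and write `results.csv`.
#' 4. `stage_select` — ANOVA + Tukey grouping; writes `optimal_fs.csv`,
#'    `optimal_mps.csv` and `summary.json` (two-way ANOVA p-values and the
#'    headline optima).
#'
#' A `manifest.json` records the configuration of each completed stage;
#' [run_pipeline()] skips a stage when its stored configuration matches and
#' its outputs exist.
#'
#' @param outdir output directory (created if absent).
#' @param sim_cfg a [sim_config()].
#' @param cfg a [run_config()].
#' @param specs data frame of (MPS, FS) specifications; default the full
#'   945-row factorial over the recording's channels.
#' @param alpha significance level for the selection stage.
#' @return Each stage returns its primary artifact path, invisibly;
#'   `run_pipeline` returns the manifest list.
#' @name pipeline
NULL

manifest_path <- function(outdir) file.path(outdir, "manifest.json")

read_manifest <- function(outdir) {
  p <- manifest_path(outdir)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE)
  else list()
}

update_manifest <- function(outdir, stage, cfg_record) {
  m <- read_manifest(outdir)
  m[[stage]] <- list(config = cfg_record,
                     completed = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(m, manifest_path(outdir), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(m)
}

stage_fresh <- function(outdir, stage, cfg_record, outputs) {
  m <- read_manifest(outdir)
  !is.null(m[[stage]]) && identical(m[[stage]]$config, cfg_record) &&
    all(file.exists(file.path(outdir, outputs)))
}

# manifests round-trip through JSON; compare on the JSON image so numeric
# types survive
cfg_record <- function(x) {
  jsonlite::parse_json(jsonlite::toJSON(unclass(x), auto_unbox = TRUE,
                                        digits = NA),
                       simplifyVector = TRUE)
}

#' @rdname pipeline
#' @export
stage_simulate <- function(outdir, sim_cfg) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rec <- generate_recording(sim_cfg)
  write_recording(rec, file.path(outdir, "recording.csv"))
  update_manifest(outdir, "simulate", cfg_record(sim_cfg))
  message("simulate: ", nrow(rec$emg), " samples, ",
          nrow(attr(rec, "actions")), " actions -> recording.csv")
  invisible(file.path(outdir, "recording.csv"))
}

#' @rdname pipeline
#' @export
stage_extract <- function(outdir, cfg = run_config()) {
  rec_path <- file.path(outdir, "recording.csv")
  if (!file.exists(rec_path))
    stop("missing ", rec_path, "; run stage_simulate (or cmd simulate) first",
         call. = FALSE)
  rec <- read_recording(rec_path)
  spans <- detect_actions(rec, cfg$force_threshold_fraction)
  segs <- trim_segments(spans, rec)
  utils::write.csv(segs, file.path(outdir, "segments.csv"),
                   row.names = FALSE)
  wcfg <- window_config(rec$fs, cfg$window_ms, cfg$overlap_fraction)
  tab <- extract_features(rec, segs, wcfg,
                          zc_threshold = cfg$zc_threshold,
                          wamp_threshold = cfg$wamp_threshold)
  write_feature_table(tab, file.path(outdir, "features.csv"))
  update_manifest(outdir, "extract", cfg_record(cfg))
  message("extract: ", nrow(segs), " segments, ", nrow(tab),
          " windows -> features.csv")
  invisible(file.path(outdir, "features.csv"))
}

#' @rdname pipeline
#' @export
stage_trials <- function(outdir, cfg = run_config(), specs = NULL) {
  feat_path <- file.path(outdir, "features.csv")
  if (!file.exists(feat_path))
    stop("missing ", feat_path, "; run stage_extract (or cmd extract) first",
         call. = FALSE)
  tab <- read_feature_table(feat_path)
  if (is.null(specs))
    specs <- subset_specs(enumerate_mps(attr(tab, "channels")),
                          enumerate_fs(attr(tab, "features")))
  res <- run_trials(tab, specs, cfg, progress = 100)
  write_results(res, file.path(outdir, "results.csv"))
  update_manifest(outdir, "trials",
                  list(cfg = cfg_record(cfg), specs = cfg_record(specs)))
  message("trials: ", nrow(specs), " specs x ", cfg$n_repeats,
          " repeats = ", nrow(res), " results -> results.csv")
  invisible(file.path(outdir, "results.csv"))
}

#' @rdname pipeline
#' @export
stage_select <- function(outdir, alpha = 0.05) {
  res_path <- file.path(outdir, "results.csv")
  if (!file.exists(res_path))
    stop("missing ", res_path, "; run stage_trials (or cmd trials) first",
         call. = FALSE)
  res <- read_results(res_path)
  reports <- build_reports(res, alpha = alpha)
  utils::write.csv(reports$optimal_fs, file.path(outdir, "optimal_fs.csv"),
                   row.names = FALSE)
  utils::write.csv(reports$optimal_mps, file.path(outdir, "optimal_mps.csv"),
                   row.names = FALSE)
  summary <- list(alpha = alpha, n_results = nrow(res))
  if (length(unique(res$mps)) > 1 && length(unique(res$fs)) > 1) {
    for (m in c("nrms", "nmae", "cc"))
      summary[[paste0("two_way_p_", m)]] <-
        as.list(two_way_anova(res[!is.na(res[[m]]), ], m)$p)
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  update_manifest(outdir, "select", list(alpha = alpha))
  message("select: ", nrow(reports$optimal_fs), " MPS rows, ",
          nrow(reports$optimal_mps), " FS rows -> optimal_*.csv")
  invisible(file.path(outdir, "summary.json"))
}

#' @rdname pipeline
#' @export
run_pipeline <- function(outdir, sim_cfg = sim_config(),
                         cfg = run_config(), specs = NULL,
                         alpha = cfg$alpha) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!stage_fresh(outdir, "simulate", cfg_record(sim_cfg), "recording.csv"))
    stage_simulate(outdir, sim_cfg)
  if (!stage_fresh(outdir, "extract", cfg_record(cfg), "features.csv"))
    stage_extract(outdir, cfg)
  trial_rec <- list(cfg = cfg_record(cfg),
                    specs = if (is.null(specs)) NULL else cfg_record(specs))
  if (!stage_fresh(outdir, "trials", trial_rec, "results.csv"))
    stage_trials(outdir, cfg, specs)
  stage_select(outdir, alpha)
  read_manifest(outdir)
}

#' Write / read a feature table as CSV
#'
#' Full-precision CSV with the `<channel>_<feature>` columns followed by
#' `force`, `segment_id`, `action_id`.
#'
#' @param table a `feature_table`.
#' @param path CSV path.
#' @return `path` / the `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  nmx <- names(table)
  lines <- paste(nmx, collapse = ",")
  if (nrow(table) > 0) {
    cols <- lapply(nmx, function(nm) {
      if (nm %in% c("segment_id", "action_id"))
        as.character(table[[nm]])
      else fmt_full(table[[nm]])
    })
    lines <- c(lines, do.call(paste, c(cols, sep = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  feat_cols <- setdiff(names(df), c("force", "segment_id", "action_id"))
  parts <- strsplit(feat_cols, "_", fixed = TRUE)
  channels <- unique(vapply(parts, `[`, "", 1))
  features <- FEATURE_ORDER[FEATURE_ORDER %in%
                              unique(vapply(parts, `[`, "", 2))]
  structure(df, class = c("feature_table", "data.frame"),
            channels = channels, features = features)
}
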