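#' Enumerate measurement-position sets and feature sets
#'
#' The optimization is exhaustive: every non-empty subset of the six
#' electrode measurement positions (63 MPSs) is crossed with every non-empty
#' subset of the four time-domain features (15 FSs), giving 945 data sets.
#' Enumeration order is deterministic — by subset size, then lexicographic
#' in the input order — so result keys are stable across runs.
#'
#' Canonical names follow the field's notation: positions joined with `+` in
#' index order (`"P1+P2+P5"`), feature letters concatenated in the order
#' V, I, W, Z (`"IW"`, `"VIWZ"`).
#'
#' @param channels character vector of distinct channel labels.
#' @param features character vector of distinct feature letters.
#' @return A named list of character vectors; names are canonical set names.
#' @name enumerate_sets
NULL

enumerate_subsets <- function(items, sep) {
  if (anyDuplicated(items)) stop("labels must be distinct", call. = FALSE)
  n <- length(items)
  out <- list()
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k, simplify = FALSE)
    out <- c(out, lapply(combos, function(ix) items[ix]))
  }
  names(out) <- vapply(out, paste, "", collapse = sep)
  out
}

#' @rdname enumerate_sets
#' @export
enumerate_mps <- function(channels = paste0("P", 1:6)) {
  enumerate_subsets(channels, sep = "+")
}

#' @rdname enumerate_sets
#' @export
enumerate_fs <- function(features = FEATURE_ORDER) {
  features <- FEATURE_ORDER[FEATURE_ORDER %in% features]
  if (length(features) == 0) stop("no valid feature letters", call. = FALSE)
  enumerate_subsets(features, sep = "")
}

#' Canonical names for position and feature sets
#'
#' @param mps character vector of channel labels (any order).
#' @param fs character vector of feature letters (any order).
#' @return A single canonical name string.
#' @export
canonical_mps <- function(mps) {
  paste(mps[order(mps_index(mps))], collapse = "+")
}

mps_index <- function(mps) {
  idx <- suppressWarnings(as.integer(sub("^\\D*", "", mps)))
  if (anyNA(idx)) order(mps) else idx
}

#' @rdname canonical_mps
#' @export
canonical_fs <- function(fs) {
  paste(FEATURE_ORDER[FEATURE_ORDER %in% fs], collapse = "")
}

#' Build the full (MPS, FS) factorial of subset specifications
#'
#' @param mps_list,fs_list named lists from [enumerate_mps()] /
#'   [enumerate_fs()] (defaults enumerate everything).
#' @return Data frame with one row per (MPS, FS) pair: columns `mps`, `fs`
#'   (canonical names), `n_positions`, `n_features`, `input_dim`
#'   (`n_positions * n_features`, the GRNN input-layer width). 63 x 15 = 945
#'   rows at the defaults.
#' @export
subset_specs <- function(mps_list = enumerate_mps(),
                         fs_list = enumerate_fs()) {
  grid <- expand.grid(fs = names(fs_list), mps = names(mps_list),
                      stringsAsFactors = FALSE)
  np <- lengths(mps_list)[grid$mps]
  nf <- lengths(fs_list)[grid$fs]
  data.frame(mps = grid$mps, fs = grid$fs,
             n_positions = as.integer(np), n_features = as.integer(nf),
             input_dim = as.integer(np * nf))
}

#' Project a feature table onto one (MPS, FS) pair
#'
#' Keeps only the feature columns belonging to the requested channels and
#' features (plus `force`, `segment_id`, `action_id`); rows and targets are
#' unchanged. The projected column count is `|mps| * |fs|`.
#'
#' @param table a `feature_table` from [extract_features()].
#' @param mps channel labels, or a canonical `"P1+P2"` string.
#' @param fs feature letters, or a canonical `"IW"` string.
#' @return A `feature_table` with the selected columns.
#' @export
project_features <- function(table, mps, fs) {
  if (length(mps) == 1 && grepl("+", mps, fixed = TRUE))
    mps <- strsplit(mps, "+", fixed = TRUE)[[1]]
  if (length(fs) == 1 && nchar(fs) > 1)
    fs <- strsplit(fs, "")[[1]]
  have_ch <- attr(table, "channels")
  have_f <- attr(table, "features")
  if (!all(mps %in% have_ch))
    stop("unknown channel label(s): ",
         paste(setdiff(mps, have_ch), collapse = ", "), call. = FALSE)
  if (!all(fs %in% have_f))
    stop("unknown feature letter(s): ",
         paste(setdiff(fs, have_f), collapse = ", "), call. = FALSE)
  mps <- have_ch[have_ch %in% mps]
  fs <- FEATURE_ORDER[FEATURE_ORDER %in% fs]
  cols <- as.vector(t(outer(mps, fs, paste, sep = "_")))
  out <- table[, c(cols, "force", "segment_id", "action_id"), drop = FALSE]
  structure(out, class = c("feature_table", "data.frame"),
            channels = mps, features = fs)
}
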