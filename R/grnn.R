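#' Fit a general regression neural network (GRNN)
#'
#' A GRNN is one-pass Gaussian kernel regression: training stores the
#' patterns, and the prediction for a query `x` is the kernel-weighted
#' average of the training targets,
#' `yhat(x) = sum_i y_i exp(-d_i^2 / (2 sigma^2)) / sum_i exp(-d_i^2 / (2 sigma^2))`,
#' where `d_i` is the Euclidean distance from `x` to training pattern `i`.
#' Features are standardized (center/scale learned on the training data;
#' constant columns get scale 1) before distances are computed, so
#' large-magnitude features such as IEMG do not dominate the metric. The
#' spread `sigma` interpolates between nearest-neighbor recall
#' (`sigma -> 0`) and the global training mean (`sigma -> Inf`).
#'
#' @param x numeric matrix (or feature-column data frame) of training
#'   inputs, one row per window.
#' @param y numeric vector of training targets (force, N).
#' @param spread positive kernel spread sigma, in standardized-feature
#'   units.
#' @return An object of class `grnn`.
#' @export
grnn_fit <- function(x, y, spread) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) < 1) stop("empty training set", call. = FALSE)
  if (nrow(x) != length(y))
    stop("x and y must have the same number of rows", call. = FALSE)
  if (!is.numeric(spread) || length(spread) != 1 || spread <= 0)
    stop("spread must be a single positive number", call. = FALSE)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  if (nrow(x) == 1) scale[] <- 1
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  structure(list(x = xs, y = y, spread = spread,
                 center = center, scale = scale),
            class = "grnn")
}

#' Predict grasp force with a fitted GRNN
#'
#' @param object a `grnn` from [grnn_fit()].
#' @param newdata matrix or data frame of query rows, same columns as the
#'   training inputs.
#' @param ... unused.
#' @return Numeric vector of predictions, each a convex combination of the
#'   training targets (hence always within their range). The squared
#'   distances are shifted by their per-query minimum before
#'   exponentiation, so tiny spreads cannot underflow every weight.
#' @export
predict.grnn <- function(object, newdata, ...) {
  q <- as.matrix(newdata)
  if (ncol(q) != ncol(object$x))
    stop("newdata must have ", ncol(object$x), " columns", call. = FALSE)
  qs <- sweep(sweep(q, 2, object$center), 2, object$scale, "/")
  # d2[i, j] = squared distance from query i to pattern j
  d2 <- outer(rowSums(qs^2), rowSums(object$x^2), "+") -
    2 * tcrossprod(qs, object$x)
  d2 <- pmax(d2, 0)
  d2 <- d2 - apply(d2, 1, min)
  w <- exp(-d2 / (2 * object$spread^2))
  as.numeric((w %*% object$y) / rowSums(w))
}

#' Select the GRNN spread on an inner action-wise hold-out
#'
#' Evaluates each candidate spread by fitting on a training subset of
#' actions and scoring NRMS on held-out actions, then returns the candidate
#' with the smallest hold-out NRMS (ties: first occurrence in the grid).
#' With five or more actions a single random 4/5 vs 1/5 action split is
#' used; with fewer, leave-one-action-out. The split is drawn from the
#' caller's RNG stream, so results are deterministic under a fixed seed.
#'
#' @param x training inputs (matrix/data frame of feature columns).
#' @param y training targets (force, N).
#' @param action_id per-row action labels; splits never divide an action.
#' @param candidates non-empty grid of positive spreads.
#' @param holdout_fraction fraction of actions held out when not using
#'   leave-one-out.
#' @return The selected spread (a single number).
#' @export
select_spread <- function(x, y, action_id,
                          candidates = 10^seq(-2, 1, length.out = 7),
                          holdout_fraction = 0.2) {
  if (length(candidates) < 1) stop("empty candidate grid", call. = FALSE)
  if (length(candidates) == 1) return(candidates)
  x <- as.matrix(x)
  actions <- unique(action_id)
  folds <- if (length(actions) >= 5) {
    n_hold <- max(1L, round(holdout_fraction * length(actions)))
    list(sample(actions, n_hold))
  } else {
    as.list(actions)
  }
  fmax <- max(y); fmin <- min(y)
  if (!(fmax > fmin)) return(candidates[1])  # constant target: any spread
  score <- numeric(length(candidates))
  for (fold in folds) {
    hold <- action_id %in% fold
    if (all(hold) || !any(hold)) next
    for (k in seq_along(candidates)) {
      fit <- grnn_fit(x[!hold, , drop = FALSE], y[!hold], candidates[k])
      pred <- predict(fit, x[hold, , drop = FALSE])
      score[k] <- score[k] + nrms(pred, y[hold], fmax, fmin)
    }
  }
  candidates[which.min(score)]
}

#' Run repeated train/test trials over (MPS, FS) specifications
#'
#' For each specification and each repeat, a fresh action-wise split assigns
#' `train_fraction` of the actions (4/5 at the default) to training and the
#' rest to testing — windows of one action never straddle the split, which
#' would leak overlapping windows across it. A GRNN is fitted on the
#' training windows (spread fixed by `cfg$grnn_spread`, or selected per
#' training fold when `"auto"`), the test windows are predicted, and NRMS,
#' NMAE and CC are computed against the test targets with the force range
#' taken over the entire table.
#'
#' Each (spec, repeat) trial derives its own RNG stream deterministically
#' from `cfg$seed`, the spec index and the repeat index, so results are
#' identical regardless of execution order.
#'
#' @param table a `feature_table` over all channels/features needed by
#'   `specs`.
#' @param specs data frame from [subset_specs()] (columns `mps`, `fs`).
#' @param cfg a [run_config()].
#' @param progress print a line every `progress` specs (0 = silent).
#' @return Data frame with columns `mps`, `fs`, `repeat`, `nrms`, `nmae`,
#'   `cc`; `nrow = nrow(specs) * cfg$n_repeats` (945 x 10 = 9,450 at the
#'   full factorial and default repeats). A degenerate trial whose
#'   correlation is undefined records `cc = NA` with a warning.
#' @export
run_trials <- function(table, specs, cfg = run_config(), progress = 0) {
  stopifnot(inherits(cfg, "run_config"))
  actions <- unique(table$action_id)
  if (length(actions) < 5)
    stop("need at least 5 actions for a ", cfg$train_fraction,
         " action-wise split", call. = FALSE)
  n_test <- max(1L, round((1 - cfg$train_fraction) * length(actions)))
  fmax <- max(table$force); fmin <- min(table$force)
  if (!(fmax > fmin)) stop("force target is constant", call. = FALSE)

  feat_mat <- as.matrix(table[, setdiff(names(table),
                                        c("force", "segment_id",
                                          "action_id")), drop = FALSE])
  y_all <- table$force
  aid <- table$action_id

  n_out <- nrow(specs) * cfg$n_repeats
  out <- data.frame(mps = character(n_out), fs = character(n_out),
                    "repeat" = integer(n_out), nrms = numeric(n_out),
                    nmae = numeric(n_out), cc = numeric(n_out),
                    check.names = FALSE)
  row <- 0L
  for (i in seq_len(nrow(specs))) {
    cols <- spec_columns(specs$mps[i], specs$fs[i], colnames(feat_mat))
    xm <- feat_mat[, cols, drop = FALSE]
    for (r in seq_len(cfg$n_repeats)) {
      set.seed(trial_seed(cfg$seed, i, r))
      test_actions <- sample(actions, n_test)
      test <- aid %in% test_actions
      sigma <- if (identical(cfg$grnn_spread, "auto")) {
        select_spread(xm[!test, , drop = FALSE], y_all[!test], aid[!test],
                      cfg$spread_grid,
                      holdout_fraction = 1 - cfg$train_fraction)
      } else cfg$grnn_spread
      fit <- grnn_fit(xm[!test, , drop = FALSE], y_all[!test], sigma)
      pred <- predict(fit, xm[test, , drop = FALSE])
      corr <- tryCatch(cc(pred, y_all[test]), error = function(e) {
        warning("undefined correlation for ", specs$mps[i], "|",
                specs$fs[i], " repeat ", r, "; recorded as NA",
                call. = FALSE)
        NA_real_
      })
      row <- row + 1L
      out$mps[row] <- specs$mps[i]
      out$fs[row] <- specs$fs[i]
      out[["repeat"]][row] <- r
      out$nrms[row] <- nrms(pred, y_all[test], fmax, fmin)
      out$nmae[row] <- nmae(pred, y_all[test], fmax, fmin)
      out$cc[row] <- corr
    }
    if (progress > 0 && i %% progress == 0)
      message("  spec ", i, "/", nrow(specs))
  }
  out
}

# deterministic per-trial seed below 2^31, decorrelated across (spec, repeat)
trial_seed <- function(master, spec_index, repeat_index) {
  as.integer((as.double(master) * 48271 + spec_index * 100003 +
                repeat_index * 7919) %% 2147483629)
}

spec_columns <- function(mps_name, fs_name, available) {
  mps <- strsplit(mps_name, "+", fixed = TRUE)[[1]]
  fs <- strsplit(fs_name, "")[[1]]
  cols <- as.vector(t(outer(mps, fs, paste, sep = "_")))
  missing <- setdiff(cols, available)
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cols
}
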