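#' Evaluation metrics for force estimation
#'
#' Three statistics compare an estimated force sequence `est` with the
#' measured sequence `act` of the same length `N`:
#'
#' * **NRMS** `= sqrt( sum((est - act)^2) / (N - 1) ) / (fmax - fmin)` —
#'   range-normalized root-mean-square error; larger values mean larger
#'   fluctuation of the estimate around the truth.
#' * **NMAE** `= sum(|est - act|) / (N * (fmax - fmin))` — range-normalized
#'   mean absolute error.
#' * **CC** — Pearson correlation between `est` and `act`.
#'
#' `fmax` and `fmin` are the extremes of the measured force over the whole
#' experiment (not per test fold), so errors from different data sets share
#' one normalization.
#'
#' @param est estimated force (N).
#' @param act measured force (N), same length as `est` (>= 2).
#' @param fmax,fmin experiment-wide extremes of the measured force,
#'   `fmax > fmin`.
#' @return A single number; NRMS and NMAE are non-negative fractions of the
#'   force range, CC lies in `[-1, 1]`.
#' @name force_metrics
NULL

check_metric_inputs <- function(est, act, fmax, fmin) {
  if (length(est) != length(act))
    stop("est and act must have the same length", call. = FALSE)
  if (length(est) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!(fmax > fmin)) stop("fmax must exceed fmin", call. = FALSE)
}

#' @rdname force_metrics
#' @export
nrms <- function(est, act, fmax, fmin) {
  check_metric_inputs(est, act, fmax, fmin)
  n <- length(est)
  sqrt(sum((est - act)^2) / (n - 1)) / (fmax - fmin)
}

#' @rdname force_metrics
#' @export
nmae <- function(est, act, fmax, fmin) {
  check_metric_inputs(est, act, fmax, fmin)
  sum(abs(est - act)) / (length(est) * (fmax - fmin))
}

#' @rdname force_metrics
#' @export
cc <- function(est, act) {
  if (length(est) != length(act))
    stop("est and act must have the same length", call. = FALSE)
  if (length(est) < 2) stop("need at least 2 samples", call. = FALSE)
  if (stats::sd(est) == 0 || stats::sd(act) == 0)
    stop("correlation undefined: a sequence has zero variance",
         call. = FALSE)
  stats::cor(est, act)
}
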