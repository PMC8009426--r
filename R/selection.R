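#' One-way fixed-effects ANOVA over factor levels
#'
#' Tests whether the per-repeat metric values differ across levels of one
#' factor (feature sets for a fixed position set, or position sets for a
#' fixed feature set). Degenerate designs are guarded: zero within-group
#' variance with separated means reports `F = Inf, p = 0`; identical
#' observations everywhere report `F = 0, p = 1`.
#'
#' @param values numeric metric values (one per trial).
#' @param groups factor-level label per value; every level needs >= 2
#'   replicates and >= 2 levels must be present.
#' @return List with `f`, `p`, `df_between`, `df_within`, `ms_within`,
#'   `means` (named level means) and `n` (named level counts).
#' @export
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 levels", call. = FALSE)
  n <- table(g)
  if (any(n < 2))
    stop("every level needs >= 2 replicates; offending level: ",
         names(n)[n < 2][1], call. = FALSE)
  means <- tapply(values, g, mean)
  df_b <- nlevels(g) - 1L
  df_w <- length(values) - nlevels(g)
  ss_within <- sum((values - means[g])^2)
  if (ss_within <= .Machine$double.eps * sum(values^2)) {
    # zero within-group variance: F is 0/0 or +Inf, guard explicitly
    separated <- stats::var(as.vector(means)) > 0
    return(list(f = if (separated) Inf else 0,
                p = if (separated) 0 else 1,
                df_between = df_b, df_within = df_w,
                ms_within = 0, means = means, n = as.vector(n)))
  }
  tab <- stats::anova(stats::lm(values ~ g))
  list(f = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df_between = df_b, df_within = df_w,
       ms_within = tab$`Mean Sq`[2], means = means, n = as.vector(n))
}

#' Balanced two-way ANOVA with interaction
#'
#' Fixed-effects two-factor ANOVA on the full (MPS x FS x repeat)
#' factorial, testing the main effects of measurement-position set and
#' feature set and their interaction.
#'
#' @param results data frame with columns `mps`, `fs` and the metric column.
#' @param metric metric column name (`"nrms"`, `"nmae"` or `"cc"`).
#' @return List with `f` and `p`, each a named vector over
#'   `c("mps", "fs", "mps:fs")`.
#' @export
two_way_anova <- function(results, metric = "nrms") {
  df <- data.frame(y = results[[metric]], mps = factor(results$mps),
                   fs = factor(results$fs))
  if (stats::var(df$y) == 0) {
    z <- c(mps = 0, fs = 0, "mps:fs" = 0)
    return(list(f = z, p = c(mps = 1, fs = 1, "mps:fs" = 1)))
  }
  tab <- stats::anova(stats::lm(y ~ mps * fs, data = df))
  terms <- c("mps", "fs", "mps:fs")
  ix <- match(terms, rownames(tab))  # a term can drop out of a sparse design
  f <- stats::setNames(tab$`F value`[ix], terms)
  p <- stats::setNames(tab$`Pr(>F)`[ix], terms)
  list(f = f, p = p)
}

#' Tukey HSD homogeneous subsets of factor levels
#'
#' After a significant ANOVA, levels are grouped into homogeneous subsets in
#' the style of SPSS's post-hoc tables: level means are ordered from best to
#' worst (smallest first for error metrics, largest first for correlation)
#' and maximal runs of consecutive levels whose range does not exceed the
#' Tukey HSD critical difference
#' `qtukey(1 - alpha, k, df) * sqrt(MS_within / n_h)` form the subsets.
#' Levels with statistically indistinguishable means share a subset; a level
#' may belong to several consecutive subsets. Each subset is annotated with
#' the studentized-range p-value of its extreme means (1 for singletons).
#' Unbalanced replicate counts are handled with the harmonic mean of the
#' level sizes, with a warning.
#'
#' When the ANOVA is not significant at `alpha` the grouping is still
#' computed but flagged `significant = FALSE`.
#'
#' @param values numeric metric values.
#' @param groups level label per value.
#' @param alpha familywise significance level.
#' @param direction `"min"` when smaller means are better (NRMS, NMAE),
#'   `"max"` when larger are better (CC).
#' @return An object of class `tukey_subsets`: list with `levels` (data
#'   frame of level, mean, n, ordered best first), `subsets` (list of
#'   character vectors, best first), `subset_p`, `anova` (the
#'   [one_way_anova()] result), `significant`, `alpha`, `direction`,
#'   `critical_difference`.
#' @export
tukey_subsets <- function(values, groups, alpha = 0.05,
                          direction = c("min", "max")) {
  direction <- match.arg(direction)
  aov_res <- one_way_anova(values, groups)
  means <- aov_res$means
  k <- length(means)
  n <- aov_res$n
  n_h <- if (length(unique(n)) > 1) {
    warning("unbalanced replicate counts; using harmonic mean n",
            call. = FALSE)
    k / sum(1 / n)
  } else n[1]

  ord <- order(means, decreasing = (direction == "max"))
  lv <- data.frame(level = names(means)[ord], mean = as.vector(means)[ord],
                   n = n[ord], stringsAsFactors = FALSE)

  if (aov_res$ms_within == 0) {
    crit <- 0
    se <- 0
  } else {
    se <- sqrt(aov_res$ms_within / n_h)
    crit <- stats::qtukey(1 - alpha, k, aov_res$df_within) * se
  }

  # maximal runs of consecutive ordered levels whose range <= crit
  subsets <- list(); subset_p <- numeric(0)
  i <- 1L
  tol <- 1e-12 * max(1, abs(lv$mean[1]))
  while (i <= k) {
    j <- i
    while (j < k && abs(lv$mean[j + 1] - lv$mean[i]) <= crit + tol)
      j <- j + 1L
    # keep only maximal runs: skip if contained in the previous one
    if (length(subsets) == 0 ||
        !all(lv$level[i:j] %in% subsets[[length(subsets)]])) {
      subsets[[length(subsets) + 1L]] <- lv$level[i:j]
      rng <- abs(lv$mean[j] - lv$mean[i])
      subset_p <- c(subset_p,
                    if (j == i || se == 0) 1
                    else stats::ptukey(rng / se, k, aov_res$df_within,
                                       lower.tail = FALSE))
    }
    if (j == k) break
    i <- i + 1L
  }

  structure(list(levels = lv, subsets = subsets, subset_p = subset_p,
                 anova = aov_res, significant = aov_res$p < alpha,
                 alpha = alpha, direction = direction,
                 critical_difference = crit),
            class = "tukey_subsets")
}

#' @export
print.tukey_subsets <- function(x, ...) {
  cat("Tukey HSD homogeneous subsets (", x$direction,
      " is better; alpha = ", x$alpha, ")\n", sep = "")
  cat(sprintf("one-way ANOVA: F = %.4g, p = %.4g%s\n", x$anova$f, x$anova$p,
              if (x$significant) "" else "  [not significant]"))
  for (s in seq_along(x$subsets))
    cat(sprintf("  subset %d (p = %.4f): %s\n", s, x$subset_p[s],
                paste(x$subsets[[s]], collapse = ", ")))
  invisible(x)
}

#' Pick the optimal level from a homogeneous-subset grouping
#'
#' Within the best subset (highest estimation accuracy), the optimal level
#' is the one with the smallest cardinality — the fewest measurement
#' positions or features, hence the smallest GRNN input dimension. Ties on
#' cardinality are broken by the better mean metric; remaining exact ties by
#' canonical name order (reported via a message).
#'
#' @param grouping a `tukey_subsets`.
#' @param cardinality named integer vector giving each level's size (number
#'   of positions or features).
#' @return List with `level`, `cardinality`, `mean`, `significant`.
#' @export
pick_optimum <- function(grouping, cardinality) {
  stopifnot(inherits(grouping, "tukey_subsets"))
  best <- grouping$subsets[[1]]
  if (!all(best %in% names(cardinality)))
    stop("cardinality must cover every level of the best subset",
         call. = FALSE)
  card <- cardinality[best]
  cand <- best[card == min(card)]
  if (length(cand) > 1) {
    m <- grouping$levels$mean[match(cand, grouping$levels$level)]
    best_m <- if (grouping$direction == "min") min(m) else max(m)
    tied <- cand[m == best_m]
    if (length(tied) > 1)
      message("exact tie between ", paste(sort(tied), collapse = ", "),
              "; choosing ", sort(tied)[1])
    cand <- sort(tied)[1]
  }
  list(level = cand,
       cardinality = unname(cardinality[cand]),
       mean = grouping$levels$mean[match(cand, grouping$levels$level)],
       significant = grouping$significant)
}

#' Build the optimal-FS-per-MPS and optimal-MPS-per-FS report tables
#'
#' For every measurement-position set, groups the 15 feature sets by Tukey
#' homogeneous subsets (per metric) and picks the optimum; and symmetrically
#' for every feature set over the position sets. With the full factorial
#' this yields a 63-row and a 15-row table, one column per metric.
#'
#' @param results trial-results data frame (`mps`, `fs`, `repeat`, `nrms`,
#'   `nmae`, `cc`).
#' @param alpha significance level passed to [tukey_subsets()].
#' @return List with data frames `optimal_fs` (one row per MPS) and
#'   `optimal_mps` (one row per FS), each with columns for the three
#'   metrics, plus `anova_significant` flags.
#' @export
build_reports <- function(results, alpha = 0.05) {
  metrics <- c(nrms = "min", nmae = "min", cc = "max")

  optimize_over <- function(by, level_col) {
    keys <- unique(results[[by]])
    keys <- keys[order(level_cardinality(keys, by), keys)]
    out <- data.frame(key = keys, stringsAsFactors = FALSE)
    names(out) <- by
    for (m in names(metrics)) {
      picks <- character(length(keys))
      sig <- logical(length(keys))
      for (q in seq_along(keys)) {
        sub <- results[results[[by]] == keys[q] & !is.na(results[[m]]), ]
        # a level whose metric is undefined in <2 repeats cannot be ranked
        n_ok <- table(sub[[level_col]])
        droppable <- names(n_ok)[n_ok < 2]
        if (length(droppable)) {
          warning("dropping level(s) with <2 defined ", m, " values for ",
                  keys[q], ": ", paste(droppable, collapse = ", "),
                  call. = FALSE)
          sub <- sub[!(sub[[level_col]] %in% droppable), ]
        }
        lvls <- unique(sub[[level_col]])
        if (length(lvls) < 2) {
          # nothing to compare: the lone level is trivially optimal
          picks[q] <- lvls
          sig[q] <- NA
          next
        }
        grouping <- tukey_subsets(sub[[m]], sub[[level_col]], alpha = alpha,
                                  direction = metrics[[m]])
        card <- stats::setNames(level_cardinality(lvls, level_col), lvls)
        opt <- pick_optimum(grouping, card)
        picks[q] <- opt$level
        sig[q] <- opt$significant
      }
      out[[m]] <- picks
      out[[paste0(m, "_significant")]] <- sig
    }
    out
  }

  list(optimal_fs = optimize_over("mps", "fs"),
       optimal_mps = optimize_over("fs", "mps"))
}

# cardinality of a canonical level name: number of '+'-joined positions for
# an MPS, number of feature letters for an FS
level_cardinality <- function(x, kind) {
  if (kind == "mps") lengths(strsplit(x, "+", fixed = TRUE))
  else nchar(x)
}
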