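# Shared fixtures built in code.

# A small, fast simulation: 8 actions (2 per level), everything else default.
small_sim <- function(seed = 1, ...) {
  sim_config(n_actions = 8, actions_per_level = 2, seed = seed, ...)
}

# A recording with a hand-made force trace and white-noise EMG, for
# segmentation tests where exact burst placement matters.
force_recording <- function(force, n_channels = 1, fs = 1000, seed = 99) {
  set.seed(seed)
  emg <- matrix(rnorm(length(force) * n_channels, sd = 10),
                ncol = n_channels)
  recording(fs = fs, emg = emg, force = force)
}

# A synthetic feature table over the full 6-channel x 4-feature grid,
# without running the simulator: feature columns are noisy functions of a
# per-window latent force. Used where only the table's structure matters.
toy_feature_table <- function(n_actions = 6, windows_per_action = 3,
                              channels = paste0("P", 1:6),
                              features = c("V", "I", "W", "Z"),
                              seed = 1) {
  set.seed(seed)
  n <- n_actions * windows_per_action
  force <- rep(runif(n_actions, 10, 250), each = windows_per_action) +
    rnorm(n, sd = 2)
  cols <- as.vector(t(outer(channels, features, paste, sep = "_")))
  tab <- as.data.frame(sapply(cols, function(nm) force * runif(1, 0.5, 2) +
                                rnorm(n, sd = 5)))
  tab$force <- pmax(force, 0)
  tab$segment_id <- rep(seq_len(n_actions), each = windows_per_action)
  tab$action_id <- tab$segment_id
  structure(tab, class = c("feature_table", "data.frame"),
            channels = channels, features = features)
}

# Textbook one-way fixed-effects ANOVA from raw sums of squares; the
# independent oracle for the package's ANOVA path.
anova_oracle <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  n_tot <- length(values)
  grand <- mean(values)
  means <- tapply(values, g, mean)
  n <- as.vector(table(g))
  ss_b <- sum(n * (means - grand)^2)
  ss_w <- sum((values - means[g])^2)
  f <- (ss_b / (k - 1)) / (ss_w / (n_tot - k))
  list(f = f, p = pf(f, k - 1, n_tot - k, lower.tail = FALSE))
}

# Exhaustive all-pairs studentized-range grouping oracle: every maximal set
# of levels that (a) is a consecutive run of the ordered means and (b) has
# all pairwise ranges below the Tukey HSD critical difference.
subsets_oracle <- function(values, groups, alpha = 0.05,
                           direction = "min") {
  g <- factor(groups)
  means <- tapply(values, g, mean)
  n <- as.vector(table(g))
  k <- length(means)
  df_w <- length(values) - k
  ms_w <- sum((values - means[g])^2) / df_w
  n_h <- k / sum(1 / n)
  crit <- qtukey(1 - alpha, k, df_w) * sqrt(ms_w / n_h)
  ord <- order(means, decreasing = (direction == "max"))
  m <- as.vector(means)[ord]
  lvl <- names(means)[ord]
  tol <- 1e-12 * max(1, abs(m[1]))
  ok <- function(ix) all(combn(ix, 2, function(p)
    abs(m[p[2]] - m[p[1]]) <= crit + tol))
  runs <- list()
  for (i in seq_len(k)) for (j in i:k) {
    ix <- i:j
    if (length(ix) == 1 || ok(ix)) runs[[length(runs) + 1]] <- ix
  }
  # maximal runs only
  keep <- vapply(runs, function(r) !any(vapply(runs, function(s)
    !identical(r, s) && all(r %in% s), TRUE)), TRUE)
  lapply(runs[keep], function(ix) lvl[ix])
}
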