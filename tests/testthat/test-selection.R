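test_that("one-way ANOVA matches textbook sums of squares", {
  set.seed(15)
  for (i in 1:30) {
    k <- sample(2:8, 1)
    n_per <- sample(3:12, 1)
    groups <- rep(letters[1:k], each = n_per)
    values <- rnorm(k * n_per, mean = rep(runif(k, 0, 3), each = n_per))
    got <- one_way_anova(values, groups)
    want <- anova_oracle(values, groups)
    expect_equal(got$f, want$f, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
})

test_that("degenerate one-way designs are guarded", {
  # separated means, zero within-group variance
  got <- one_way_anova(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3))
  expect_identical(got$f, Inf)
  expect_identical(got$p, 0)
  # all observations equal
  flat <- one_way_anova(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_identical(flat$f, 0)
  expect_identical(flat$p, 1)
  expect_error(one_way_anova(1:4, rep("a", 4)), "2 levels")
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "replicates")
})

test_that("indistinguishable level means share one homogeneous subset", {
  set.seed(2)
  values <- c(rnorm(20, 10, 5), rnorm(20, 10.001, 5))
  groups <- rep(c("a", "b"), each = 20)
  g <- suppressWarnings(tukey_subsets(values, groups))
  expect_length(g$subsets, 1)
  expect_setequal(g$subsets[[1]], c("a", "b"))
  expect_false(g$significant)
})

test_that("a far-away level splits into its own subset", {
  set.seed(3)
  values <- c(rnorm(10, 0, 0.5), rnorm(10, 0.01, 0.5),
              rnorm(10, 100, 0.5))
  groups <- rep(c("a", "b", "c"), each = 10)
  g <- tukey_subsets(values, groups)
  expect_length(g$subsets, 2)
  expect_setequal(g$subsets[[1]], c("a", "b"))
  expect_setequal(g$subsets[[2]], "c")
  expect_true(g$significant)
  # hand q-statistic: the a-b range must be below the critical difference
  expect_lt(abs(mean(values[1:10]) - mean(values[11:20])),
            g$critical_difference)
})

test_that("subset structure equals the exhaustive all-pairs oracle", {
  set.seed(23)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    n_per <- sample(4:10, 1)
    sep <- sample(c(0.2, 1, 5), 1)
    groups <- rep(paste0("L", 1:k), each = n_per)
    values <- rnorm(k * n_per, mean = rep(sort(runif(k, 0, sep)),
                                          each = n_per))
    dir <- sample(c("min", "max"), 1)
    got <- suppressWarnings(tukey_subsets(values, groups, direction = dir))
    want <- subsets_oracle(values, groups, direction = dir)
    expect_equal(got$subsets, want)
    # structural invariants: every level appears; memberships contiguous
    expect_setequal(unlist(got$subsets), unique(groups))
    for (lvl in unique(groups)) {
      hit <- which(vapply(got$subsets, function(s) lvl %in% s, TRUE))
      expect_equal(hit, seq(min(hit), max(hit)))
    }
    # subsets ordered best first
    first_means <- vapply(got$subsets, function(s)
      got$levels$mean[match(s[1], got$levels$level)], 0)
    expect_true(all(diff(if (dir == "min") first_means
                         else -first_means) >= 0))
  }
})

test_that("two-way ANOVA flags planted interactions and stays quiet under
           the additive null", {
  make_data <- function(seed, interact) {
    set.seed(seed)
    d <- expand.grid(mps = paste0("M", 1:3), fs = paste0("F", 1:3),
                     "repeat" = 1:4, stringsAsFactors = FALSE)
    mu <- 1 + 0.5 * as.integer(factor(d$mps)) +
      0.3 * as.integer(factor(d$fs)) +
      interact * as.integer(factor(d$mps)) * as.integer(factor(d$fs))
    d$nrms <- mu + rnorm(nrow(d), sd = 0.3)
    d
  }
  null_ps <- sapply(1:100, function(s)
    two_way_anova(make_data(s, 0))$p[["mps:fs"]])
  expect_gte(mean(null_ps > 0.05), 0.88)   # ~95% expected under the null

  alt <- two_way_anova(make_data(1, 2))
  expect_lt(alt$p[["mps:fs"]], 0.05)
  expect_lt(alt$p[["mps"]], 0.05)

  flat <- two_way_anova(data.frame(mps = rep(c("a", "b"), 4),
                                   fs = rep(c("x", "y"), each = 4),
                                   nrms = rep(1, 8)))
  expect_identical(unname(flat$f), c(0, 0, 0))
})

test_that("two-way ANOVA agrees with the balanced textbook decomposition", {
  set.seed(44)
  d <- expand.grid(mps = paste0("M", 1:4), fs = paste0("F", 1:3),
                   r = 1:5, stringsAsFactors = FALSE)
  d$nrms <- rnorm(nrow(d), mean = as.integer(factor(d$mps)) * 0.4)
  got <- two_way_anova(d)
  # oracle: balanced two-factor sums of squares
  a <- factor(d$mps); b <- factor(d$fs); y <- d$nrms
  I <- nlevels(a); J <- nlevels(b); n <- 5
  ybar <- mean(y)
  ya <- tapply(y, a, mean); yb <- tapply(y, b, mean)
  yab <- tapply(y, interaction(a, b), mean)
  ss_a <- J * n * sum((ya - ybar)^2)
  ss_b <- I * n * sum((yb - ybar)^2)
  cell_mean <- ave(y, a, b)
  ss_e <- sum((y - cell_mean)^2)
  ss_ab <- sum((cell_mean - ave(y, a) - ave(y, b) + ybar)^2)
  df_e <- I * J * (n - 1)
  f_a <- (ss_a / (I - 1)) / (ss_e / df_e)
  f_ab <- (ss_ab / ((I - 1) * (J - 1))) / (ss_e / df_e)
  expect_equal(unname(got$f[["mps"]]), f_a, tolerance = 1e-8)
  expect_equal(unname(got$f[["mps:fs"]]), f_ab, tolerance = 1e-8)
})

test_that("pick_optimum applies minimal cardinality then accuracy", {
  grouping <- structure(list(
    levels = data.frame(
      level = c("VIWZ", "IWZ", "VIW", "IW", "VIZ", "IZ"),
      mean = c(4.4103, 4.4113, 4.5638, 4.5651, 4.9456, 4.9508),
      n = rep(10, 6)),
    subsets = list(c("VIWZ", "IWZ", "VIW", "IW", "VIZ", "IZ")),
    subset_p = 0.39, anova = list(p = 1e-10), significant = TRUE,
    alpha = 0.05, direction = "min"), class = "tukey_subsets")
  card <- c(VIWZ = 4, IWZ = 3, VIW = 3, IW = 2, VIZ = 3, IZ = 2)
  opt <- pick_optimum(grouping, card)
  expect_identical(opt$level, "IW")
  expect_identical(opt$cardinality, 2)

  single <- grouping
  single$subsets <- list("VIWZ")
  expect_identical(pick_optimum(single, card)$level, "VIWZ")

  tie <- grouping
  tie$levels$mean[c(4, 6)] <- 4.5  # IW and IZ exactly tied
  expect_message(opt_t <- pick_optimum(tie, card), "tie")
  expect_identical(opt_t$level, "IW")   # lexicographically first
})

test_that("report tables select only informative channels on planted
           structure", {
  set.seed(30)
  # synthetic trial results: error depends on whether the MPS includes an
  # informative channel (P1 or P2); FS is irrelevant
  mps_names <- names(enumerate_mps(paste0("P", 1:4)))
  fs_names <- c("I", "W", "IW")
  d <- expand.grid(mps = mps_names, fs = fs_names, "repeat" = 1:6,
                   stringsAsFactors = FALSE)
  informative <- sapply(strsplit(d$mps, "+", fixed = TRUE),
                        function(m) any(c("P1", "P2") %in% m))
  d$nrms <- ifelse(informative, 0.05, 0.30) + rnorm(nrow(d), sd = 0.01)
  d$nmae <- d$nrms * 0.8 + rnorm(nrow(d), sd = 0.005)
  d$cc <- ifelse(informative, 0.95, 0.2) + rnorm(nrow(d), sd = 0.02)
  reports <- suppressWarnings(build_reports(d))
  expect_equal(nrow(reports$optimal_fs), 15)
  expect_equal(nrow(reports$optimal_mps), 3)
  for (m in c("nrms", "nmae", "cc")) {
    picked <- strsplit(reports$optimal_mps[[m]], "+", fixed = TRUE)
    expect_true(all(vapply(picked, function(p)
      any(c("P1", "P2") %in% p), TRUE)))
  }
})

test_that("the chosen optimum always lies in the best subset", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    lv <- paste0("L", 1:k)
    values <- rnorm(k * 5, mean = rep(runif(k), each = 5), sd = 0.3)
    groups <- rep(lv, each = 5)
    g <- suppressWarnings(tukey_subsets(values, groups))
    card <- setNames(sample(1:4, k, replace = TRUE), lv)
    opt <- suppressMessages(pick_optimum(g, card))
    expect_true(opt$level %in% g$subsets[[1]])
  }
})
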