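test_that("a single training pattern predicts its own target everywhere", {
  fit <- grnn_fit(matrix(c(1, 2), 1), y = 42, spread = 0.7)
  q <- matrix(rnorm(20), ncol = 2)
  expect_equal(predict(fit, q), rep(42, 10))
})

test_that("spread limits recover the training mean and nearest neighbor", {
  set.seed(3)
  x <- matrix(runif(60), ncol = 2)
  y <- runif(30, 0, 100)
  q <- matrix(runif(10), ncol = 2)

  wide <- grnn_fit(x, y, spread = 1e6)
  expect_equal(predict(wide, q), rep(mean(y), 5), tolerance = 1e-6)

  narrow <- grnn_fit(x, y, spread = 1e-4)
  xs <- scale(x)
  nn <- apply(q, 1, function(p) {
    ps <- (p - attr(xs, "scaled:center")) / attr(xs, "scaled:scale")
    which.min(colSums((t(xs) - ps)^2))
  })
  expect_equal(predict(narrow, q), y[nn])
})

test_that("predictions are convex combinations of training targets", {
  set.seed(11)
  for (sigma in c(1e-3, 0.1, 1, 50)) {
    x <- matrix(rnorm(40 * 3), ncol = 3)
    y <- rnorm(40, 50, 30)
    fit <- grnn_fit(x, y, sigma)
    q <- matrix(rnorm(1000 * 3, sd = 4), ncol = 3)
    p <- predict(fit, q)
    expect_true(all(p >= min(y) - 1e-9 & p <= max(y) + 1e-9))
    expect_true(all(is.finite(p)))
  }
})

test_that("constant feature columns are standardized harmlessly", {
  x <- cbind(rep(5, 8), rnorm(8))
  fit <- grnn_fit(x, rnorm(8), spread = 1)
  expect_true(all(is.finite(predict(fit, x))))
  expect_error(grnn_fit(x[0, ], numeric(0), 1), "empty")
  expect_error(grnn_fit(x, rnorm(8), spread = 0), "spread")
})

test_that("spread selection honors the grid contract", {
  set.seed(5)
  x <- matrix(runif(200), ncol = 2)
  y <- sin(4 * x[, 1]) + 0.1 * rnorm(100)
  aid <- rep(1:10, each = 10)

  expect_equal(select_spread(x, y, aid, candidates = 0.3), 0.3)
  expect_equal(select_spread(x, y, aid, candidates = c(0.5, 0.5, 0.5)), 0.5)

  # the selected spread beats both grid endpoints on a fresh hold-out
  grid <- 10^seq(-2, 1, length.out = 7)
  set.seed(9)
  sigma <- select_spread(x, y, aid, candidates = grid)
  hold <- aid %in% 9:10
  score <- function(s) {
    fit <- grnn_fit(x[!hold, ], y[!hold], s)
    nrms(predict(fit, x[hold, ]), y[hold], max(y), min(y))
  }
  expect_lte(score(sigma), score(grid[1]))
  expect_lte(score(sigma), score(grid[length(grid)]))
})

test_that("run_trials is reproducible and sized |specs| x n_repeats", {
  tab <- toy_feature_table(n_actions = 8)
  specs <- data.frame(mps = c("P1", "P1+P2"), fs = c("I", "IW"))
  cfg <- run_config(n_repeats = 3, grnn_spread = 0.5, seed = 77)
  a <- run_trials(tab, specs, cfg)
  b <- run_trials(tab, specs, cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 6)
  expect_identical(unique(a$mps), c("P1", "P1+P2"))
  expect_true(all(a$nrms >= 0 & a$nmae >= 0))
  expect_true(all(abs(a$cc) <= 1, na.rm = TRUE))

  other <- run_trials(tab, specs, run_config(n_repeats = 3,
                                             grnn_spread = 0.5, seed = 78))
  expect_false(identical(a$nrms, other$nrms))

  expect_error(run_trials(toy_feature_table(n_actions = 4), specs, cfg),
               "at least 5 actions")
})

test_that("force is recovered from an informative channel's IEMG", {
  # IEMG grows almost linearly with the EMG envelope, which is linear in
  # force at the default exponent; the GRNN should track it closely
  ccs <- sapply(1:5, function(s) {
    rec <- generate_recording(sim_config(n_actions = 12,
                                         actions_per_level = 3,
                                         channel_gains = c(1, 0, 0, 0, 0, 0),
                                         seed = 100 + s))
    segs <- trim_segments(detect_actions(rec), rec)
    tab <- extract_features(rec, segs, window_config(rec$fs))
    res <- run_trials(tab, data.frame(mps = "P1", fs = "I"),
                      run_config(n_repeats = 2, seed = s))
    mean(res$cc)
  })
  expect_gt(min(ccs), 0.9)
})
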