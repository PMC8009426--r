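test_that("feature definitions match hand-computed windows", {
  expect_equal(var_feature(numeric(8)), 0)
  expect_equal(var_feature(c(30, -30, 30, -30)), 900)

  expect_equal(iemg_feature(numeric(5)), 0)
  expect_equal(iemg_feature(c(1, -2, 3)), 6)

  expect_equal(zc_feature(c(5, 40, 90, 2), 30), 0)      # no sign change
  alt <- rep(c(100, -100), 10)
  expect_equal(zc_feature(alt, 30), length(alt) - 1)    # every pair crosses
  expect_equal(zc_feature(rep(c(10, -10), 10), 30), 0)  # sub-threshold

  expect_equal(wamp_feature(rep(7, 6), 150), 0)
  expect_equal(wamp_feature(c(0, 200, 0, 200), 150), 3)
})

test_that("features agree with brute-force loop evaluation on random
           windows", {
  set.seed(42)
  for (i in 1:200) {
    w <- rnorm(sample(2:50, 1), sd = sample(c(5, 40, 120), 1))
    # oracles: literal loops over the defining sums
    var_o <- 0; iemg_o <- 0; zc_o <- 0L; wamp_o <- 0L
    for (j in seq_along(w)) {
      var_o <- var_o + w[j]^2
      iemg_o <- iemg_o + abs(w[j])
      if (j > 1) {
        if (w[j] * w[j - 1] < 0 && abs(w[j] - w[j - 1]) > 30)
          zc_o <- zc_o + 1L
        if (abs(w[j] - w[j - 1]) > 150) wamp_o <- wamp_o + 1L
      }
    }
    var_o <- var_o / length(w)
    expect_equal(var_feature(w), var_o, tolerance = 1e-12)
    expect_equal(iemg_feature(w), iemg_o, tolerance = 1e-12)
    expect_identical(as.integer(zc_feature(w, 30)), zc_o)
    expect_identical(as.integer(wamp_feature(w, 150)), wamp_o)
    n <- length(w)
    expect_lte(zc_feature(w, 30), n - 1)
    expect_lte(wamp_feature(w, 150), n - 1)
  }
})

test_that("VAR and IEMG ignore sample order; ZC and WAMP do not", {
  set.seed(7)
  w <- cumsum(rnorm(40, sd = 120))   # strong serial structure
  perm <- sample(w)
  expect_equal(var_feature(perm), var_feature(w))
  expect_equal(iemg_feature(perm), iemg_feature(w))
  expect_false(zc_feature(perm, 30) == zc_feature(w, 30) &&
                 wamp_feature(perm, 150) == wamp_feature(w, 150))
})

test_that("200 ms windows at 1 kHz with 50% overlap give N=200, step=100", {
  wcfg <- window_config(fs = 1000, window_ms = 200, overlap_fraction = 0.5)
  expect_identical(wcfg$N, 200L)
  expect_identical(wcfg$step, 100L)
  expect_error(window_config(1000, window_ms = 1), ">= 2")
})

test_that("window counts per segment follow floor((L - N)/step) + 1", {
  rec <- force_recording(c(numeric(100), rep(50, 1200), numeric(200)),
                         n_channels = 2)
  segs <- trim_segments(detect_actions(rec), rec)
  expect_equal(segs$kept_end - segs$kept_start, 1500)  # 300-sample flanks
  wcfg <- window_config(1000)
  tab <- extract_features(rec, segs, wcfg)
  expect_equal(nrow(tab), 14)                       # floor((1500-200)/100)+1

  # a segment of exactly N samples yields one window
  one <- data.frame(action = 1L, onset = 1L, offset = 201L,
                    kept_start = 1L, kept_end = 201L)
  class(one) <- c("action_segments", "data.frame")
  expect_equal(nrow(extract_features(rec, one, wcfg)), 1)

  # shorter than one window: skipped with a warning
  short <- data.frame(action = 1L, onset = 1L, offset = 150L,
                      kept_start = 1L, kept_end = 150L)
  class(short) <- c("action_segments", "data.frame")
  expect_warning(tab0 <- extract_features(rec, short, wcfg), "skipped")
  expect_equal(nrow(tab0), 0)
})

test_that("feature table layout and targets are correct", {
  rec <- generate_recording(small_sim(seed = 13))
  segs <- trim_segments(detect_actions(rec), rec)
  tab <- extract_features(rec, segs, window_config(1000))
  expect_s3_class(tab, "feature_table")
  expect_identical(names(tab)[1:4], c("P1_V", "P1_I", "P1_W", "P1_Z"))
  expect_equal(ncol(tab), 6 * 4 + 3)
  expect_false(anyNA(tab))
  expect_true(all(tab$force >= 0))

  # target equals the mean force over the window's own samples
  first_start <- segs$kept_start[1]
  expect_equal(tab$force[1],
               mean(rec$force[first_start:(first_start + 199)]))

  # restricting channels/features shrinks columns accordingly
  sub <- extract_features(rec, segs, window_config(1000),
                          features = c("I", "W"),
                          channels = c("P4", "P5", "P6"))
  expect_identical(setdiff(names(sub),
                           c("force", "segment_id", "action_id")),
                   c("P4_I", "P4_W", "P5_I", "P5_W", "P6_I", "P6_W"))
  expect_error(extract_features(rec, segs, window_config(1000),
                                channels = "P9"), "P9")
})
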