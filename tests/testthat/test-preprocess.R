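test_that("moving-average smoothing matches hand-computed shrinking-edge values", {
  expect_equal(smooth_trace(c(0, 3, 0, 3, 0), 3), c(1.5, 1, 2, 1, 1.5))
  expect_equal(smooth_trace(rep(4.2, 30), 15), rep(4.2, 30))
  expect_error(smooth_trace(1:10, 0), "window_frames")
  expect_error(smooth_trace(1:10, 11), "exceed")
  expect_warning(smooth_trace(1:20, 17), "3-15")
})

test_that("smoothing preserves the trace mean to within edge effects", {
  set.seed(7)
  for (w in c(3, 9, 15)) {
    x <- abs(rnorm(500, 10, 2))
    sm <- smooth_trace(x, w)
    expect_lt(abs(mean(sm) - mean(x)) / mean(x), w / length(x))
    expect_length(sm, length(x))
  }
})

test_that("general fold change follows (F - Fmin)/Fmin and is gain-invariant", {
  expect_equal(as.numeric(fold_change_general(c(100, 150, 100))), c(0, 0.5, 0))
  expect_equal(as.numeric(fold_change_general(rep(7, 10))), rep(0, 10))
  # invariance to positive gain
  set.seed(1)
  x <- abs(rnorm(200, 100, 5))
  for (k in c(0.5, 3, 1000)) {
    expect_equal(as.numeric(fold_change_general(k * x)),
                 as.numeric(fold_change_general(x)), tolerance = 1e-12)
  }
  # min over the baseline window is exactly 0
  fc <- fold_change_general(x, baseline_window = 1:50)
  expect_equal(min(fc[1:50]), 0)
  expect_error(fold_change_general(c(0, 1, 2)), "positive")
  expect_error(fold_change_general(c(-5, 1, 2)), "positive")
})

test_that("min-max normalization maps the window onto [0, 1]", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(1, 3, 2, 5, 4)
  nx <- minmax_normalize(x)
  expect_equal(min(nx), 0)
  expect_equal(max(nx), 1)
  expect_equal(nx[which(x == 3)], 0.5)
  expect_error(minmax_normalize(rep(2, 5)), "degenerate")
})

test_that("local extrema match a brute-force scan and handle plateaus", {
  expect_equal(detect_local_extrema(1:10), list(peaks = integer(0), valleys = integer(0)))
  tri <- c(0, 1, 2, 1, 0)
  expect_equal(detect_local_extrema(tri)$peaks, 3L)
  expect_length(detect_local_extrema(tri)$valleys, 0)
  two <- c(0, 2, 0.5, 2, 0)
  expect_equal(detect_local_extrema(two), list(peaks = c(2L, 4L), valleys = 3L))
  # plateau takes its first frame
  expect_equal(detect_local_extrema(c(0, 1, 1, 1, 0))$peaks, 2L)

  brute <- function(x) {
    pk <- vl <- integer(0)
    for (i in 2:(length(x) - 1)) {
      before <- rev(x[1:(i - 1)]); after <- x[(i + 1):length(x)]
      bprev <- before[before != x[i]][1]; bnext <- after[after != x[i]][1]
      if (is.na(bprev) || is.na(bnext)) next
      if (x[i] > bprev && x[i] > bnext && x[i - 1] != x[i]) pk <- c(pk, i)
      if (x[i] < bprev && x[i] < bnext && x[i - 1] != x[i]) vl <- c(vl, i)
    }
    list(peaks = pk, valleys = vl)
  }
  set.seed(23)
  for (rep in 1:50) {
    x <- round(rnorm(40), 1)
    got <- detect_local_extrema(x)
    want <- brute(x)
    expect_equal(got$peaks, as.integer(want$peaks))
    expect_equal(got$valleys, as.integer(want$valleys))
  }
})

test_that("prominence pruning removes sub-threshold wiggles only", {
  x <- c(0, 1, 0.98, 1.01, 0, 1, 0)
  pruned <- detect_local_extrema(x, min_prominence = 0.1)
  expect_length(pruned$peaks, 2)
  expect_length(pruned$valleys, 1)
  expect_equal(pruned$valleys, 5L)
  # with zero prominence everything strict is kept
  expect_length(detect_local_extrema(x)$peaks, 3)
})

test_that("valley filtering applies the drop and proximity rules as printed", {
  mk <- function(peak_val, valley_val) {
    x <- rep(0.9, 300)
    x[100] <- peak_val
    x[200] <- valley_val
    x
  }
  x1 <- mk(1.0, 0.69)
  f1 <- filter_extrema(x1, peaks = 100L, valleys = 200L)
  expect_equal(f1$valleys, 200L) # drop 0.31 >= 0.30

  x2 <- mk(1.0, 0.75)
  f2 <- filter_extrema(x2, peaks = 100L, valleys = 200L)
  expect_length(f2$valleys, 0) # drop 0.25 < 0.30
  expect_equal(f2$removed_valleys$frame, 200L)

  # a valley 10 frames after its peak discards the peak from the pairing,
  # and the orphaned valley is retained as an anchor
  x3 <- rep(0.9, 300); x3[100] <- 1.0; x3[110] <- 0.1
  f3 <- filter_extrema(x3, peaks = 100L, valleys = 110L)
  expect_length(f3$peaks, 0)
  expect_equal(f3$removed_peaks$frame, 100L)
  expect_equal(f3$valleys, 110L)

  # ties at exactly 30% drop are kept (>= as printed)
  x4 <- mk(1.0, 0.70)
  expect_equal(filter_extrema(x4, 100L, 200L)$valleys, 200L)
})

test_that("filtered valleys are a subset of the input valleys, in order", {
  set.seed(5)
  for (rep in 1:20) {
    x <- as.numeric(smooth_trace(abs(rnorm(300, 1, 0.5)), 5))
    ex <- detect_local_extrema(x)
    f <- filter_extrema(x, ex$peaks, ex$valleys)
    expect_true(all(f$valleys %in% ex$valleys))
    expect_false(is.unsorted(f$valleys))
  }
})

test_that("the adaptive baseline is the line through its anchors, extended flat", {
  x <- numeric(101)
  x[1] <- 0; x[101] <- 10
  ab <- build_adaptive_baseline(x, c(1L, 101L))
  expect_equal(ab$baseline[51], 5)
  expect_equal(ab$baseline[1], 0)
  # single anchor: constant
  ab1 <- build_adaptive_baseline(c(5, 1, 5, 9), 2L)
  expect_equal(ab1$baseline, rep(1, 4))
  # no anchors: constant at the minimum, logged
  expect_message(ab0 <- build_adaptive_baseline(c(3, 2, 4), integer(0)), "constant")
  expect_equal(ab0$baseline, rep(2, 3))
  # flat extension beyond terminal anchors
  ab2 <- build_adaptive_baseline(c(9, 1, 9, 3, 9), c(2L, 4L))
  expect_equal(ab2$baseline[1], 1)
  expect_equal(ab2$baseline[5], 3)
})

test_that("baseline slope tracks a linear drift under square waves", {
  set.seed(9)
  dt <- 0.5
  n <- 2000
  t <- (seq_len(n) - 1) * dt
  m <- 0.004 # drift per second
  x <- 1000 * (1 + m * t + pulse_trace(n, seq(100, 1800, by = 160), 40, 1)) +
    rnorm(n, 0, 10)
  det <- detrend_section(smooth_trace(x, 15), dt)
  anchors <- det$baseline$valley_frames
  expect_gt(length(anchors), 5)
  fit <- stats::lm(det$baseline$baseline[anchors] ~ t[anchors])
  # in section fold-change units the drift slope is m / (f_min/f0) ~ m
  expect_lt(abs(coef(fit)[2] - m) / m, 0.10)
})

test_that("adaptive fold change follows (F - BL)/BL and flags bad baselines", {
  expect_equal(as.numeric(fold_change_adaptive(rep(110, 5), rep(100, 5))),
               rep(0.1, 5))
  bl <- build_adaptive_baseline(c(5, 2, 5, 2, 5), c(2L, 4L))
  expect_equal(as.numeric(fold_change_adaptive(c(2, 2, 2, 2, 2), bl)),
               (c(2, 2, 2, 2, 2) - bl$baseline) / bl$baseline)
  expect_error(fold_change_adaptive(1:5, c(1, 1, 0, 1, 1)), "frame 3")
  expect_error(fold_change_adaptive(1:5, 1:4), "length")
})

test_that("detrending an already-detrended trace leaves a near-zero baseline", {
  set.seed(31)
  dt <- 0.5
  n <- 2400
  sigma <- 0.02
  x <- 1000 * (1 + 0.002 * (seq_len(n) - 1) * dt +
                 pulse_trace(n, seq(100, 2200, by = 160), 40, 1)) +
    rnorm(n, 0, sigma * 1000)
  det <- detrend_section(smooth_trace(x, 15), dt)
  sf <- det$sf_fold_change
  ex <- detect_local_extrema(sf, min_prominence = 0.1)
  f <- filter_extrema(sf, ex$peaks, ex$valleys)
  ab2 <- suppressMessages(build_adaptive_baseline(sf, f))
  expect_lt(max(abs(ab2$baseline)), 3 * sigma)
})

test_that("adaptive detrending recovers waves that a fixed baseline misses", {
  set.seed(17)
  dt <- 0.5
  n <- 2400
  starts <- seq(100, 2200, by = 160)
  x <- 1000 * (1 + 0.0006 * (seq_len(n) - 1) * dt +
                 pulse_trace(n, starts, 40, 1)) + rnorm(n, 0, 20)
  sm <- smooth_trace(x, 15)
  det <- detrend_section(sm, dt)
  n_adaptive <- nrow(detect_waves(det$sf_fold_change, frame_interval_s = dt))
  n_general <- nrow(detect_waves(as.numeric(fold_change_general(sm)),
                                 frame_interval_s = dt))
  expect_gte(n_adaptive, n_general)
  expect_equal(n_adaptive, length(starts))
})
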