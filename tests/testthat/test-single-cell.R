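test_that("the KCl filter excludes exactly the planted dead cells", {
  tl <- short_timeline()
  n <- tl$n_frames
  flat <- rep(100, n)
  responder <- flat; responder[kcl_window(tl)] <- 160 # 0.6 fold change
  m <- rbind(dead = flat, live = responder)
  k <- kcl_filter(m, tl)
  expect_equal(k$included, c(FALSE, TRUE))
  expect_equal(k$kcl_peak_fold_change[2], 0.6)

  sim <- simulate_islet(islet_preset("clean", n_cells = 20,
                                     n_first_responders = 2, n_leaders = 2,
                                     n_high_participation = 2,
                                     n_dead_cells = 3, noise_sd = 0,
                                     rng_seed = 4))
  cells_s <- t(apply(cell_traces(sim$traces), 1, smooth_trace, 15))
  k2 <- kcl_filter(cells_s, sim$timeline)
  expect_setequal(k2$cell_id[!k2$included], sim$truth$dead_cells)
})

test_that("an empty KCl window includes everyone with a warning", {
  tl <- experiment_timeline(0.5, 400, 50, 200, 400)
  m <- rbind(a = rep(100, 400), b = rep(100, 400))
  expect_warning(k <- kcl_filter(m, tl), "all cells included")
  expect_true(all(k$included))
})

test_that("T20 latency matches a linear-scan oracle on random traces", {
  expect_equal(activation_time_t20(c(rep(0, 480), rep(1, 20)),
                                   window = seq_len(500), frame_interval_s = 0.5),
               240)
  expect_true(is.na(activation_time_t20(rep(0.1, 100), frame_interval_s = 0.5)))
  # crossing is inclusive (>= 0.2)
  expect_equal(activation_time_t20(c(0, 0.2, 1), frame_interval_s = 0.5), 0.5)

  oracle <- function(v, win, thr, dt) {
    k <- 0L
    for (j in seq_along(win)) {
      if (v[win[j]] >= thr) { k <- j; break }
    }
    if (k == 0L) NA_real_ else (k - 1L) * dt
  }
  set.seed(99)
  for (rep in 1:100) {
    v <- runif(60)
    win <- sample(10:50, 1):60
    expect_identical(activation_time_t20(v, win, 0.2, 0.5),
                     oracle(v, win, 0.2, 0.5))
  }
})

test_that("first-responders are the ceiling(10%) fastest, ties by cell order", {
  tl <- short_timeline()
  n <- tl$n_frames
  # 20 cells with latencies 1..20 s after g11
  m <- t(vapply(1:20, function(i) {
    v <- rep(100, n)
    v[(tl$frame_g11 + 1L + i * 2L):n] <- 200 # crossing at i seconds (dt 0.5)
    v
  }, numeric(n)))
  rownames(m) <- sprintf("c%02d", 1:20)
  fr <- identify_first_responders(m, tl, frame_interval_s = 0.5)
  expect_equal(sum(fr$is_first_responder), 2) # ceiling(0.1 * 20)
  expect_equal(fr$cell_id[fr$is_first_responder], c("c01", "c02"))
  expect_equal(fr$fr_t20_s[1:3], c(1, 2, 3), tolerance = 0.51)

  # ties at the cutoff: equal latencies resolved by cell order (stable)
  m2 <- m
  m2[2, ] <- m[1, ]
  rownames(m2) <- rownames(m)
  fr2 <- identify_first_responders(m2, tl, frame_interval_s = 0.5)
  expect_equal(fr2$cell_id[fr2$is_first_responder], c("c01", "c02"))

  # never-crossing cells rank last and are never labeled
  m3 <- m
  m3[1, ] <- rep(100, n)
  fr3 <- identify_first_responders(m3, tl, frame_interval_s = 0.5)
  expect_true(is.na(fr3$fr_t20_s[1]))
  expect_false(fr3$is_first_responder[1])

  # fewer than 10 included cells warns but still labels
  expect_warning(fr4 <- identify_first_responders(m[1:5, ], tl,
                                                  frame_interval_s = 0.5),
                 "unstable")
  expect_equal(sum(fr4$is_first_responder), 1)
})

test_that("planted early cells are recovered as first-responders", {
  sim <- simulate_islet(islet_preset("clean", rng_seed = 21))
  cells_s <- t(apply(cell_traces(sim$traces), 1, smooth_trace, 15))
  fr <- identify_first_responders(cells_s, sim$timeline, frame_interval_s = 0.5)
  expect_setequal(fr$cell_id[fr$is_first_responder], sim$truth$first_responders)
})

test_that("per-wave windows are ordered, disjoint and contain their wave", {
  waves <- tibble::tibble(wave_id = 1:3,
                          activation_frame = c(100L, 300L, 500L),
                          deactivation_frame = c(140L, 340L, 540L))
  valleys <- c(60L, 200L, 420L, 600L)
  ww <- wave_windows(waves, valleys, 1L, 700L)
  expect_equal(ww$start_frame, c(60L, 200L, 420L))
  expect_equal(ww$end_frame, c(200L, 420L, 600L))

  # first wave at section start: window clipped to the section
  ww2 <- wave_windows(waves[1, ], integer(0), 1L, 700L)
  expect_equal(ww2$start_frame, 1L)
  expect_equal(ww2$end_frame, 700L)

  # two waves sharing flanking anchors: split at the midpoint, no overlap
  waves3 <- tibble::tibble(wave_id = 1:2,
                           activation_frame = c(100L, 160L),
                           deactivation_frame = c(120L, 180L))
  ww3 <- wave_windows(waves3, c(50L, 300L), 1L, 400L)
  expect_lte(ww3$end_frame[1], ww3$start_frame[2])
  expect_true(ww3$start_frame[1] <= 100 && 100 < ww3$end_frame[1])
  expect_true(ww3$start_frame[2] <= 160 && 160 < ww3$end_frame[2])
})

test_that("windows never overlap on simulated islets", {
  for (s in 1:5) {
    sim <- simulate_islet(islet_preset("clean", n_cells = 10,
                                       n_first_responders = 1, n_leaders = 1,
                                       n_high_participation = 1, rng_seed = s))
    tl <- sim$timeline
    sec <- section_window(tl)
    det <- detrend_section(smooth_trace(islet_trace(sim$traces), 15)[sec], 0.5)
    waves <- detect_waves(det$sf_fold_change, frame_interval_s = 0.5)
    ww <- wave_windows(waves, det$baseline$valley_frames, 1L, length(sec) + 1L)
    expect_false(is.unsorted(ww$start_frame))
    expect_true(all(ww$end_frame[-nrow(ww)] <= ww$start_frame[-1]))
    expect_true(all(ww$start_frame >= 1 & ww$end_frame <= length(sec) + 1L))
  }
})

test_that("leader latencies order cells by their consistent lead", {
  dt <- 0.5
  n <- 1200
  starts <- seq(100, 1100, by = 100)
  # cell A activates 2 s (4 frames) before cell B in every wave
  a <- pulse_trace(n, starts, 30, 1)
  b <- pulse_trace(n, starts + 4L, 30, 1)
  m <- rbind(A = a, B = b)
  waves <- detect_waves(pmax(a, b), frame_interval_s = dt)
  ww <- wave_windows(waves, integer(0), 1L, n + 1L)
  # force per-wave tiling from midpoints
  ld <- identify_leaders(m, ww, dt)
  dA <- ld$mean_scsp_t20_s[ld$cell_id == "A"]
  dB <- ld$mean_scsp_t20_s[ld$cell_id == "B"]
  expect_equal(dB - dA, 2, tolerance = 1e-9)
  expect_true(ld$is_leader[ld$cell_id == "A"])
})

test_that("the leader percentile is computed over per-cell means", {
  # 10 cells, means 1..10 s; inclusive linear 10th percentile = 1.9
  dt <- 1
  n <- 400
  starts <- c(50L, 150L, 250L)
  m <- t(vapply(1:10, function(i) pulse_trace(n, starts + i, 20, 1), numeric(n)))
  rownames(m) <- paste0("c", 1:10)
  ww <- tibble::tibble(wave_id = 1:3, start_frame = c(40L, 140L, 240L),
                       end_frame = c(140L, 240L, 340L))
  ld <- identify_leaders(m, ww, dt)
  expect_equal(sum(ld$is_leader), 1)
  expect_true(ld$is_leader[1])
  # boundary inclusivity: two cells tied at the fastest mean are both leaders
  m2 <- m
  m2[2, ] <- m[1, ]
  ld2 <- identify_leaders(m2, ww, dt)
  expect_equal(sum(ld2$is_leader), 2)
})

test_that("planted leaders are recovered and low-participation cells excluded", {
  sim <- simulate_islet(islet_preset("clean", rng_seed = 31))
  tl <- sim$timeline
  sec <- section_window(tl)
  det <- detrend_section(smooth_trace(islet_trace(sim$traces), 15)[sec], 0.5)
  waves <- detect_waves(det$sf_fold_change, frame_interval_s = 0.5)
  ww <- wave_windows(waves, det$baseline$valley_frames, 1L, length(sec) + 1L)
  cells_s <- t(apply(cell_traces(sim$traces), 1, smooth_trace, 15))
  sf <- t(apply(cells_s, 1, function(v) detrend_section(v[sec], 0.5)$sf_fold_change))
  rownames(sf) <- rownames(cells_s)
  ld <- identify_leaders(sf, ww, 0.5)
  found <- ld$cell_id[ld$is_leader]
  expect_gte(sum(sim$truth$leaders %in% found), 4) # >= 4/5 recovered

  # a cell active in under half the waves is ineligible
  sparse <- sf
  sparse[1, ] <- 0
  for (w in seq_len(min(3, nrow(ww)))) {
    sparse[1, ww$start_frame[w]:(ww$end_frame[w] - 1L)] <-
      sf[1, ww$start_frame[w]:(ww$end_frame[w] - 1L)]
  }
  ld2 <- identify_leaders(sparse, ww, 0.5)
  expect_false(ld2$leader_eligible[1])
  expect_false(ld2$is_leader[1])
})

test_that("zero waves yield no leader labels, with a warning", {
  m <- rbind(a = rep(0, 100), b = rep(0, 100))
  ww <- tibble::tibble(wave_id = integer(0), start_frame = integer(0),
                       end_frame = integer(0))
  expect_warning(ld <- identify_leaders(m, ww, 0.5), "no wave windows")
  expect_false(any(ld$is_leader))
})

test_that("subpopulation calls are invariant to per-cell affine gain and offset", {
  sim <- simulate_islet(islet_preset("clean", n_cells = 20,
                                     n_first_responders = 2, n_leaders = 2,
                                     n_high_participation = 2, rng_seed = 8))
  tl <- sim$timeline
  cells_s <- t(apply(cell_traces(sim$traces), 1, smooth_trace, 15))
  fr1 <- identify_first_responders(cells_s, tl, frame_interval_s = 0.5)
  set.seed(2)
  gains <- runif(nrow(cells_s), 0.5, 3)
  scaled <- cells_s * gains
  fr2 <- identify_first_responders(scaled, tl, frame_interval_s = 0.5)
  expect_equal(fr1$is_first_responder, fr2$is_first_responder)
  expect_equal(fr1$fr_t20_s, fr2$fr_t20_s, tolerance = 1e-12)
})
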