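# Small programmatic fixtures shared across the suite.

# A fold-change trace of `n` frames with square pulses of `amplitude`
# starting at `starts` (frames), each `width` frames long.
pulse_trace <- function(n, starts, width, amplitude = 0.5) {
  x <- numeric(n)
  for (s in starts) x[s:min(n, s + width - 1L)] <- amplitude
  x
}

# Binary activity vector with bursts at given start frames.
burst_vector <- function(n, starts, width) {
  x <- integer(n)
  for (s in starts) x[s:min(n, s + width - 1L)] <- 1L
  x
}

# Two-state Markov on/off chain (stationary bursty activity).
markov_activity <- function(n, p_on = 0.02, p_off = 0.1) {
  x <- integer(n)
  state <- 0L
  for (i in seq_len(n)) {
    state <- if (state == 0L) as.integer(runif(1) < p_on) else as.integer(runif(1) >= p_off)
    x[i] <- state
  }
  x
}

# Write a Multi-Measure style CSV from a frames x ROIs data.frame.
write_mm_fixture <- function(df, index_col = FALSE) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  if (index_col) df <- cbind(data.frame(` ` = seq_len(nrow(df)), check.names = FALSE), df)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# A short timeline for fast synthetic-free tests: 400 frames at 0.5 s,
# stimuli at 50 / 200 / 350.
short_timeline <- function() {
  experiment_timeline(frame_interval_s = 0.5, n_frames = 400,
                      frame_g11 = 50, frame_g25 = 200, frame_kcl = 350)
}
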