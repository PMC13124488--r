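#' Detect calcium waves with a double threshold
#'
#' Event detection on an adaptive-baseline fold-change trace. An event opens
#' at the first frame strictly above `threshold` (the activation point,
#' SP-T20 of that wave) and closes at the first subsequent frame strictly
#' below it (the deactivation point); values exactly at the threshold do not
#' toggle the state. Events sustained for less than `min_duration_s` are
#' discarded. An event still open at the end of the trace closes at the last
#' frame and is flagged `truncated`.
#'
#' @param sf_fold_change Adaptive-baseline fold-change trace.
#' @param threshold Activation threshold in fold-change units (default 0.2,
#'   i.e. 20% above the local baseline).
#' @param min_duration_s Minimum sustained activity in seconds (default 2).
#' @param frame_interval_s Seconds per frame.
#' @return A tibble with one row per wave: `wave_id`, `activation_frame`,
#'   `deactivation_frame`, `activation_s` (time of activation from trace
#'   start), `width_s` (active duration), `peak_amplitude` (max fold change
#'   during the event) and `truncated`.
#' @export
#' @examples
#' sf <- rep(0, 100); sf[21:40] <- 0.5
#' detect_waves(sf, frame_interval_s = 0.5)
detect_waves <- function(sf_fold_change, threshold = 0.2, min_duration_s = 2,
                         frame_interval_s = 0.5) {
  x <- as.numeric(sf_fold_change)
  n <- length(x)
  act <- deact <- integer(0)
  width <- peak <- numeric(0)
  trunc <- logical(0)
  cur <- 1L
  while (cur <= n) {
    rel <- which(x[cur:n] > threshold)
    if (!length(rel)) break
    a <- cur + rel[1] - 1L
    rel2 <- if (a < n) which(x[(a + 1L):n] < threshold) else integer(0)
    if (length(rel2)) {
      d <- a + rel2[1]
      tr <- FALSE
      active_n <- d - a # active frames are a..(d-1)
    } else {
      d <- n
      tr <- TRUE
      active_n <- n - a + 1L
    }
    act <- c(act, a)
    deact <- c(deact, d)
    trunc <- c(trunc, tr)
    width <- c(width, active_n * frame_interval_s)
    peak <- c(peak, max(x[a:(a + active_n - 1L)]))
    if (tr) break
    cur <- d + 1L
  }
  out <- tibble(
    wave_id = seq_along(act),
    activation_frame = act,
    deactivation_frame = deact,
    activation_s = (act - 1L) * frame_interval_s,
    width_s = width,
    peak_amplitude = peak,
    truncated = trunc
  )
  out <- out[out$width_s >= min_duration_s, , drop = FALSE]
  out$wave_id <- seq_len(nrow(out))
  out
}

#' Apparent area under the curve
#'
#' The "apparent AUC": the plain sum of fold-change values over a window.
#' The fold-change trace should have minimum 0 over its defining window
#' (as produced by [fold_change_general()]).
#'
#' @param fold_change Fold-change trace.
#' @param window Frame indices to sum over (default: whole trace).
#' @return A single number (unitless fold-change sum).
#' @export
auc_app <- function(fold_change, window = seq_along(fold_change)) {
  sum(as.numeric(fold_change)[window])
}

#' Trapezoid-rule area under the curve
#'
#' Standard trapezoid rule over a contiguous frame window:
#' `sum over consecutive frames of (F_i + F_{i+1}) / 2 * dt`, in units of
#' fold change x seconds.
#'
#' @param fold_change Fold-change trace.
#' @param window Contiguous frame indices (default: whole trace).
#' @param frame_interval_s Seconds per frame.
#' @return A single number (fold change x seconds).
#' @export
#' @examples
#' auc_trapezoid(c(0, 1, 0), frame_interval_s = 1) # triangle pulse, area 1
auc_trapezoid <- function(fold_change, window = seq_along(fold_change),
                          frame_interval_s = 0.5) {
  x <- as.numeric(fold_change)[window]
  if (length(x) < 2) return(0)
  sum((x[-1] + x[-length(x)]) / 2) * frame_interval_s
}

#' First-phase amplitude, activation time and width
#'
#' Islet-level metrics of the initial glucose response, computed on the
#' general-baseline fold-change trace over the first-phase window
#' `(frame_g11, first_phase_end_frame]`:
#'
#' * `fp_amplitude` — the maximum fold change in the window (the height of
#'   the first, usually largest, peak);
#' * `fp_t20_s` — time from the 11 mM glucose addition to the first frame
#'   strictly above `threshold` (FP-T20, the activation time);
#' * `fp_width_s` — time from that activation until the trace first falls
#'   strictly back below `threshold` (the operational first-phase end).
#'
#' If the trace never crosses the threshold inside the window, the islet is
#' reported as not activated: `fp_t20_s` and `fp_width_s` are `NA` while the
#' amplitude is still computed.
#'
#' @param fold_change General-baseline fold-change trace over the full
#'   recording.
#' @param timeline An [experiment_timeline()].
#' @param threshold Activation threshold (default 0.2).
#' @return A one-row tibble: `fp_t20_s`, `fp_amplitude`, `fp_width_s`,
#'   `fp_activated`.
#' @export
first_phase_metrics <- function(fold_change, timeline, threshold = 0.2) {
  stopifnot(inherits(timeline, "experiment_timeline"))
  win <- first_phase_window(timeline)
  x <- as.numeric(fold_change)[win]
  dt <- timeline$frame_interval_s
  amp <- max(x)
  cross <- which(x > threshold)[1]
  if (is.na(cross)) {
    return(tibble(fp_t20_s = NA_real_, fp_amplitude = amp,
                  fp_width_s = NA_real_, fp_activated = FALSE))
  }
  t20 <- (cross - 1L) * dt
  fall <- if (cross < length(x)) which(x[(cross + 1L):length(x)] < threshold)[1] else NA_integer_
  width <- if (is.na(fall)) (length(x) - cross + 1L) * dt else fall * dt
  tibble(fp_t20_s = t20, fp_amplitude = amp, fp_width_s = width,
         fp_activated = TRUE)
}

#' Second-phase frequency, mean amplitude and mean width
#'
#' Summarizes the steady-state oscillations from detected waves restricted
#' to an analysis window: the frequency is the number of waves divided by
#' the window length in minutes (15 waves over a 1,200 s window give 0.75
#' waves/min); amplitude and width are the means of the per-event peak
#' amplitudes and active durations. With zero waves the frequency is 0 and
#' the means are reported absent (`NA`).
#'
#' @param waves Tibble from [detect_waves()], frames on the same axis as
#'   `window`.
#' @param window Frame indices of the analysis window (must be non-empty).
#' @param frame_interval_s Seconds per frame.
#' @return A one-row tibble: `sp_frequency_per_min`, `sp_mean_amplitude`,
#'   `sp_mean_width_s`, `n_waves`.
#' @export
second_phase_metrics <- function(waves, window, frame_interval_s = 0.5) {
  if (!length(window)) abort("second-phase window is empty")
  minutes <- length(window) * frame_interval_s / 60
  w <- waves[waves$activation_frame >= min(window) &
               waves$activation_frame <= max(window), , drop = FALSE]
  n <- nrow(w)
  tibble(
    sp_frequency_per_min = n / minutes,
    sp_mean_amplitude = if (n) mean(w$peak_amplitude) else NA_real_,
    sp_mean_width_s = if (n) mean(w$width_s) else NA_real_,
    n_waves = n
  )
}
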