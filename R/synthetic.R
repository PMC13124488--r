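#' Simulation parameters for a synthetic islet recording
#'
#' Bundles every knob of the synthetic generator. The defaults emulate the
#' standard glucose-ramp protocol (0.5 s/frame, 42 min, 11 mM at 3 min,
#' 25 mM at 18 min, KCl at 40 min) with a biphasic response: a per-cell
#' smoothed step during the first phase (onset ~4 min after the 11 mM
#' addition), a square-wave train of steady-state oscillations during the
#' 25 mM phase in which participating cells activate at the wave time plus
#' a per-cell lag, and a terminal KCl depolarization. Planted ground-truth
#' subpopulations: first-responders (first-phase onset earlier by
#' `fr_lead_s`), leaders (zero second-phase lag, full participation),
#' high-participation hub-like cells (participation probability 1.0) and
#' dead cells (flat everywhere, including the KCl window). The signal model
#' is additive (drift + phase signals, Gaussian noise), not biophysical:
#' the pipeline consumes fluorescence statistics, and a closed-form model
#' gives every stage an exact oracle.
#'
#' @param n_cells Number of cells.
#' @param timeline An [experiment_timeline()].
#' @param baseline_f0 Raw baseline intensity (arbitrary units).
#' @param noise_sd Gaussian noise SD as a fraction of `baseline_f0`.
#' @param drift_per_min Linear drift slope, fraction of `baseline_f0` per
#'   minute.
#' @param drift_sin_amplitude,drift_sin_period_s Slow sinusoidal drift
#'   component (fraction of `baseline_f0`; seconds).
#' @param fp_onset_mean_s,fp_onset_sd_s Per-cell first-phase onset (seconds
#'   after the 11 mM addition), normal across cells.
#' @param fp_duration_s,fp_amplitude,fp_ramp_s First-phase plateau length,
#'   height (fold-change units over `f0`) and linear ramp time.
#' @param n_first_responders,fr_lead_s Planted fast cells and their onset
#'   lead.
#' @param sp_start_offset_s Delay of the first wave after the 25 mM
#'   addition.
#' @param sp_period_s,sp_width_s,sp_amplitude Second-phase wave train:
#'   period, active width and height (fold-change units).
#' @param sp_participation Per-wave participation probability of ordinary
#'   cells (hub-like and leader cells use 1.0).
#' @param n_leaders,leader_lead_s Planted leader cells; ordinary cells lag
#'   each wave by `leader_lead_s` plus a per-cell uniform spread.
#' @param lag_spread_s Width of the per-cell uniform lag component.
#' @param lag_jitter_sd_s Per-cell, per-wave Gaussian lag jitter.
#' @param n_high_participation Planted hub-like cells.
#' @param n_dead_cells Planted dead cells (no response to anything).
#' @param kcl_amplitude,kcl_delay_s KCl depolarization response height and
#'   onset delay.
#' @param include_islet_roi Prepend a whole-islet ROI (sum of cell traces)?
#' @param rng_seed Integer seed; [simulate_islet()] is deterministic given
#'   the seed.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_cells = 50,
                              timeline = experiment_timeline(),
                              baseline_f0 = 1000,
                              noise_sd = 0.02,
                              drift_per_min = 0,
                              drift_sin_amplitude = 0,
                              drift_sin_period_s = 400,
                              fp_onset_mean_s = 240,
                              fp_onset_sd_s = 20,
                              fp_duration_s = 360,
                              fp_amplitude = 3,
                              fp_ramp_s = 5,
                              n_first_responders = 5,
                              fr_lead_s = 90,
                              sp_start_offset_s = 30,
                              sp_period_s = 24,
                              sp_width_s = 12,
                              sp_amplitude = 1,
                              sp_participation = 0.75,
                              n_leaders = 5,
                              leader_lead_s = 1.5,
                              lag_spread_s = 1,
                              lag_jitter_sd_s = 0.25,
                              n_high_participation = 5,
                              n_dead_cells = 0,
                              kcl_amplitude = 4,
                              kcl_delay_s = 5,
                              include_islet_roi = TRUE,
                              rng_seed = 1L) {
  stopifnot(inherits(timeline, "experiment_timeline"))
  p <- as.list(environment())
  if (n_cells < 1) abort("n_cells must be >= 1")
  if (sp_participation < 0 || sp_participation > 1) {
    abort("sp_participation must be a probability in [0, 1]")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  n_planted <- n_first_responders + n_leaders + n_high_participation + n_dead_cells
  if (n_planted > n_cells) {
    abort(sprintf(
      "planted subpopulations (%d cells) exceed n_cells (%d); planted sets must be disjoint",
      n_planted, n_cells
    ))
  }
  # planted signals must clear the 0.2 detection threshold with margin
  if (sp_amplitude <= 0.3) abort("sp_amplitude must exceed 0.3 (detection threshold 0.2 plus margin)")
  if (fp_amplitude <= 0.3) abort("fp_amplitude must exceed 0.3")
  if (n_dead_cells < n_cells && kcl_amplitude <= 0.3) {
    abort("kcl_amplitude must exceed 0.3 so live cells pass the KCl filter")
  }
  if (sp_width_s >= sp_period_s) abort("sp_width_s must be shorter than sp_period_s")
  structure(p, class = "simulation_params")
}

#' Named simulation presets
#'
#' Documented parameter bundles for common study conditions:
#'
#' * `"clean"` — 50 cells, noise SD 2% of baseline, no drift; 5 planted
#'   first-responders (90 s onset lead over a 20 s onset SD), 5 leaders
#'   (1.5 s wave lead), 5 hub-like full-participation cells, ordinary cells
#'   participating in 75% of waves. Fast steady-state oscillations (24 s
#'   period, 12 s width).
#' * `"noisy"` — as `"clean"` with noise SD 8%.
#' * `"drifting"` — 30 exchangeable, fully participating cells with slower
#'   waves (80 s period, 20 s width) on a strong upward linear drift
#'   (7.5% of baseline per minute, plus a slow sinusoid). The drift is
#'   strong enough that fixed-baseline wave detection merges the later
#'   waves while adaptive-baseline detection recovers the full train.
#' * `"no_heterogeneity"` — 50 exchangeable cells (no planted sets; every
#'   cell draws its onset, lag and participation from the same
#'   distributions), for label-bias tests.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [simulation_params()] (e.g.
#'   `rng_seed`).
#' @return A [simulation_params()] object.
#' @export
islet_preset <- function(name = c("clean", "noisy", "drifting", "no_heterogeneity"),
                         ...) {
  name <- match.arg(name)
  base <- switch(name,
    clean = list(),
    noisy = list(noise_sd = 0.08),
    drifting = list(
      n_cells = 30, sp_period_s = 80, sp_width_s = 20, sp_participation = 1,
      n_first_responders = 0, n_leaders = 0, n_high_participation = 0,
      drift_per_min = 0.075, drift_sin_amplitude = 0.03, drift_sin_period_s = 400
    ),
    no_heterogeneity = list(
      n_first_responders = 0, n_leaders = 0, n_high_participation = 0
    )
  )
  do.call(simulation_params, modifyList(base, list(...)))
}

# linear-ramp pulse: 0 outside [t0, t1], amp on the plateau, linear ramps
# of `ramp` seconds at both ends
pulse_profile <- function(t, t0, t1, amp, ramp) {
  amp * pmin(1, pmax(0, (t - t0) / ramp), pmax(0, (t1 - t) / ramp))
}

#' Simulate a synthetic islet recording with planted ground truth
#'
#' Generates per-cell raw fluorescence traces
#' `f0 * (1 + drift(t) + signal_i(t)) + noise`, cell centroids uniform in a
#' disc, the experiment timeline, and the planted ground truth (which cells
#' are first-responders, leaders, hub-like or dead, plus every per-cell,
#' per-wave activation frame). Deterministic for a given `rng_seed`.
#'
#' @param params A [simulation_params()] or [islet_preset()] object.
#' @return An object of class `islet_simulation`: list with `traces`
#'   (a [trace_matrix()]), `centroids`, `timeline` and `truth` (list:
#'   `first_responders`, `leaders`, `high_participation`, `dead_cells`,
#'   `wave_start_frames`, `n_waves`, `activation` tibble, `onset_s`).
#' @export
#' @examples
#' sim <- simulate_islet(islet_preset("clean", n_cells = 10, rng_seed = 7))
#' sim$traces
simulate_islet <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  tl <- p$timeline
  dt <- tl$frame_interval_s
  n <- tl$n_frames
  t <- (seq_len(n) - 1) * dt
  t_g11 <- tl$frame_g11 * dt
  t_g25 <- tl$frame_g25 * dt
  t_kcl <- tl$frame_kcl * dt

  withr::with_seed(p$rng_seed, {
    ids <- sprintf("cell_%03d", seq_len(p$n_cells))
    perm <- sample.int(p$n_cells)
    fr <- if (p$n_first_responders) perm[seq_len(p$n_first_responders)] else integer(0)
    used <- length(fr)
    lead <- if (p$n_leaders) perm[used + seq_len(p$n_leaders)] else integer(0)
    used <- used + length(lead)
    high <- if (p$n_high_participation) perm[used + seq_len(p$n_high_participation)] else integer(0)
    used <- used + length(high)
    dead <- if (p$n_dead_cells) perm[used + seq_len(p$n_dead_cells)] else integer(0)

    onset <- rnorm(p$n_cells, p$fp_onset_mean_s, p$fp_onset_sd_s)
    onset[fr] <- rnorm(length(fr), p$fp_onset_mean_s - p$fr_lead_s, p$fp_onset_sd_s)
    onset <- pmax(onset, 5)

    lag <- p$leader_lead_s + runif(p$n_cells, 0, p$lag_spread_s)
    lag[lead] <- 0
    particip <- rep(p$sp_participation, p$n_cells)
    particip[c(lead, high)] <- 1
    particip[dead] <- 0

    # wave train: fully inside the 25 mM section, clear of the KCl window
    max_lag <- max(lag) + 4 * p$lag_jitter_sd_s
    wave_start <- seq(t_g25 + p$sp_start_offset_s, by = p$sp_period_s,
                      length.out = 10000)
    wave_start <- wave_start[wave_start + p$sp_width_s + max_lag + p$fp_ramp_s <
                               t_kcl - 5]
    n_waves <- length(wave_start)

    active <- matrix(runif(p$n_cells * n_waves) < rep(particip, n_waves),
                     nrow = p$n_cells)
    act_time <- matrix(NA_real_, p$n_cells, n_waves)

    drift <- (p$drift_per_min / 60) * t +
      p$drift_sin_amplitude * sin(2 * pi * t / p$drift_sin_period_s)

    mat <- matrix(0, nrow = p$n_cells, ncol = n)
    for (i in seq_len(p$n_cells)) {
      s <- numeric(n)
      if (!(i %in% dead)) {
        t_on <- t_g11 + onset[i]
        s <- s + pulse_profile(t, t_on, t_on + p$fp_duration_s,
                               p$fp_amplitude, p$fp_ramp_s)
        for (k in seq_len(n_waves)) {
          if (!active[i, k]) next
          a <- wave_start[k] + lag[i] + abs(rnorm(1, 0, p$lag_jitter_sd_s))
          act_time[i, k] <- a
          s <- s + pulse_profile(t, a, a + p$sp_width_s, p$sp_amplitude, 1)
        }
        s <- s + pulse_profile(t, t_kcl + p$kcl_delay_s, max(t) + 10,
                               p$kcl_amplitude, 5)
      }
      mat[i, ] <- p$baseline_f0 * (1 + drift + s) +
        rnorm(n, 0, p$noise_sd * p$baseline_f0)
    }
    mat <- pmax(mat, 0.01 * p$baseline_f0) # intensities stay positive

    if (p$include_islet_roi) {
      mat <- rbind(islet = colSums(mat), mat)
      rownames(mat) <- c("islet", ids)
    } else {
      rownames(mat) <- ids
    }

    r <- 60 * sqrt(runif(p$n_cells))
    th <- runif(p$n_cells, 0, 2 * pi)
    centroids <- tibble(cell_id = ids,
                        x_px = 128 + r * cos(th),
                        y_px = 128 + r * sin(th))

    act_idx <- which(!is.na(act_time), arr.ind = TRUE)
    activation <- tibble(
      cell_id = ids[act_idx[, 1]],
      wave = as.integer(act_idx[, 2]),
      activation_frame = as.integer(round(act_time[act_idx] / dt)) + 1L
    )

    structure(
      list(
        traces = trace_matrix(mat, frame_interval_s = dt,
                              includes_islet_roi = p$include_islet_roi),
        centroids = centroids,
        timeline = tl,
        truth = list(
          first_responders = ids[sort(fr)],
          leaders = ids[sort(lead)],
          high_participation = ids[sort(high)],
          dead_cells = ids[sort(dead)],
          wave_start_frames = as.integer(round(wave_start / dt)) + 1L,
          n_waves = n_waves,
          activation = activation,
          onset_s = stats::setNames(onset, ids)
        ),
        params = p
      ),
      class = "islet_simulation"
    )
  })
}

#' @export
print.islet_simulation <- function(x, ...) {
  cat(sprintf("<islet_simulation> %d cells, %d frames, %d planted waves (seed %d)\n",
              nrow(cell_traces(x$traces)), n_frames(x$traces),
              x$truth$n_waves, x$params$rng_seed))
  cat(sprintf("  planted: %d first-responders, %d leaders, %d high-participation, %d dead\n",
              length(x$truth$first_responders), length(x$truth$leaders),
              length(x$truth$high_participation), length(x$truth$dead_cells)))
  invisible(x)
}

#' Write a simulated recording in the on-disk input formats
#'
#' Exports the three artifacts an imaging experiment would provide: the
#' Multi-Measure trace CSV, the centroid CSV and the timeline JSON, so a
#' simulation can exercise the full file-based pipeline (and the CLI).
#'
#' @param sim An [simulate_islet()] result.
#' @param dir Output directory.
#' @return Invisibly, the named paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "islet_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    traces = file.path(dir, "traces.csv"),
    centroids = file.path(dir, "centroids.csv"),
    timeline = file.path(dir, "timeline.json")
  )
  write_multimeasure_csv(sim$traces, paths[["traces"]])
  write_centroids_csv(sim$centroids, paths[["centroids"]])
  write_timeline_config(sim$timeline, paths[["timeline"]])
  invisible(paths)
}
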