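#' KCl-responsiveness filter
#'
#' Excludes cells that show no calcium increase after the terminal forced
#' depolarization with KCl: such cells (weak signal, dead, or out of focus)
#' cannot be quantified reliably and would create false positives. A cell is
#' included iff its general-baseline fold change exceeds `threshold` at any
#' frame of the KCl window. If the timeline has no frames after the KCl
#' addition every cell is included with a warning.
#'
#' @param traces A [trace_matrix()] of cell ROIs, or a cells x frames
#'   numeric matrix (smoothed raw fluorescence).
#' @param timeline An [experiment_timeline()].
#' @param threshold Fold-change threshold (default 0.2).
#' @return A tibble: `cell_id`, `included`, `kcl_peak_fold_change`.
#' @export
kcl_filter <- function(traces, timeline, threshold = 0.2) {
  stopifnot(inherits(timeline, "experiment_timeline"))
  m <- if (inherits(traces, "trace_matrix")) cell_traces(traces) else traces
  ids <- rownames(m) %||% paste0("cell_", seq_len(nrow(m)))
  kwin <- kcl_window(timeline)
  bwin <- baseline_window(timeline)
  if (!length(kwin)) {
    warn("timeline has no frames after the KCl addition: all cells included")
    return(tibble(cell_id = ids, included = TRUE,
                  kcl_peak_fold_change = NA_real_))
  }
  f_min <- apply(m[, bwin, drop = FALSE], 1, min)
  if (any(f_min <= 0)) {
    abort(sprintf("cell '%s' has a non-positive 3 mM baseline minimum; fold change is undefined",
                  ids[which(f_min <= 0)[1]]))
  }
  peak <- apply(m[, kwin, drop = FALSE], 1, max)
  kcl_fc <- unname((peak - f_min) / f_min)
  tibble(cell_id = ids, included = kcl_fc > threshold,
         kcl_peak_fold_change = kcl_fc)
}

#' Activation time (T20) of a normalized trace
#'
#' Time from the window start to the first frame at which a normalized trace
#' reaches at least `threshold` (by convention 0.20, a 20% rise). Returns
#' `NA` if the trace never crosses inside the window.
#'
#' @param normalized_values Trace normalized over the relevant analysis
#'   window (see [minmax_normalize()]).
#' @param window Frame indices of the analysis window.
#' @param threshold Crossing threshold (default 0.2); the crossing is
#'   inclusive (`>=`).
#' @param frame_interval_s Seconds per frame.
#' @return Latency in seconds, or `NA_real_`.
#' @export
activation_time_t20 <- function(normalized_values,
                                window = seq_along(normalized_values),
                                threshold = 0.2, frame_interval_s = 0.5) {
  rel <- which(as.numeric(normalized_values)[window] >= threshold)[1]
  if (is.na(rel)) NA_real_ else (rel - 1L) * frame_interval_s
}

#' Identify first-responder cells
#'
#' First-responders are the fraction (by default 10%) of KCl-responsive
#' beta-cells with the fastest activation during the first phase. Each
#' cell's trace is min-max normalized with `F_min` taken over the 3 mM
#' baseline window (the minimum before the initial glucose response) and
#' `F_max` over frames up to the first-phase end; the per-cell FR-T20 is the
#' time from the 11 mM addition to the first frame at or above `threshold`
#' of that normalized trace. Cells are ranked by latency ascending;
#' `ceiling(fraction * n_included)` fastest cells are labeled. Ties at the
#' cutoff are broken by earlier crossing frame and then by cell order
#' (i.e. the ranking is stable); cells that never cross rank last and are
#' never labeled. Cells whose trace is constant over the normalization
#' window are reported with `NA` latency.
#'
#' @param traces A [trace_matrix()] of cell ROIs or a cells x frames matrix
#'   of smoothed raw fluorescence.
#' @param timeline An [experiment_timeline()].
#' @param fraction Fraction of included cells to label (default 0.10).
#' @param threshold T20 threshold on the normalized trace (default 0.2).
#' @param included Optional logical vector (or tibble from [kcl_filter()])
#'   marking analyzable cells; defaults to all.
#' @param frame_interval_s Seconds per frame (taken from `traces` when it is
#'   a `trace_matrix`).
#' @return A tibble: `cell_id`, `included`, `fr_t20_s`,
#'   `is_first_responder`.
#' @export
identify_first_responders <- function(traces, timeline, fraction = 0.10,
                                      threshold = 0.2, included = NULL,
                                      frame_interval_s = NULL) {
  stopifnot(inherits(timeline, "experiment_timeline"))
  if (inherits(traces, "trace_matrix")) {
    frame_interval_s <- traces$frame_interval_s
    m <- cell_traces(traces)
  } else {
    m <- traces
    frame_interval_s <- frame_interval_s %||% timeline$frame_interval_s
  }
  ids <- rownames(m) %||% paste0("cell_", seq_len(nrow(m)))
  if (is.data.frame(included)) included <- included$included
  included <- included %||% rep(TRUE, nrow(m))
  bwin <- baseline_window(timeline)
  fpw <- first_phase_window(timeline)
  norm_win <- seq_len(timeline$first_phase_end_frame)

  lat <- rep(NA_real_, nrow(m))
  for (i in which(included)) {
    v <- m[i, ]
    f_min <- min(v[bwin])
    f_max <- max(v[norm_win])
    if (!(f_max > f_min)) next # constant over window: unanalyzable, NA latency
    nv <- (v - f_min) / (f_max - f_min)
    lat[i] <- activation_time_t20(nv, fpw, threshold, frame_interval_s)
  }

  n_inc <- sum(included)
  if (n_inc < 10) {
    warn(sprintf("only %d included cells: first-responder fraction is unstable", n_inc))
  }
  k <- max(1L, ceiling(fraction * n_inc))
  is_fr <- rep(FALSE, nrow(m))
  cand <- which(included & !is.na(lat))
  if (length(cand)) {
    ord <- cand[order(lat[cand], cand)] # stable: latency, then cell order
    is_fr[head(ord, k)] <- TRUE
  }
  tibble(cell_id = ids, included = included, fr_t20_s = lat,
         is_first_responder = is_fr)
}

#' Per-wave analysis windows
#'
#' Builds one frame window per detected islet wave so that each wave can be
#' independently normalized for single-cell latency measurement. Window i
#' runs from the last adaptive-baseline valley anchor at or before the
#' wave's activation to the first anchor at or after its deactivation,
#' clipped to the section bounds. When two consecutive windows would overlap
#' (two waves sharing the same flanking anchors), the boundary is placed at
#' the midpoint frame between the first wave's deactivation and the second
#' wave's activation, so windows are always non-overlapping, ordered and
#' tile at most the section.
#'
#' @param waves Tibble from [detect_waves()] (frames on the section axis).
#' @param valleys Integer valley anchor frames (e.g.
#'   `detrend_section(x)$baseline$valley_frames`).
#' @param section_start,section_end Half-open section bounds
#'   `[section_start, section_end)` on the same frame axis; defaults to
#'   frame 1 and one past the last anchor/wave frame.
#' @return A tibble: `wave_id`, `start_frame`, `end_frame` (half-open).
#' @export
wave_windows <- function(waves, valleys, section_start = 1L,
                         section_end = NULL) {
  k <- nrow(waves)
  if (k == 0L) {
    return(tibble(wave_id = integer(0), start_frame = integer(0),
                  end_frame = integer(0)))
  }
  valleys <- sort(as.integer(valleys))
  section_end <- as.integer(section_end %||%
                              (max(waves$deactivation_frame, valleys, 0L) + 1L))
  act <- waves$activation_frame
  deact <- waves$deactivation_frame
  start <- end <- integer(k)
  for (i in seq_len(k)) {
    prev <- valleys[valleys <= act[i]]
    start[i] <- if (length(prev)) max(prev) else section_start
    nxt <- valleys[valleys >= deact[i]]
    end[i] <- if (length(nxt)) min(nxt) else section_end
  }
  start <- pmax(start, section_start)
  end <- pmin(end, section_end)
  if (k > 1) {
    for (i in seq_len(k - 1L)) {
      if (end[i] > start[i + 1L]) {
        mid <- as.integer(floor((deact[i] + act[i + 1L]) / 2))
        end[i] <- mid
        start[i + 1L] <- mid
      }
    }
  }
  tibble(wave_id = waves$wave_id, start_frame = start, end_frame = end)
}

#' Identify leader cells
#'
#' Leader cells initiate the second-phase calcium waves: they are the cells
#' whose mean per-wave activation latency is at or below the
#' `percentile`-th percentile across analyzable cells. For each wave window
#' the cell's adaptive-baseline fold-change trace is min-max rescaled within
#' the window and its SCSP-T20 (time from window start to the first frame at
#' or above 0.2 of the rescaled range) is recorded. A cell participates in a
#' wave only if its un-rescaled fold change exceeds `activation_threshold`
#' inside the window (otherwise rescaled noise would fabricate latencies);
#' cells active in fewer than `min_participation` of the islet waves are
#' excluded from leader eligibility. The percentile is computed over the
#' eligible cells' means with the inclusive (linear interpolation)
#' definition, and the boundary is inclusive.
#'
#' @param sf_matrix Cells x frames matrix of per-cell adaptive-baseline
#'   fold-change traces over the section.
#' @param windows Tibble from [wave_windows()].
#' @param frame_interval_s Seconds per frame.
#' @param percentile Percentile cutoff (default 10).
#' @param activation_threshold Fold-change participation threshold
#'   (default 0.2).
#' @param t20_threshold Threshold on the rescaled trace (default 0.2).
#' @param included Optional logical vector (or [kcl_filter()] tibble).
#' @param min_participation Minimum fraction of waves a cell must be active
#'   in to be leader-eligible (default 0.5).
#' @return A tibble: `cell_id`, `mean_scsp_t20_s`, `n_waves_active`,
#'   `leader_eligible`, `is_leader`.
#' @export
identify_leaders <- function(sf_matrix, windows, frame_interval_s = 0.5,
                             percentile = 10, activation_threshold = 0.2,
                             t20_threshold = 0.2, included = NULL,
                             min_participation = 0.5) {
  m <- sf_matrix
  ids <- rownames(m) %||% paste0("cell_", seq_len(nrow(m)))
  if (is.data.frame(included)) included <- included$included
  included <- included %||% rep(TRUE, nrow(m))
  k <- nrow(windows)
  if (k == 0L) {
    warn("no wave windows: no leader labels assigned")
    return(tibble(cell_id = ids, mean_scsp_t20_s = NA_real_,
                  n_waves_active = 0L, leader_eligible = FALSE,
                  is_leader = FALSE))
  }
  lat <- matrix(NA_real_, nrow = nrow(m), ncol = k)
  for (w in seq_len(k)) {
    seg <- m[, windows$start_frame[w]:(windows$end_frame[w] - 1L), drop = FALSE]
    mx <- apply(seg, 1, max)
    mn <- apply(seg, 1, min)
    part <- mx > activation_threshold & mx > mn
    for (i in which(part)) {
      resc <- (seg[i, ] - mn[i]) / (mx[i] - mn[i])
      cross <- which(resc >= t20_threshold)[1]
      if (!is.na(cross)) lat[i, w] <- (cross - 1L) * frame_interval_s
    }
  }
  n_active <- rowSums(!is.na(lat))
  means <- ifelse(n_active > 0, rowMeans(lat, na.rm = TRUE), NA_real_)
  eligible <- included & n_active >= min_participation * k & n_active > 0
  is_leader <- rep(FALSE, nrow(m))
  if (any(eligible)) {
    cutoff <- quantile(means[eligible], percentile / 100, type = 7, names = FALSE)
    is_leader <- eligible & !is.na(means) & means <= cutoff
  } else {
    warn("no leader-eligible cells (insufficient wave participation)")
  }
  tibble(cell_id = ids, mean_scsp_t20_s = means,
         n_waves_active = as.integer(n_active),
         leader_eligible = eligible, is_leader = is_leader)
}
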