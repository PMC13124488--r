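#' Moving-average smoothing of a fluorescence trace
#'
#' Centered moving average with shrinking windows at the edges (each output
#' frame averages whatever part of the window lies inside the trace), so the
#' output has the same length as the input. The conventional filter size for
#' 2 Hz islet recordings is 3-15 frames; a warning is issued outside that
#' range. Even window sizes are reduced by one so the window stays centered.
#'
#' @param values Numeric trace.
#' @param window_frames Filter size in frames (default 15).
#' @return Smoothed numeric trace, same length as `values`.
#' @export
#' @examples
#' smooth_trace(c(0, 3, 0, 3, 0), window_frames = 3)
smooth_trace <- function(values, window_frames = 15) {
  if (!is.numeric(values)) abort("values must be numeric")
  n <- length(values)
  if (!is.numeric(window_frames) || length(window_frames) != 1 || window_frames < 1) {
    abort("window_frames must be a single value >= 1")
  }
  window_frames <- as.integer(window_frames)
  if (window_frames > n) abort("window_frames cannot exceed the trace length")
  if (window_frames < 3 || window_frames > 15) {
    warn(sprintf("smoothing window of %d frames is outside the usual 3-15 range",
                 window_frames))
  }
  if (window_frames %% 2L == 0L) {
    warn(sprintf("even smoothing window %d reduced to %d to stay centered",
                 window_frames, window_frames - 1L))
    window_frames <- window_frames - 1L
  }
  h <- (window_frames - 1L) %/% 2L
  if (h == 0L) return(values)
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' General-baseline fold change
#'
#' Expresses a fluorescence trace relative to its minimum over a baseline
#' window (for a glucose ramp, the 3 mM glucose period):
#' `(F_i - F_min) / F_min`. The minimum over the baseline window of the
#' result is exactly 0, and the transform is invariant to rescaling the raw
#' trace by any positive gain.
#'
#' @param values Raw fluorescence trace (positive).
#' @param baseline_window Frame indices over which `F_min` is taken
#'   (default: the whole trace).
#' @return Numeric fold-change trace with attributes `f_min`,
#'   `baseline_kind = "general"` and `source_window`.
#' @export
fold_change_general <- function(values, baseline_window = seq_along(values)) {
  if (!is.numeric(values) || !length(values)) abort("values must be a numeric trace")
  f_min <- min(values[baseline_window])
  if (!is.finite(f_min) || f_min <= 0) {
    abort(sprintf(
      "baseline minimum is %.4g but must be positive: fluorescence intensities must be > 0 over the baseline window (apply an offset correction to the raw trace)",
      f_min
    ))
  }
  out <- (values - f_min) / f_min
  attr(out, "f_min") <- f_min
  attr(out, "baseline_kind") <- "general"
  attr(out, "source_window") <- range(baseline_window)
  out
}

#' Min-max normalization of a trace
#'
#' Rescales a trace so the window minimum maps to 0 and the window maximum
#' to 1: `(F_i - F_min) / (F_max - F_min)`. Used to compare single-cell
#' activation times independently of per-cell gain and offset. `min_window`
#' and `max_window` let `F_min` and `F_max` come from different windows
#' (e.g. `F_min` from the pre-stimulus baseline, `F_max` from the response
#' window).
#'
#' @param values Numeric trace.
#' @param window Frame indices defining both extremes (default: whole trace).
#' @param min_window,max_window Optional separate windows for `F_min` and
#'   `F_max`; default to `window`.
#' @return Normalized numeric trace.
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 6))
minmax_normalize <- function(values, window = seq_along(values),
                             min_window = window, max_window = window) {
  if (!is.numeric(values) || !length(values)) abort("values must be a numeric trace")
  f_min <- min(values[min_window])
  f_max <- max(values[max_window])
  if (!(f_max > f_min)) {
    abort(sprintf(
      "degenerate trace: F_max (%.4g) must exceed F_min (%.4g); a constant trace cannot be normalized and the cell should be flagged unanalyzable",
      f_max, f_min
    ))
  }
  (values - f_min) / (f_max - f_min)
}

#' Local extrema of a trace
#'
#' Strict local maxima and minima; a plateau reports its first frame, and
#' the first/last frames of the trace are never extrema. With
#' `min_prominence > 0`, alternating peak/valley pairs whose amplitude
#' difference is below the threshold are iteratively merged away (the same
#' role as a minimum-prominence argument to a peak finder), which keeps
#' anchor placement insensitive to residual noise wiggles after smoothing.
#'
#' @param values Numeric trace, length >= 3.
#' @param min_prominence Minimum peak-to-valley swing retained (default 0 =
#'   keep all strict extrema).
#' @return A list with integer vectors `peaks` and `valleys` (frame indices).
#' @export
#' @examples
#' detect_local_extrema(c(0, 1, 0, 2, 0))
detect_local_extrema <- function(values, min_prominence = 0) {
  if (!is.numeric(values) || length(values) < 3) {
    abort("values must be a numeric trace of length >= 3")
  }
  r <- rle(values)
  k <- length(r$values)
  peaks <- valleys <- integer(0)
  if (k >= 3) {
    starts <- cumsum(c(1L, r$lengths[-k]))
    v <- r$values
    mid <- 2:(k - 1)
    peaks <- starts[mid][v[mid] > v[mid - 1] & v[mid] > v[mid + 1]]
    valleys <- starts[mid][v[mid] < v[mid - 1] & v[mid] < v[mid + 1]]
  }
  if (min_prominence > 0 && length(peaks) + length(valleys) > 1) {
    pos <- c(peaks, valleys)
    typ <- rep(c(TRUE, FALSE), c(length(peaks), length(valleys))) # TRUE = peak
    ord <- order(pos)
    pos <- pos[ord]
    typ <- typ[ord]
    val <- values[pos]
    repeat {
      if (length(pos) < 2) break
      d <- abs(diff(val))
      j <- which.min(d)
      if (d[j] >= min_prominence) break
      keep <- -c(j, j + 1L)
      pos <- pos[keep]
      val <- val[keep]
      typ <- typ[keep]
    }
    peaks <- pos[typ]
    valleys <- pos[!typ]
  }
  list(peaks = as.integer(peaks), valleys = as.integer(valleys))
}

#' Filter extrema into adaptive-baseline valley anchors
#'
#' Applies the two anchor-selection rules used before building an adaptive
#' baseline on a section fold-change trace:
#'
#' 1. Peaks closer than `min_separation_frames` to any valley are discarded
#'    from the pairing (a genuine wave takes about 12.5 s to deactivate, so
#'    a nearer valley marks a noise peak; at 0.5 s/frame, 12.5 s = 25
#'    frames).
#' 2. A valley is kept only if, relative to the immediately preceding
#'    surviving peak, `(Peak - Valley) / Peak >= min_drop_frac`. Valleys
#'    with no surviving peak before them are retained as anchors.
#'
#' @param values The trace the extrema were detected on.
#' @param peaks,valleys Frame indices from [detect_local_extrema()] on the
#'   same trace.
#' @param min_separation_frames Minimum peak-valley distance in frames
#'   (default 25, i.e. 12.5 s at 2 frames/s).
#' @param min_drop_frac Minimum fractional drop from the preceding surviving
#'   peak (default 0.30).
#' @return An object of class `extrema_filter`: a list with `valleys` (kept
#'   anchors), `peaks` (surviving peaks) and audit tibbles `removed_peaks`,
#'   `removed_valleys` with a `reason` column.
#' @export
filter_extrema <- function(values, peaks, valleys,
                           min_separation_frames = 25, min_drop_frac = 0.30) {
  peaks <- as.integer(peaks)
  valleys <- as.integer(valleys)
  removed_peaks <- integer(0)
  surviving <- peaks
  if (length(peaks) && length(valleys)) {
    near <- vapply(peaks, function(p) min(abs(p - valleys)) < min_separation_frames,
                   logical(1))
    surviving <- peaks[!near]
    removed_peaks <- peaks[near]
  }
  kept <- removed_valleys <- integer(0)
  for (v in valleys) {
    prev <- surviving[surviving < v]
    if (!length(prev)) {
      kept <- c(kept, v)
      next
    }
    p <- max(prev)
    pk <- values[p]
    ok <- pk <= 0 || (pk - values[v]) / pk >= min_drop_frac
    if (ok) kept <- c(kept, v) else removed_valleys <- c(removed_valleys, v)
  }
  structure(
    list(
      valleys = kept,
      peaks = surviving,
      removed_peaks = tibble(frame = removed_peaks,
                             reason = rep("within_min_separation_of_valley",
                                          length(removed_peaks))),
      removed_valleys = tibble(frame = removed_valleys,
                               reason = rep("drop_below_min_fraction",
                                            length(removed_valleys)))
    ),
    class = "extrema_filter"
  )
}

#' Piecewise-linear adaptive baseline through valley anchors
#'
#' Connects the retained valley anchors with straight line segments and
#' extends flat beyond the first and last anchor, yielding a per-frame
#' baseline that tracks slow drift so individual waves can be measured
#' against their local baseline. With a single anchor the baseline is
#' constant at that anchor's value; with no anchors it falls back to a
#' constant at the window minimum (logged via `message()`).
#'
#' @param values The trace the anchors belong to.
#' @param valleys Integer anchor frames, or an `extrema_filter` object from
#'   [filter_extrema()] (whose audit lists are carried along).
#' @return An object of class `adaptive_baseline`: list with per-frame
#'   `baseline`, `valley_frames`, and audit tibbles `removed_peaks` /
#'   `removed_valleys`.
#' @export
build_adaptive_baseline <- function(values, valleys) {
  removed_peaks <- tibble(frame = integer(0), reason = character(0))
  removed_valleys <- removed_peaks
  if (inherits(valleys, "extrema_filter")) {
    removed_peaks <- valleys$removed_peaks
    removed_valleys <- valleys$removed_valleys
    valleys <- valleys$valleys
  }
  valleys <- sort(as.integer(valleys))
  n <- length(values)
  if (length(valleys) == 0L) {
    message("no valley anchors: falling back to a constant baseline at the window minimum")
    baseline <- rep(min(values), n)
  } else if (length(valleys) == 1L) {
    baseline <- rep(values[valleys], n)
  } else {
    baseline <- approx(valleys, values[valleys], xout = seq_len(n), rule = 2)$y
  }
  structure(
    list(baseline = baseline, valley_frames = valleys,
         removed_peaks = removed_peaks, removed_valleys = removed_valleys),
    class = "adaptive_baseline"
  )
}

#' @export
print.adaptive_baseline <- function(x, ...) {
  cat(sprintf("<adaptive_baseline> %d frames, %d valley anchors (%d peaks, %d valleys removed)\n",
              length(x$baseline), length(x$valley_frames),
              nrow(x$removed_peaks), nrow(x$removed_valleys)))
  invisible(x)
}

#' Adaptive-baseline fold change
#'
#' Expresses a trace relative to a per-frame baseline:
#' `(F_i - F_adaptBL_i) / F_adaptBL_i`. The baseline must be positive at
#' every frame; applied to raw intensities this is the direct analogue of
#' the general fold change with the constant `F_min` replaced by the
#' adaptive baseline. For traces already in fold-change units see
#' [detrend_section()], which shifts both into ratio space first.
#'
#' @param values Numeric trace.
#' @param baseline An [build_adaptive_baseline()] result or a numeric
#'   per-frame baseline of the same length.
#' @return Numeric fold-change trace with attribute `baseline_kind = "adaptive"`.
#' @export
fold_change_adaptive <- function(values, baseline) {
  bl <- if (inherits(baseline, "adaptive_baseline")) baseline$baseline else baseline
  if (length(bl) != length(values)) {
    abort("baseline and values must have the same length")
  }
  bad <- which(bl <= 0)
  if (length(bad)) {
    abort(sprintf("adaptive baseline is not positive at frame %d (%.4g); fold change is undefined there",
                  bad[1], bl[bad[1]]))
  }
  out <- (values - bl) / bl
  attr(out, "baseline_kind") <- "adaptive"
  out
}

#' Detrend one analysis section with an adaptive baseline
#'
#' The full signal-conditioning chain for one section of a (smoothed, raw)
#' fluorescence trace, e.g. the 25 mM glucose period:
#'
#' 1. express the section as a fold change over its own minimum ("section
#'    fold change");
#' 2. find local extrema (with prominence pruning, default half the
#'    activation threshold) and filter them into valley anchors;
#' 3. connect the anchors into a piecewise-linear adaptive baseline;
#' 4. re-express the section relative to that baseline. Because the section
#'    fold change (and its baseline) can be ~0, both are shifted by +1 into
#'    ratio space first: `SF = (1 + F) / (1 + BL) - 1`, which reduces
#'    exactly to `(F_raw - BL_raw) / BL_raw` on raw intensities and keeps
#'    the "fraction above local baseline" meaning.
#'
#' @param values Raw (smoothed) fluorescence over the section; positive.
#' @param frame_interval_s Seconds per frame.
#' @param activation_threshold Fold-change activity threshold of the
#'   downstream wave detection (default 0.2); also sets the default
#'   prominence.
#' @param valley_sep_s Minimum peak-valley separation in seconds
#'   (default 12.5 s; converted to frames with `frame_interval_s`).
#' @param min_drop_frac Minimum valley drop fraction (default 0.30).
#' @param min_prominence Extrema prominence (default
#'   `activation_threshold / 2`).
#' @return An object of class `detrended_trace`: list with
#'   `section_fold_change`, `baseline` (an `adaptive_baseline`),
#'   `sf_fold_change` and `frame_interval_s`.
#' @export
detrend_section <- function(values, frame_interval_s,
                            activation_threshold = 0.2,
                            valley_sep_s = 12.5,
                            min_drop_frac = 0.30,
                            min_prominence = activation_threshold / 2) {
  fc <- fold_change_general(values, seq_along(values))
  ex <- detect_local_extrema(as.numeric(fc), min_prominence = min_prominence)
  sep_frames <- max(1L, as.integer(round(valley_sep_s / frame_interval_s)))
  flt <- filter_extrema(as.numeric(fc), ex$peaks, ex$valleys,
                        min_separation_frames = sep_frames,
                        min_drop_frac = min_drop_frac)
  ab <- suppressMessages(build_adaptive_baseline(as.numeric(fc), flt))
  sf <- (1 + as.numeric(fc)) / (1 + ab$baseline) - 1
  structure(
    list(section_fold_change = as.numeric(fc), baseline = ab,
         sf_fold_change = sf, frame_interval_s = frame_interval_s),
    class = "detrended_trace"
  )
}
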