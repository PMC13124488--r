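#' Experiment timeline
#'
#' Describes when each stimulus was added during a glucose-ramp recording:
#' 3 mM glucose baseline, submaximal 11 mM glucose, maximal 25 mM glucose and
#' a terminal KCl depolarization. All positions are 1-based frame indices;
#' `frame_g11 = 360` means frames 1..360 were acquired at 3 mM and frame 361
#' is the first frame after the 11 mM addition. Defaults reproduce the
#' standard acquisition protocol: 0.5 s/frame, 5,040 frames (42 min), 11 mM
#' at frame 360 (3 min), 25 mM at frame 2,160 (18 min) and KCl at frame
#' 4,800.
#'
#' @param frame_interval_s Seconds per frame (> 0).
#' @param n_frames Total number of frames (>= 2).
#' @param frame_g11 Frame at which glucose was raised from 3 to 11 mM.
#' @param frame_g25 Frame at which glucose was raised to 25 mM.
#' @param frame_kcl Frame at which KCl was added.
#' @param first_phase_end_frame End of the first-phase analysis window; must
#'   lie in `(frame_g11, frame_g25]`. Defaults to `frame_g25`.
#'
#' @return An object of class `experiment_timeline`.
#' @export
#' @examples
#' tl <- experiment_timeline()
#' first_phase_window(tl)[1:3]
experiment_timeline <- function(frame_interval_s = 0.5,
                                n_frames = 5040L,
                                frame_g11 = 360L,
                                frame_g25 = 2160L,
                                frame_kcl = 4800L,
                                first_phase_end_frame = frame_g25) {
  for (nm in c("frame_interval_s", "n_frames", "frame_g11", "frame_g25",
               "frame_kcl", "first_phase_end_frame")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("timeline field '%s' must be a finite numeric scalar", nm))
    }
  }
  if (frame_interval_s <= 0) abort("frame_interval_s must be > 0")
  if (n_frames < 2) abort("n_frames must be >= 2")
  if (!(0 < frame_g11 && frame_g11 < frame_g25 && frame_g25 < frame_kcl &&
        frame_kcl <= n_frames)) {
    abort(sprintf(
      "stimulus frames must satisfy 0 < frame_g11 < frame_g25 < frame_kcl <= n_frames (got %d, %d, %d, %d)",
      as.integer(frame_g11), as.integer(frame_g25), as.integer(frame_kcl),
      as.integer(n_frames)
    ))
  }
  if (!(frame_g11 < first_phase_end_frame && first_phase_end_frame <= frame_g25)) {
    abort("first_phase_end_frame must lie in (frame_g11, frame_g25]")
  }
  structure(
    list(
      frame_interval_s = as.numeric(frame_interval_s),
      n_frames = as.integer(n_frames),
      frame_g11 = as.integer(frame_g11),
      frame_g25 = as.integer(frame_g25),
      frame_kcl = as.integer(frame_kcl),
      first_phase_end_frame = as.integer(first_phase_end_frame)
    ),
    class = "experiment_timeline"
  )
}

#' @export
print.experiment_timeline <- function(x, ...) {
  mins <- function(f) sprintf("%.1f min", f * x$frame_interval_s / 60)
  cat("<experiment_timeline>\n")
  cat(sprintf("  %d frames @ %.3g s/frame (%s total)\n",
              x$n_frames, x$frame_interval_s, mins(x$n_frames)))
  cat(sprintf("  11 mM glucose : frame %d (%s)\n", x$frame_g11, mins(x$frame_g11)))
  cat(sprintf("  25 mM glucose : frame %d (%s)\n", x$frame_g25, mins(x$frame_g25)))
  cat(sprintf("  KCl           : frame %d (%s)\n", x$frame_kcl, mins(x$frame_kcl)))
  cat(sprintf("  first-phase end: frame %d\n", x$first_phase_end_frame))
  invisible(x)
}

#' Analysis windows of a timeline
#'
#' Frame-index windows used throughout the pipeline. `baseline_window()` is
#' the 3 mM glucose period, `first_phase_window()` runs from the 11 mM
#' addition to `first_phase_end_frame`, `second_phase_window()` from the
#' 25 mM addition to the KCl addition, and `kcl_window()` from the KCl
#' addition to the end of the recording. `section_window()` selects the
#' section used for adaptive-baseline detrending, connectivity and leader
#' analysis: `"g25"` (default) is the 25 mM section, `"g11"` the 11 mM
#' section (useful when the 11 mM period was extended for connectivity).
#'
#' @param timeline An [experiment_timeline()].
#' @param section `"g25"` or `"g11"`.
#' @return Integer vector of frame indices.
#' @export
baseline_window <- function(timeline) seq_len(timeline$frame_g11)

#' @rdname baseline_window
#' @export
first_phase_window <- function(timeline) {
  (timeline$frame_g11 + 1L):timeline$first_phase_end_frame
}

#' @rdname baseline_window
#' @export
second_phase_window <- function(timeline) {
  (timeline$frame_g25 + 1L):timeline$frame_kcl
}

#' @rdname baseline_window
#' @export
kcl_window <- function(timeline) {
  if (timeline$frame_kcl >= timeline$n_frames) return(integer(0))
  (timeline$frame_kcl + 1L):timeline$n_frames
}

#' @rdname baseline_window
#' @export
section_window <- function(timeline, section = c("g25", "g11")) {
  section <- match.arg(section)
  if (section == "g25") second_phase_window(timeline)
  else (timeline$frame_g11 + 1L):timeline$frame_g25
}

timeline_fields <- c("frame_interval_s", "n_frames", "frame_g11", "frame_g25",
                     "frame_kcl", "first_phase_end_frame")

#' Read or write an experiment-timeline configuration
#'
#' The configuration is flat JSON with explicit keys (`frame_interval_s`,
#' `n_frames`, `frame_g11`, `frame_g25`, `frame_kcl`, and optionally
#' `first_phase_end_frame`). Stimulus frames are experimenter-controlled and
#' are never inferred from the trace itself. If the file sets
#' `"use_protocol_defaults": true`, missing fields fall back to the standard
#' protocol defaults of [experiment_timeline()]; otherwise every field except
#' `first_phase_end_frame` is required.
#'
#' @param path Path to a JSON file.
#' @param timeline An [experiment_timeline()] (for writing).
#' @return [read_timeline_config()] returns an [experiment_timeline()];
#'   [write_timeline_config()] returns `path` invisibly.
#' @export
read_timeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("timeline config '%s' does not exist", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- unclass(experiment_timeline())
  use_def <- isTRUE(cfg$use_protocol_defaults)
  vals <- list()
  for (nm in timeline_fields) {
    if (!is.null(cfg[[nm]])) {
      vals[[nm]] <- cfg[[nm]]
    } else if (use_def) {
      vals[[nm]] <- defaults[[nm]]
    } else if (nm == "first_phase_end_frame") {
      vals[[nm]] <- NULL # constructor default (frame_g25)
    } else {
      abort(sprintf(
        "timeline config is missing required field '%s' (set use_protocol_defaults to fall back)",
        nm
      ))
    }
  }
  if (is.null(vals$first_phase_end_frame)) {
    do.call(experiment_timeline, vals[setdiff(timeline_fields, "first_phase_end_frame")])
  } else {
    do.call(experiment_timeline, vals)
  }
}

#' @rdname read_timeline_config
#' @export
write_timeline_config <- function(timeline, path) {
  stopifnot(inherits(timeline, "experiment_timeline"))
  jsonlite::write_json(unclass(timeline), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
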