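#' Analysis configuration
#'
#' All tunable thresholds of the pipeline with their conventional defaults:
#' smoothing window 15 frames; activation threshold 0.2 fold change; minimum
#' wave duration 2 s; valley filter 30% drop and 12.5 s peak-valley
#' separation; binarization threshold 0.2; 10,000 shuffles per pair;
#' leader percentile 10; first-responder fraction 10%; both hub rules. Every
#' run writes its resolved configuration next to its outputs.
#'
#' @param smoothing_window Moving-average filter size in frames.
#' @param activation_threshold Fold-change activity threshold.
#' @param min_wave_s Minimum sustained activity for a wave, seconds.
#' @param valley_min_drop Minimum valley drop fraction for baseline anchors.
#' @param valley_sep_s Minimum peak-valley separation, seconds.
#' @param min_prominence Extrema prominence for anchor detection; default
#'   half the activation threshold.
#' @param binarize_threshold Binarization threshold.
#' @param n_shuffles Shuffle-null surrogates per cell pair.
#' @param leader_percentile Leader latency percentile cutoff.
#' @param fr_fraction First-responder fraction.
#' @param hub_rule `"criterion"`, `"top10"` or `"both"`.
#' @param connectivity_section Section for detrending/connectivity/leaders:
#'   `"g25"` (default) or `"g11"`.
#' @param coactivity_norm `"sqrt"` or `"printed"` (see [coactivity_pair()]).
#' @param c_islet_significant_only Average only significant pairs into the
#'   islet connectivity score.
#' @param rng_seed Seed for the shuffle null.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(smoothing_window = 15,
                       activation_threshold = 0.2,
                       min_wave_s = 2.0,
                       valley_min_drop = 0.30,
                       valley_sep_s = 12.5,
                       min_prominence = activation_threshold / 2,
                       binarize_threshold = 0.2,
                       n_shuffles = 10000,
                       leader_percentile = 10,
                       fr_fraction = 0.10,
                       hub_rule = c("both", "criterion", "top10"),
                       connectivity_section = c("g25", "g11"),
                       coactivity_norm = c("sqrt", "printed"),
                       c_islet_significant_only = FALSE,
                       rng_seed = 1L) {
  hub_rule <- match.arg(hub_rule)
  connectivity_section <- match.arg(connectivity_section)
  coactivity_norm <- match.arg(coactivity_norm)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full islet analysis pipeline
#'
#' Executes, in order: smoothing of every trace; islet general-baseline fold
#' change; first-phase metrics and apparent/trapezoid AUCs of both phases;
#' adaptive-baseline detrending of the analysis section; islet wave
#' detection and second-phase metrics; KCl-responsiveness filter;
#' first-responder identification; per-cell detrending, binarization,
#' coactivity matrix with shuffle-null significance and hub calls; per-wave
#' windows and leader identification; network export. Cells excluded by the
#' KCl filter carry no subpopulation labels.
#'
#' @param traces A [trace_matrix()], or an [simulate_islet()] result (whose
#'   timeline and centroids are then used).
#' @param timeline An [experiment_timeline()] (required unless `traces` is a
#'   simulation).
#' @param centroids Optional centroid tibble (`cell_id`, `x_px`, `y_px`).
#' @param config A [run_config()].
#' @return An object of class `islet_analysis`: list with `global` (one-row
#'   tibble of islet-level metrics), `waves`, `cells` (per-cell labels),
#'   `coactivity` (a `coactivity_result` or `NULL`), `edges`, `windows`,
#'   `islet` (fold-change and detrended traces), `sf_matrix`, `timeline`
#'   and the resolved `config`.
#' @export
#' @examples
#' sim <- simulate_islet(islet_preset("clean", n_cells = 12, rng_seed = 1))
#' res <- run_islet_analysis(sim, config = run_config(n_shuffles = 100))
#' glance(res)
run_islet_analysis <- function(traces, timeline = NULL, centroids = NULL,
                               config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(traces, "islet_simulation")) {
    timeline <- timeline %||% traces$timeline
    centroids <- centroids %||% traces$centroids
    traces <- traces$traces
  }
  if (!inherits(traces, "trace_matrix")) abort("traces must be a trace_matrix")
  if (is.null(timeline)) abort("a timeline is required")
  stopifnot(inherits(timeline, "experiment_timeline"))
  if (n_frames(traces) != timeline$n_frames) {
    abort(sprintf("trace matrix has %d frames but the timeline expects %d",
                  n_frames(traces), timeline$n_frames))
  }
  dt <- traces$frame_interval_s
  if (abs(dt - timeline$frame_interval_s) > 1e-9) {
    abort("trace matrix and timeline disagree on the frame interval")
  }

  # -- signal conditioning -------------------------------------------------
  cells_raw <- cell_traces(traces)
  cells_s <- t(apply(cells_raw, 1, smooth_trace, window_frames = config$smoothing_window))
  rownames(cells_s) <- rownames(cells_raw)
  islet_s <- smooth_trace(islet_trace(traces), config$smoothing_window)

  # -- islet-level global metrics -----------------------------------------
  islet_fc <- fold_change_general(islet_s, baseline_window(timeline))
  fp <- first_phase_metrics(islet_fc, timeline, config$activation_threshold)
  fpw <- first_phase_window(timeline)
  spw <- second_phase_window(timeline)
  aucs <- tibble(
    auc_app_first = auc_app(islet_fc, fpw),
    auc_app_second = auc_app(islet_fc, spw),
    auc_trap_first = auc_trapezoid(islet_fc, fpw, dt),
    auc_trap_second = auc_trapezoid(islet_fc, spw, dt)
  )

  sec <- section_window(timeline, config$connectivity_section)
  islet_det <- detrend_section(islet_s[sec], dt,
                               activation_threshold = config$activation_threshold,
                               valley_sep_s = config$valley_sep_s,
                               min_drop_frac = config$valley_min_drop,
                               min_prominence = config$min_prominence)
  waves <- detect_waves(islet_det$sf_fold_change, config$activation_threshold,
                        config$min_wave_s, dt)
  sp <- second_phase_metrics(waves, seq_along(sec), dt)
  waves$activation_frame_abs <- waves$activation_frame + sec[1] - 1L
  waves$deactivation_frame_abs <- waves$deactivation_frame + sec[1] - 1L

  # -- per-cell analyses ---------------------------------------------------
  kcl <- kcl_filter(cells_s, timeline, config$activation_threshold)
  fr <- identify_first_responders(cells_s, timeline, config$fr_fraction,
                                  config$activation_threshold,
                                  included = kcl$included,
                                  frame_interval_s = dt)

  sf_matrix <- t(apply(cells_s, 1, function(v) {
    detrend_section(v[sec], dt,
                    activation_threshold = config$activation_threshold,
                    valley_sep_s = config$valley_sep_s,
                    min_drop_frac = config$valley_min_drop,
                    min_prominence = config$min_prominence)$sf_fold_change
  }))
  rownames(sf_matrix) <- rownames(cells_s)

  inc <- which(kcl$included)
  coact <- NULL
  hubs_c <- hubs_t <- NULL
  edges <- tibble(source = character(0), target = character(0),
                  weight = numeric(0), significant = logical(0))
  if (length(inc) >= 2) {
    bin <- binarize(sf_matrix[inc, , drop = FALSE], config$binarize_threshold)
    coact <- coactivity_matrix(bin, n_shuffles = config$n_shuffles,
                               seed = config$rng_seed,
                               norm = config$coactivity_norm,
                               c_islet_significant_only = config$c_islet_significant_only)
    if (config$hub_rule %in% c("criterion", "both")) {
      hubs_c <- identify_hubs_criterion(coact)
    }
    if (config$hub_rule %in% c("top10", "both")) {
      hubs_t <- identify_hubs_top10(coact)
    }
    net <- withCallingHandlers(
      export_network(coact, centroids),
      warning = function(w) invokeRestart("muffleWarning")
    )
    edges <- net$edges
  } else {
    warn("fewer than 2 KCl-responsive cells: connectivity analysis skipped")
  }

  ww <- wave_windows(waves[, c("wave_id", "activation_frame",
                               "deactivation_frame")],
                     islet_det$baseline$valley_frames,
                     section_start = 1L, section_end = length(sec) + 1L)
  leaders <- suppressWarnings(
    identify_leaders(sf_matrix, ww, dt,
                     percentile = config$leader_percentile,
                     activation_threshold = config$binarize_threshold,
                     included = kcl$included)
  )

  # -- assemble ------------------------------------------------------------
  cells <- dplyr::left_join(kcl, fr[, c("cell_id", "fr_t20_s", "is_first_responder")],
                            by = "cell_id")
  cells <- dplyr::left_join(
    cells, leaders[, c("cell_id", "mean_scsp_t20_s", "n_waves_active", "is_leader")],
    by = "cell_id"
  )
  cells$is_hub_criterion <- FALSE
  cells$is_hub_top10 <- FALSE
  if (!is.null(hubs_c)) {
    cells$is_hub_criterion[match(hubs_c$cell_id, cells$cell_id)] <- hubs_c$is_hub_criterion
  }
  if (!is.null(hubs_t)) {
    cells$is_hub_top10[match(hubs_t$cell_id, cells$cell_id)] <- hubs_t$is_hub_top10
  }
  if (!is.null(centroids)) {
    cells <- dplyr::left_join(cells, centroids[, c("cell_id", "x_px", "y_px")],
                              by = "cell_id")
  } else {
    cells$x_px <- NA_real_
    cells$y_px <- NA_real_
  }

  global <- dplyr::bind_cols(
    fp, aucs, sp,
    tibble(
      n_cells = nrow(cells_s),
      n_included = sum(kcl$included),
      c_islet = if (is.null(coact)) NA_real_ else coact$c_islet,
      connectivity_class = if (is.null(coact)) NA_character_ else coact$connectivity_class
    )
  )

  cfg_out <- unclass(config)
  cfg_out$timeline <- unclass(timeline)

  structure(
    list(global = global, waves = waves, cells = cells, coactivity = coact,
         edges = edges, windows = ww,
         islet = list(smoothed = islet_s, fold_change = as.numeric(islet_fc),
                      detrended = islet_det, section = sec),
         sf_matrix = sf_matrix, timeline = timeline, config = cfg_out),
    class = "islet_analysis"
  )
}

#' @export
print.islet_analysis <- function(x, ...) {
  g <- x$global
  cat(sprintf("<islet_analysis> %d cells (%d KCl-responsive), %d second-phase waves\n",
              g$n_cells, g$n_included, g$n_waves))
  cat(sprintf("  first phase : T20 %.1f s, amplitude %.2f, width %.1f s\n",
              g$fp_t20_s, g$fp_amplitude, g$fp_width_s))
  cat(sprintf("  second phase: %.2f waves/min, mean amplitude %.2f, mean width %.1f s\n",
              g$sp_frequency_per_min, g$sp_mean_amplitude, g$sp_mean_width_s))
  if (!is.na(g$c_islet)) {
    cat(sprintf("  connectivity: c_islet %.3f (%s)\n", g$c_islet, g$connectivity_class))
  }
  cat(sprintf("  labels: %d first-responders, %d leaders, %d criterion hubs, %d top-10%% hubs\n",
              sum(x$cells$is_first_responder, na.rm = TRUE),
              sum(x$cells$is_leader, na.rm = TRUE),
              sum(x$cells$is_hub_criterion, na.rm = TRUE),
              sum(x$cells$is_hub_top10, na.rm = TRUE)))
  invisible(x)
}

#' Run the file-based analysis pipeline
#'
#' Thin wrapper binding [read_multimeasure_csv()], [read_centroids_csv()],
#' [read_timeline_config()], [run_islet_analysis()] and [write_results()]
#' for one-command runs (this is what the CLI `analyze` subcommand calls).
#' A missing centroid file degrades the network export with a warning
#' instead of failing.
#'
#' @param traces_csv,timeline_json Input paths (required).
#' @param centroids_csv Optional centroid CSV path.
#' @param outdir Output directory.
#' @param islet_roi_first Is the first ROI column the whole-islet polygon?
#' @param config A [run_config()].
#' @return The `islet_analysis`, invisibly; results are written to `outdir`.
#' @export
run_full_analysis <- function(traces_csv, timeline_json, centroids_csv = NULL,
                              outdir = "islet-results", islet_roi_first = FALSE,
                              config = run_config()) {
  timeline <- read_timeline_config(timeline_json)
  traces <- read_multimeasure_csv(traces_csv, timeline$frame_interval_s,
                                  islet_roi_first = islet_roi_first)
  centroids <- NULL
  if (!is.null(centroids_csv)) {
    if (file.exists(centroids_csv)) {
      centroids <- read_centroids_csv(centroids_csv)
    } else {
      warn(sprintf("centroid file '%s' not found: network export degraded",
                   centroids_csv))
    }
  }
  res <- run_islet_analysis(traces, timeline, centroids, config)
  write_results(res, outdir)
  invisible(res)
}

#' Tidiers for analysis results
#'
#' `tidy()` on an `islet_analysis` returns the per-cell label table; on a
#' `coactivity_result` the weighted edge list. `glance()` returns the
#' one-row islet-level summary.
#'
#' @param x An `islet_analysis` or `coactivity_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.islet_analysis <- function(x, ...) x$cells

#' @rdname tidy.islet_analysis
#' @export
glance.islet_analysis <- function(x, ...) x$global

#' @rdname tidy.islet_analysis
#' @export
tidy.coactivity_result <- function(x, ...) {
  ut <- which(upper.tri(x$C), arr.ind = TRUE)
  tibble(
    source = x$cell_ids[ut[, 1]],
    target = x$cell_ids[ut[, 2]],
    coactivity = x$C[ut],
    null_mean = x$null_mean[ut],
    null_sd = x$null_sd[ut],
    significant = x$significant[ut]
  )
}

#' @rdname tidy.islet_analysis
#' @export
glance.coactivity_result <- function(x, ...) {
  tibble(
    n_cells = length(x$cell_ids),
    n_pairs = choose(length(x$cell_ids), 2),
    n_significant = sum(x$significant[upper.tri(x$significant)]),
    c_islet = x$c_islet,
    connectivity_class = x$connectivity_class,
    n_shuffles = x$n_shuffles
  )
}
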