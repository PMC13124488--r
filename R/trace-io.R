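#' Read an ImageJ Multi-Measure trace CSV
#'
#' Reads the CSV written by ImageJ's ROI manager "Multi Measure" (one row per
#' frame, one fluorescence column per ROI, integrated density per frame).
#' Both bare ROI names and `IntDen1..IntDenN` style headers are accepted. A
#' leading row-index column (the ImageJ frame counter: unnamed, or named
#' something like `X`/`...1`, holding the strictly increasing integers
#' `1..n`) is recognized and excluded from the ROI set. Column order is
#' preserved; ROIs are never reordered.
#'
#' Any cell that does not parse as a finite number (including `NaN`) is an
#' error naming the offending data row and column: rows are never silently
#' dropped.
#'
#' @param path Path to the CSV file.
#' @param frame_interval_s Seconds per frame of the recording.
#' @param islet_roi_first Is the first ROI column the whole-islet polygon?
#' @return A [trace_matrix()] (ROIs x frames).
#' @export
read_multimeasure_csv <- function(path, frame_interval_s = 0.5,
                                  islet_roi_first = FALSE) {
  if (!file.exists(path)) abort(sprintf("trace file '%s' does not exist", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("'%s' is not a rectangular CSV: %s (first problem at row %d)",
                  path, prob$expected[1], prob$row[1]))
  }
  if (nrow(raw) < 2) abort(sprintf("'%s' must contain at least 2 data rows", path))

  nms <- names(raw)
  nms[is.na(nms)] <- ""
  first <- suppressWarnings(as.numeric(raw[[1]]))
  # a strictly increasing 1..n integer first column is the ImageJ frame
  # counter whatever its header; never dropped if it is the only column
  index_like <- !anyNA(first) && all(first == seq_len(nrow(raw)))
  drop_first <- ncol(raw) > 1 && index_like
  dat <- if (drop_first) raw[-1] else raw
  if (ncol(dat) < 1) abort(sprintf("'%s' has no ROI columns", path))

  ids <- names(dat)
  blank <- !nzchar(ids) | is.na(ids)
  ids[blank] <- paste0("roi_", which(blank))

  mat <- matrix(NA_real_, nrow = nrow(dat), ncol = ncol(dat))
  for (j in seq_len(ncol(dat))) {
    v <- suppressWarnings(as.numeric(dat[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      abort(sprintf(
        "'%s': value '%s' at data row %d, column '%s' is not a finite number",
        path, as.character(dat[[j]][bad[1]]), bad[1], ids[j]
      ))
    }
    mat[, j] <- v
  }

  trace_matrix(t(mat), frame_interval_s = frame_interval_s,
               cell_ids = ids, includes_islet_roi = islet_roi_first)
}

#' Write a trace matrix as a Multi-Measure style CSV
#'
#' Inverse of [read_multimeasure_csv()]: one row per frame, a leading frame
#' counter column, one column per ROI. Reading the file back yields the same
#' trace matrix (within float formatting).
#'
#' @param tm A [trace_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimeasure_csv <- function(tm, path) {
  stopifnot(inherits(tm, "trace_matrix"))
  df <- as.data.frame(t(tm$fluorescence))
  names(df) <- tm$cell_ids
  out <- cbind(data.frame(` ` = seq_len(nrow(df)), check.names = FALSE), df)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an ImageJ centroid table
#'
#' Reads the CSV produced by ImageJ "Measure" with the centroid measurement
#' selected: one row per cell ROI with `X` and `Y` pixel coordinates
#' (case-insensitive column match). Row order is preserved so the i-th
#' centroid belongs to the i-th cell ROI of the trace file. An optional
#' label column (`cell_id`, `label` or `roi`, case-insensitive) supplies cell
#' identities; otherwise `cell_1..cell_n` are assigned.
#'
#' @param path Path to the CSV file.
#' @param expected_n Optional expected number of centroids; a mismatch is a
#'   validation error listing both counts.
#' @return A tibble with columns `cell_id`, `x_px`, `y_px`.
#' @export
read_centroids_csv <- function(path, expected_n = NULL) {
  if (!file.exists(path)) abort(sprintf("centroid file '%s' does not exist", path))
  dat <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  lower <- tolower(names(dat))
  xi <- which(lower == "x")[1]
  yi <- which(lower == "y")[1]
  if (is.na(xi) || is.na(yi)) {
    abort(sprintf("'%s' must have X and Y columns (case-insensitive); found: %s",
                  path, paste(names(dat), collapse = ", ")))
  }
  x <- suppressWarnings(as.numeric(dat[[xi]]))
  y <- suppressWarnings(as.numeric(dat[[yi]]))
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    bad <- which(!is.finite(x) | !is.finite(y))[1]
    abort(sprintf("'%s': centroid coordinates at row %d are not finite numbers",
                  path, bad))
  }
  if (!is.null(expected_n) && nrow(dat) != expected_n) {
    abort(sprintf("'%s' holds %d centroids but %d were expected",
                  path, nrow(dat), as.integer(expected_n)))
  }
  li <- which(lower %in% c("cell_id", "label", "roi"))[1]
  ids <- if (!is.na(li)) as.character(dat[[li]]) else paste0("cell_", seq_along(x))
  tibble(cell_id = ids, x_px = x, y_px = y)
}

#' @rdname read_centroids_csv
#' @param centroids A tibble with `cell_id`, `x_px`, `y_px` columns.
#' @export
write_centroids_csv <- function(centroids, path) {
  readr::write_csv(
    data.frame(cell_id = centroids$cell_id, X = centroids$x_px, Y = centroids$y_px),
    path, progress = FALSE
  )
  invisible(path)
}

#' Write the full result file set of an analysis
#'
#' Writes a deterministic, diffable file set into `outdir`:
#' `global_metrics.json` (islet-level metrics), `waves.csv` (detected
#' second-phase waves), `coactivity_matrix.csv` and `significance_mask.csv`
#' (dense, header = cell ids), `cell_labels.csv` (per-cell latencies, flags
#' and centroid positions), `edges.csv` (weighted edge list with a
#' `significant` column) and `resolved_config.json` (the full configuration
#' the run used). Numeric CSV fields use shortest round-trip formatting
#' (>= 10 significant digits), so re-running the same configuration and seed
#' yields byte-identical files.
#'
#' @param analysis An `islet_analysis` object from [run_islet_analysis()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_results <- function(analysis, outdir) {
  stopifnot(inherits(analysis, "islet_analysis"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create output directory '%s'", outdir))

  paths <- c(
    global_metrics = file.path(outdir, "global_metrics.json"),
    waves = file.path(outdir, "waves.csv"),
    coactivity = file.path(outdir, "coactivity_matrix.csv"),
    mask = file.path(outdir, "significance_mask.csv"),
    labels = file.path(outdir, "cell_labels.csv"),
    edges = file.path(outdir, "edges.csv"),
    config = file.path(outdir, "resolved_config.json")
  )

  jsonlite::write_json(as.list(analysis$global), paths[["global_metrics"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  readr::write_csv(analysis$waves, paths[["waves"]], progress = FALSE, na = "")

  co <- analysis$coactivity
  if (!is.null(co)) {
    cm <- as.data.frame(co$C)
    names(cm) <- co$cell_ids
    readr::write_csv(cbind(data.frame(cell_id = co$cell_ids), cm),
                     paths[["coactivity"]], progress = FALSE)
    sm <- as.data.frame(co$significant * 1L)
    names(sm) <- co$cell_ids
    readr::write_csv(cbind(data.frame(cell_id = co$cell_ids), sm),
                     paths[["mask"]], progress = FALSE)
    readr::write_csv(analysis$edges, paths[["edges"]], progress = FALSE, na = "")
  } else {
    readr::write_csv(tibble(cell_id = character()), paths[["coactivity"]],
                     progress = FALSE)
    readr::write_csv(tibble(cell_id = character()), paths[["mask"]],
                     progress = FALSE)
    readr::write_csv(tibble(source = character(), target = character(),
                            weight = numeric(), significant = logical()),
                     paths[["edges"]], progress = FALSE)
  }

  readr::write_csv(analysis$cells, paths[["labels"]], progress = FALSE, na = "")
  jsonlite::write_json(analysis$config, paths[["config"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(unname(paths))
}
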