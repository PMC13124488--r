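#' Fluorescence trace matrix
#'
#' Container for per-ROI raw fluorescence: a cells x frames numeric matrix
#' with ROI identities and a time axis. When `includes_islet_roi` is `TRUE`
#' the first row is the whole-islet polygon ROI rather than a single cell.
#'
#' @param fluorescence Numeric matrix, one row per ROI, one column per frame.
#' @param frame_interval_s Seconds per frame (> 0).
#' @param cell_ids Character vector of ROI labels (defaults to rownames or
#'   `roi_1..roi_n`).
#' @param includes_islet_roi Is row 1 the whole-islet polygon trace?
#'
#' @return An object of class `trace_matrix`.
#' @export
#' @examples
#' tm <- trace_matrix(matrix(c(10, 20, 11, 21, 12, 22), nrow = 2), 0.5)
#' n_frames(tm)
trace_matrix <- function(fluorescence, frame_interval_s,
                         cell_ids = NULL, includes_islet_roi = FALSE) {
  if (!is.matrix(fluorescence) || !is.numeric(fluorescence)) {
    abort("fluorescence must be a numeric matrix (cells x frames)")
  }
  if (ncol(fluorescence) < 2) abort("a trace matrix needs at least 2 frames")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1 ||
      frame_interval_s <= 0) {
    abort("frame_interval_s must be a positive scalar")
  }
  if (anyNA(fluorescence)) abort("fluorescence contains missing values")
  if (any(fluorescence < 0)) abort("fluorescence intensities must be >= 0")
  if (is.null(cell_ids)) {
    cell_ids <- rownames(fluorescence) %||% paste0("roi_", seq_len(nrow(fluorescence)))
  }
  if (length(cell_ids) != nrow(fluorescence)) {
    abort("cell_ids length must match the number of rows")
  }
  if (anyDuplicated(cell_ids)) abort("cell_ids must be unique")
  rownames(fluorescence) <- cell_ids
  structure(
    list(
      fluorescence = fluorescence,
      cell_ids = as.character(cell_ids),
      frame_interval_s = as.numeric(frame_interval_s),
      includes_islet_roi = isTRUE(includes_islet_roi)
    ),
    class = "trace_matrix"
  )
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d ROI%s x %d frames @ %.3g s/frame%s\n",
              nrow(x$fluorescence), if (nrow(x$fluorescence) == 1) "" else "s",
              ncol(x$fluorescence), x$frame_interval_s,
              if (x$includes_islet_roi) " (row 1 = whole-islet ROI)" else ""))
  invisible(x)
}

#' @rdname trace_matrix
#' @param tm A `trace_matrix`.
#' @export
n_frames <- function(tm) ncol(tm$fluorescence)

#' Cell-only and islet-level views of a trace matrix
#'
#' `cell_traces()` drops the whole-islet ROI row (if present) and returns the
#' cells x frames matrix. `islet_trace()` returns the whole-islet
#' fluorescence vector: the polygon ROI row when the matrix carries one,
#' otherwise the column-wise sum of the cell ROIs (fold change is invariant
#' to that scale, so sum versus mean is immaterial downstream).
#'
#' @param tm A [trace_matrix()].
#' @return A numeric matrix (`cell_traces`) or vector (`islet_trace`).
#' @export
cell_traces <- function(tm) {
  stopifnot(inherits(tm, "trace_matrix"))
  m <- tm$fluorescence
  if (tm$includes_islet_roi) m[-1L, , drop = FALSE] else m
}

#' @rdname cell_traces
#' @export
islet_trace <- function(tm) {
  stopifnot(inherits(tm, "trace_matrix"))
  if (tm$includes_islet_roi) tm$fluorescence[1L, ] else colSums(tm$fluorescence)
}

#' @export
as_tibble.trace_matrix <- function(x, ...) {
  m <- x$fluorescence
  tibble(
    cell_id = rep(x$cell_ids, times = ncol(m)),
    frame = rep(seq_len(ncol(m)), each = nrow(m)),
    time_s = (rep(seq_len(ncol(m)), each = nrow(m)) - 1) * x$frame_interval_s,
    fluorescence = as.vector(m)
  )
}
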