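#' Binarize fold-change activity
#'
#' Maps per-cell adaptive-baseline fold-change traces to on/off activity:
#' 1 where the value is strictly above `threshold`, else 0. At 20% above the
#' local baseline this threshold sits at the elbow of the
#' connectivity-vs-threshold curve for GCaMP6 recordings, balancing noise
#' suppression against coactivity information loss; other sensors may need
#' a different value.
#'
#' @param sf_fold_change A cells x frames matrix (or a single trace) of
#'   adaptive-baseline fold-change values.
#' @param threshold Binarization threshold (default 0.2; strict `>`).
#' @return A 0/1 matrix (or vector) of the same shape, with attribute
#'   `threshold`.
#' @export
#' @examples
#' binarize(c(0.25, 0.15, 0.2)) # 1, 0, 0 — exactly-at-threshold is inactive
binarize <- function(sf_fold_change, threshold = 0.2) {
  out <- (sf_fold_change > threshold) * 1L
  attr(out, "threshold") <- threshold
  out
}

#' Coactivity coefficient of a cell pair
#'
#' `C_ij = T_ij / sqrt(T_i * T_j)` where `T_i`, `T_j` are the total active
#' times of the two cells and `T_ij` their co-active time. The coefficient
#' lies in `[0, 1]`: 1 means the pair is perfectly coordinated (always
#' active together), 0.5 that two equally active cells are coordinated half
#' the time they are active, and 0 that they share no coordination. Pairs
#' where either cell is never active get 0. The literal product
#' normalization `T_ij / (T_i * T_j)` is available as `norm = "printed"`
#' for comparison with legacy scripts (note it cannot reach 1).
#'
#' @param a_binary,b_binary Equal-length 0/1 activity vectors.
#' @param norm `"sqrt"` (default) or `"printed"`.
#' @return The coactivity coefficient (a single number).
#' @export
coactivity_pair <- function(a_binary, b_binary, norm = c("sqrt", "printed")) {
  norm <- match.arg(norm)
  if (length(a_binary) != length(b_binary)) {
    abort("activity vectors must have the same length")
  }
  ti <- sum(a_binary)
  tj <- sum(b_binary)
  if (ti == 0 || tj == 0) return(0)
  tij <- sum(a_binary * b_binary)
  if (norm == "sqrt") tij / sqrt(ti * tj) else tij / (ti * tj)
}

# Circular cross-correlation of two 0/1 vectors: co-active counts at every
# relative rotation (lag 0..n-1), via FFT. Independent circular rotations of
# the two vectors only matter through their lag difference, which is itself
# uniform on 0..n-1, so sampling one uniform lag per surrogate reproduces
# the rotation null exactly.
circular_overlap <- function(a, b) {
  n <- length(a)
  o <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / n
  pmax(round(o), 0)
}

#' Shuffle null for a coactivity coefficient
#'
#' Tests an observed pairwise coactivity against surrogates in which each
#' cell's activity is independently circularly rotated by a uniform random
#' offset: rotations preserve each cell's total active time and burst-length
#' structure while destroying their temporal alignment. The pair is
#' significantly linked iff the observed coefficient exceeds the surrogate
#' mean by more than two surrogate standard deviations (the conventional
#' p < 0.01 rule). Uses the current RNG state; seed with `set.seed()` (or
#' let [coactivity_matrix()] manage the seed) for reproducibility.
#'
#' @param a_binary,b_binary Equal-length 0/1 activity vectors.
#' @param n_shuffles Number of surrogates (default 10,000; must be >= 1).
#' @param norm Coactivity normalization, see [coactivity_pair()].
#' @return A list: `observed`, `null_mean`, `null_sd`, `significant`.
#' @export
shuffle_null <- function(a_binary, b_binary, n_shuffles = 10000,
                         norm = c("sqrt", "printed")) {
  norm <- match.arg(norm)
  if (!is.numeric(n_shuffles) || length(n_shuffles) != 1 || n_shuffles < 1) {
    abort("n_shuffles must be a single value >= 1")
  }
  if (length(a_binary) != length(b_binary)) {
    abort("activity vectors must have the same length")
  }
  n <- length(a_binary)
  ti <- sum(a_binary)
  tj <- sum(b_binary)
  if (ti == 0 || tj == 0) {
    return(list(observed = 0, null_mean = 0, null_sd = 0, significant = FALSE))
  }
  den <- if (norm == "sqrt") sqrt(ti * tj) else ti * tj
  obs <- sum(a_binary * b_binary) / den
  o <- circular_overlap(as.numeric(a_binary), as.numeric(b_binary))
  lags <- sample.int(n, n_shuffles, replace = TRUE)
  nulls <- o[lags] / den
  nm <- mean(nulls)
  nsd <- sd(nulls)
  if (is.na(nsd)) nsd <- 0
  list(observed = obs, null_mean = nm, null_sd = nsd,
       significant = obs > nm + 2 * nsd)
}

#' Pairwise coactivity matrix with shuffle-null significance
#'
#' Computes the full symmetric coactivity matrix of a binarized activity
#' matrix, a per-pair circular-rotation shuffle null (see [shuffle_null()]),
#' the islet connectivity score `c_islet` (mean off-diagonal coactivity, by
#' default over all pairs; optionally over significant pairs only) and the
#' islet connectivity class: low (`c_islet <= 0.5`), medium
#' (`0.5 < c_islet <= 0.75`) or high (`c_islet > 0.75`). Healthy islets
#' typically score in the high band.
#'
#' @param binarized Cells x frames 0/1 matrix from [binarize()] (>= 2 cells).
#' @param n_shuffles Surrogates per pair (default 10,000).
#' @param seed Optional integer seed for the shuffle RNG; recorded in the
#'   result. `NULL` uses the current RNG state.
#' @param norm Coactivity normalization, see [coactivity_pair()].
#' @param c_islet_significant_only Average only significant pairs into
#'   `c_islet` (default `FALSE`: all off-diagonal pairs).
#' @return An object of class `coactivity_result`: list with matrices `C`,
#'   `significant`, `null_mean`, `null_sd`; `cell_ids`, `n_shuffles`,
#'   `rng_seed`, `c_islet`, `connectivity_class`, and per-cell `degree`
#'   (number of significant partners).
#' @export
coactivity_matrix <- function(binarized, n_shuffles = 10000, seed = NULL,
                              norm = c("sqrt", "printed"),
                              c_islet_significant_only = FALSE) {
  norm <- match.arg(norm)
  m <- nrow(binarized)
  if (is.null(m) || m < 2) abort("coactivity needs at least 2 cells")
  if (!is.numeric(n_shuffles) || n_shuffles < 1) {
    abort("n_shuffles must be >= 1")
  }
  ids <- rownames(binarized) %||% paste0("cell_", seq_len(m))
  A <- matrix(as.numeric(binarized), nrow = m)
  n <- ncol(A)
  Tact <- rowSums(A)
  Tij <- tcrossprod(A)
  den <- if (norm == "sqrt") sqrt(outer(Tact, Tact)) else outer(Tact, Tact)
  C <- ifelse(den > 0, Tij / den, 0)
  diag(C) <- 1

  run_null <- function() {
    Fr <- mvfft(t(A)) # columns = cells
    sig <- matrix(FALSE, m, m)
    nm <- nsd <- matrix(0, m, m)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (Tact[i] == 0 || Tact[j] == 0) next
        o <- pmax(round(Re(fft(Fr[, i] * Conj(Fr[, j]), inverse = TRUE)) / n), 0)
        nulls <- o[sample.int(n, n_shuffles, replace = TRUE)] / den[i, j]
        mu <- mean(nulls)
        s <- sd(nulls)
        if (is.na(s)) s <- 0
        nm[i, j] <- nm[j, i] <- mu
        nsd[i, j] <- nsd[j, i] <- s
        sig[i, j] <- sig[j, i] <- C[i, j] > mu + 2 * s
      }
    }
    list(sig = sig, nm = nm, nsd = nsd)
  }
  nl <- if (is.null(seed)) run_null() else withr::with_seed(seed, run_null())

  off <- upper.tri(C)
  c_islet <- if (c_islet_significant_only) {
    if (any(nl$sig[off])) mean(C[off][nl$sig[off]]) else 0
  } else {
    mean(C[off])
  }
  cls <- if (c_islet <= 0.5) "low" else if (c_islet <= 0.75) "medium" else "high"

  dimnames(C) <- dimnames(nl$sig) <- dimnames(nl$nm) <- dimnames(nl$nsd) <-
    list(ids, ids)
  structure(
    list(C = C, significant = nl$sig, null_mean = nl$nm, null_sd = nl$nsd,
         cell_ids = ids, n_shuffles = as.integer(n_shuffles),
         rng_seed = seed, norm = norm, c_islet = c_islet,
         connectivity_class = cls, degree = rowSums(nl$sig)),
    class = "coactivity_result"
  )
}

#' @export
print.coactivity_result <- function(x, ...) {
  cat(sprintf("<coactivity_result> %d cells, %d shuffles/pair\n",
              length(x$cell_ids), x$n_shuffles))
  cat(sprintf("  c_islet = %.3f (%s connectivity); %d of %d pairs significant\n",
              x$c_islet, x$connectivity_class,
              sum(x$significant[upper.tri(x$significant)]),
              choose(length(x$cell_ids), 2)))
  invisible(x)
}

#' Identify hub cells by the strong-connection criterion
#'
#' Flags cells for which at least `min_fraction` (default 80%) of their
#' significantly connected pairs have a coactivity coefficient of at least
#' `min_coactivity` (default 0.8). Cells with zero significant partners are
#' never hubs. Only significant partners enter the denominator.
#'
#' @param result A [coactivity_matrix()] result.
#' @param min_coactivity Strong-connection threshold (default 0.8,
#'   inclusive).
#' @param min_fraction Required fraction of strong partners (default 0.8,
#'   inclusive).
#' @return A tibble: `cell_id`, `n_significant`, `frac_strong`,
#'   `is_hub_criterion`.
#' @export
identify_hubs_criterion <- function(result, min_coactivity = 0.8,
                                    min_fraction = 0.8) {
  stopifnot(inherits(result, "coactivity_result"))
  m <- length(result$cell_ids)
  frac <- rep(NA_real_, m)
  hub <- rep(FALSE, m)
  for (i in seq_len(m)) {
    partners <- which(result$significant[i, ])
    if (!length(partners)) next
    frac[i] <- mean(result$C[i, partners] >= min_coactivity)
    hub[i] <- frac[i] >= min_fraction
  }
  tibble(cell_id = result$cell_ids,
         n_significant = as.integer(result$degree),
         frac_strong = frac, is_hub_criterion = hub)
}

#' Identify hub cells as the best-connected fraction
#'
#' Flags the top `fraction` (default 10%) of cells ranked by number of
#' significant connections; ties are broken by mean coactivity over
#' significant partners and then by cell order. Cells with zero significant
#' connections are never flagged, even if that leaves fewer than
#' `ceiling(fraction * n)` hubs.
#'
#' @param result A [coactivity_matrix()] result.
#' @param fraction Fraction of cells to flag (default 0.10).
#' @return A tibble: `cell_id`, `n_significant`, `mean_significant_coactivity`,
#'   `is_hub_top10`.
#' @export
identify_hubs_top10 <- function(result, fraction = 0.10) {
  stopifnot(inherits(result, "coactivity_result"))
  m <- length(result$cell_ids)
  deg <- result$degree
  mean_c <- vapply(seq_len(m), function(i) {
    partners <- which(result$significant[i, ])
    if (length(partners)) mean(result$C[i, partners]) else 0
  }, numeric(1))
  k <- max(1L, ceiling(fraction * m))
  ord <- order(-deg, -mean_c, seq_len(m))
  flag <- rep(FALSE, m)
  flag[head(ord, k)] <- TRUE
  flag[deg == 0] <- FALSE
  tibble(cell_id = result$cell_ids, n_significant = as.integer(deg),
         mean_significant_coactivity = mean_c, is_hub_top10 = flag)
}

#' Export the functional network as node and edge tables
#'
#' Builds a weighted edge list (one row per unordered cell pair, weight =
#' coactivity coefficient, with the significance flag) and a node table
#' placed at the cell centroids for topographic plotting. Cells without a
#' centroid are placed at the origin with a warning.
#'
#' @param result A [coactivity_matrix()] result.
#' @param centroids Optional tibble with `cell_id`, `x_px`, `y_px`.
#' @param significant_only Drop non-significant edges (default `FALSE`).
#' @return A list of tibbles: `nodes` (`cell_id`, `x_px`, `y_px`, `degree`)
#'   and `edges` (`source`, `target`, `weight`, `significant`).
#' @export
export_network <- function(result, centroids = NULL, significant_only = FALSE) {
  stopifnot(inherits(result, "coactivity_result"))
  ids <- result$cell_ids
  m <- length(ids)
  ut <- which(upper.tri(result$C), arr.ind = TRUE)
  edges <- tibble(
    source = ids[ut[, 1]],
    target = ids[ut[, 2]],
    weight = result$C[ut],
    significant = result$significant[ut]
  )
  if (significant_only) edges <- edges[edges$significant, , drop = FALSE]
  nodes <- tibble(cell_id = ids, x_px = 0, y_px = 0,
                  degree = as.integer(result$degree))
  if (!is.null(centroids)) {
    idx <- match(ids, centroids$cell_id)
    miss <- is.na(idx)
    if (any(miss)) {
      warn(sprintf("no centroid for %d cell(s) (%s ...): placed at the origin",
                   sum(miss), ids[which(miss)[1]]))
    }
    nodes$x_px <- ifelse(miss, 0, centroids$x_px[idx])
    nodes$y_px <- ifelse(miss, 0, centroids$y_px[idx])
  } else {
    warn("no centroids supplied: all nodes placed at the origin")
  }
  list(nodes = nodes, edges = edges)
}
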