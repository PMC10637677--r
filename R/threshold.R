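#' Threshold estimates
#'
#' A `threshold_estimate` records one candidate species-delimitation cutoff
#' plus the diagnostics that produced it: the kernel-density curve for the
#' local-minima method, or the full TP/FN/FP/TN error grid for the
#' cumulative-error optimiser. `value` is a proportion; `candidates` holds
#' every admissible threshold the method found (all density dips, or all
#' grid points attaining minimal cumulative error), in ascending order, with
#' `value` the smallest so pipelines stay deterministic while the full range
#' remains visible.
#'
#' @name threshold_estimate
NULL

new_threshold_estimate <- function(method, value, candidates, diagnostics,
                                   no_threshold = FALSE) {
  structure(list(method = method, value = value,
                 candidates = candidates, diagnostics = diagnostics,
                 no_threshold = no_threshold),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("threshold_estimate [%s]\n", x$method))
  if (x$no_threshold || is.na(x$value)) {
    cat("  no threshold found (degenerate or unimodal distance density)\n")
  } else {
    cat(sprintf("  value: %.5f (%.3f%%)\n", x$value, 100 * x$value))
    cat(sprintf("  candidates: %s\n",
                paste(sprintf("%.5f", x$candidates), collapse = ", ")))
  }
  invisible(x)
}

#' Threshold from local minima of the distance density
#'
#' Builds a Gaussian kernel density estimate of all unordered pairwise
#' distances and reports every interior strict local minimum of the curve as
#' a candidate threshold: a dip in the density marks the transition between
#' the intra- and interspecific distance modes, with no species labels
#' needed. A flat run of equal density values lower than both flanking
#' values — which arises when the density underflows across a wide gap —
#' counts as a single minimum at the run's midpoint. Bandwidth defaults to
#' Silverman's rule of thumb (`stats::bw.nrd0`), evaluated on `n_grid`
#' points spanning `[0, max distance]`.
#'
#' If the density has no interior minimum (unimodal, or all distances equal)
#' a no-threshold estimate is returned with `value = NA`.
#'
#' @param dist_matrix a `distance_matrix`, or directly a numeric vector of
#'   pairwise distances.
#' @param bw bandwidth specification passed to [stats::density()].
#' @param n_grid number of density evaluation points.
#' @return A [threshold_estimate] with method `"LOCAL_MINIMA"`; diagnostics
#'   hold the evaluation grid and density values.
#' @export
local_minima_threshold <- function(dist_matrix, bw = "nrd0", n_grid = 512L) {
  d <- if (is.numeric(dist_matrix)) dist_matrix[!is.na(dist_matrix)]
       else pairwise_values(dist_matrix)
  if (length(unique(d)) < 2L)
    return(new_threshold_estimate("LOCAL_MINIMA", NA_real_, numeric(0),
                                  list(grid = numeric(0), density = numeric(0),
                                       reason = "degenerate distances"),
                                  no_threshold = TRUE))
  dens <- stats::density(d, bw = bw, kernel = "gaussian", n = n_grid,
                         from = 0, to = max(d))
  # run-length compress equal density values first: in a wide gap the KDE
  # underflows to a flat run, and a strict pointwise test would miss the dip;
  # an interior run lower than both flanking runs is one minimum, located at
  # the run's midpoint
  r <- rle(dens$y)
  k <- length(r$values)
  cand <- numeric(0)
  if (k >= 3L) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    j <- 2:(k - 1L)
    is_min <- r$values[j - 1L] > r$values[j] & r$values[j] < r$values[j + 1L]
    cand <- vapply(j[is_min], function(jj)
      (dens$x[starts[jj]] + dens$x[ends[jj]]) / 2, numeric(1))
  }
  diag <- list(grid = dens$x, density = dens$y, bw = dens$bw)
  if (!length(cand))
    return(new_threshold_estimate("LOCAL_MINIMA", NA_real_, numeric(0),
                                  c(diag, reason = "unimodal density"),
                                  no_threshold = TRUE))
  new_threshold_estimate("LOCAL_MINIMA", min(cand), sort(cand), diag)
}

#' Identification outcome counts at a fixed threshold
#'
#' For each query, every other sequence within distance `<= t` is examined:
#' no neighbour within `t` gives `no_id`; all conspecific gives `correct`;
#' all heterospecific gives `incorrect`; a mix gives `ambiguous`. The counts
#' map onto the confusion totals as TP = correct, FN = no_id,
#' FP = incorrect + ambiguous, and TN = n - TP - FN - FP; cumulative error is
#' FN + FP, the quantity the grid optimiser minimises. Undefined (`NA`)
#' distances are treated as beyond any threshold.
#'
#' @param dist_matrix a `distance_matrix`.
#' @param labels species labels, parallel to `dist_matrix$ids`.
#' @param t distance threshold (proportion, `>= 0`); a distance exactly
#'   equal to `t` counts as within the threshold.
#' @return list with `status` (factor per sequence), `counts`
#'   (TP/FN/FP/TN), and `cumulative_error`.
#' @export
threshold_id <- function(dist_matrix, labels, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    bg_stop("bg_domain_error", "threshold t must be a single number >= 0")
  labels <- as.character(labels)
  n <- length(dist_matrix$ids)
  if (length(labels) != n)
    bg_stop("bg_shape_error", "labels must match distance matrix ids")
  status <- character(n)
  for (q in seq_len(n)) {
    v <- dist_matrix$values[q, ]
    v[q] <- NA_real_
    within <- which(!is.na(v) & v <= t)
    status[q] <- if (!length(within)) "no_id" else {
      con <- labels[within] == labels[q]
      if (all(con)) "correct" else if (!any(con)) "incorrect" else "ambiguous"
    }
  }
  status <- factor(status, levels = STATUS_LEVELS)
  cnt <- table(status)
  counts <- c(TP = unname(cnt["correct"]), FN = unname(cnt["no_id"]),
              FP = unname(cnt["incorrect"] + cnt["ambiguous"]))
  counts <- c(counts, TN = n - sum(counts))
  list(status = status, counts = counts,
       cumulative_error = unname(counts["FN"] + counts["FP"]))
}

STATUS_LEVELS <- c("correct", "incorrect", "ambiguous", "no_id")

#' Threshold by cumulative-error minimisation over a grid
#'
#' Evaluates [threshold_id()] at every grid point and selects the thresholds
#' with minimal cumulative error (false negatives + false positives). All
#' minimising grid points are kept as candidates — optimal thresholds often
#' form a plateau — and the smallest is reported as `value`. The default
#' grid runs from 0.1% to 2% in 0.1% increments.
#'
#' @inheritParams threshold_id
#' @param grid strictly increasing vector of candidate thresholds
#'   (proportions).
#' @return A [threshold_estimate] with method `"THRESH_OPT"`; diagnostics
#'   hold the full per-threshold TP/FN/FP/TN/error table.
#' @export
optimize_threshold <- function(dist_matrix, labels,
                               grid = seq(0.001, 0.020, by = 0.001)) {
  if (!length(grid) || any(diff(grid) <= 0) || any(grid < 0))
    bg_stop("bg_domain_error",
            "grid must be a non-empty strictly increasing vector of proportions >= 0")
  rows <- lapply(grid, function(t) {
    r <- threshold_id(dist_matrix, labels, t)
    data.frame(threshold = t, TP = r$counts[["TP"]], FN = r$counts[["FN"]],
               FP = r$counts[["FP"]], TN = r$counts[["TN"]],
               cumulative_error = r$cumulative_error)
  })
  tab <- do.call(rbind, rows)
  best <- tab$cumulative_error == min(tab$cumulative_error)
  cand <- tab$threshold[best]
  new_threshold_estimate("THRESH_OPT", min(cand), cand, list(error_grid = tab))
}

#' Threshold from the 95% intraspecific-distance rule
#'
#' Collects all intraspecific pairwise distances and returns the smallest
#' observed value below-or-at which at least `coverage` of them fall — the
#' classic "95% rule" for setting a barcode cutoff from the intraspecific
#' distance distribution alone.
#'
#' @inheritParams threshold_id
#' @param coverage required fraction of intraspecific distances at or below
#'   the returned value (default 0.95).
#' @return A [threshold_estimate] with method `"PERCENTILE_95"`; diagnostics
#'   hold the sorted intraspecific distances and the coverage used.
#' @export
percentile_threshold <- function(dist_matrix, labels, coverage = 0.95) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1)
    bg_stop("bg_domain_error", "coverage must be in (0, 1]")
  labels <- as.character(labels)
  d <- intra_distances(dist_matrix, labels)
  if (!length(d))
    bg_stop("bg_no_intraspecific",
            "no intraspecific pairs: every species is a singleton")
  uv <- sort(unique(d))
  frac <- vapply(uv, function(v) mean(d <= v), numeric(1))
  value <- uv[which(frac >= coverage)[1L]]
  new_threshold_estimate("PERCENTILE_95", value, value,
                         list(intraspecific = sort(d), coverage = coverage))
}

# all defined intraspecific pairwise distances (lower triangle)
intra_distances <- function(dm, labels) {
  same <- outer(labels, labels, "==")
  d <- dm$values[lower.tri(dm$values) & same]
  d[!is.na(d)]
}

inter_distances <- function(dm, labels) {
  same <- outer(labels, labels, "==")
  d <- dm$values[lower.tri(dm$values) & !same]
  d[!is.na(d)]
}

#' Export threshold diagnostics
#'
#' Writes the density curve (local-minima method) or the error grid
#' (cumulative-error method) as TSV for external plotting.
#' @param est a [threshold_estimate].
#' @param path output file path.
#' @return Invisibly, `est`.
#' @export
write_threshold_diagnostics <- function(est, path) {
  tab <- switch(est$method,
    LOCAL_MINIMA = data.frame(distance = est$diagnostics$grid,
                              density = est$diagnostics$density),
    THRESH_OPT = est$diagnostics$error_grid,
    PERCENTILE_95 = data.frame(
      intraspecific_distance = est$diagnostics$intraspecific),
    bg_stop("bg_domain_error", "unknown threshold method"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(est)
}
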