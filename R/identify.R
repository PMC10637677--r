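#' Best-close-match identification
#'
#' Classifies every sequence against the rest of the dataset at a distance
#' threshold `t`. For a query `q`, let `m` be the distance to its nearest
#' neighbour (self-matches always excluded). If `m > t` the query is
#' `no_id`. Otherwise the species of all sequences within `tie_tol` of `m`
#' are collected: more than one species is `ambiguous`; exactly the query's
#' own species is `correct`; any other single species is `incorrect`.
#'
#' `strict_ambiguity = TRUE` switches to the stricter reading under which a
#' query is `ambiguous` whenever more than one species occurs anywhere
#' within the threshold, not just among nearest-neighbour ties. This makes
#' generous thresholds degenerate (at large `t` almost everything is within
#' range), so it is off by default; it is provided because both readings of
#' the method circulate.
#'
#' Undefined (`NA`) distances are treated as beyond any threshold.
#'
#' @param dist_matrix a `distance_matrix`.
#' @param labels species labels parallel to `dist_matrix$ids`; no species
#'   may be a singleton (filter upstream with [apply_filter()]).
#' @param t distance threshold (proportion, `>= 0`).
#' @param tie_tol tolerance within which distances to the nearest neighbour
#'   count as tied (default `1e-12`, i.e. exact ties up to floating point).
#' @param strict_ambiguity see Details.
#' @return An `identification_report`: `per_sequence` data.frame (id,
#'   species, status, nn_distance, nn_species), `counts` and `proportions`
#'   per status, `per_species` status counts, and the `threshold` used.
#' @examples
#' aln <- labeled_alignment(paste0("s", 1:4),
#'                          c("AAAA", "AAAA", "TTTT", "TTTT"),
#'                          c("X", "X", "Y", "Y"))
#' dm <- pairwise_distance_matrix(aln, "P_DIST")
#' best_close_match(dm, aln$labels, t = 0.05)
#' @export
best_close_match <- function(dist_matrix, labels, t, tie_tol = 1e-12,
                             strict_ambiguity = FALSE) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    bg_stop("bg_domain_error", "threshold t must be a single number >= 0")
  if (tie_tol < 0)
    bg_stop("bg_domain_error", "tie_tol must be >= 0")
  labels <- as.character(labels)
  n <- length(dist_matrix$ids)
  if (n < 2L)
    bg_stop("bg_empty_input", "need at least 2 sequences")
  if (length(labels) != n)
    bg_stop("bg_shape_error", "labels must match distance matrix ids")

  status <- character(n)
  nn_dist <- numeric(n)
  nn_species <- character(n)
  for (q in seq_len(n)) {
    v <- dist_matrix$values[q, ]
    v[q] <- NA_real_
    if (all(is.na(v))) {          # every pair undefined: nothing comparable
      status[q] <- "no_id"; nn_dist[q] <- NA_real_; nn_species[q] <- ""
      next
    }
    m <- min(v, na.rm = TRUE)
    nn_dist[q] <- m
    if (m > t) {
      status[q] <- "no_id"
      nn_species[q] <- paste(sort(unique(
        labels[which(!is.na(v) & v <= m + tie_tol)])), collapse = ";")
      next
    }
    sp <- if (strict_ambiguity) {
      unique(labels[which(!is.na(v) & v <= t)])
    } else {
      unique(labels[which(!is.na(v) & v <= m + tie_tol)])
    }
    nn_species[q] <- paste(sort(unique(
      labels[which(!is.na(v) & v <= m + tie_tol)])), collapse = ";")
    status[q] <- if (length(sp) > 1L) "ambiguous"
      else if (identical(sp, labels[q])) "correct" else "incorrect"
  }
  status <- factor(status, levels = STATUS_LEVELS)
  per_sequence <- data.frame(
    id = dist_matrix$ids, species = labels, status = as.character(status),
    nn_distance = nn_dist, nn_species = nn_species, stringsAsFactors = FALSE)
  counts <- as.integer(table(status))
  names(counts) <- STATUS_LEVELS
  per_species <- as.data.frame.matrix(table(labels, status))
  per_species <- cbind(species = rownames(per_species),
                       n = as.integer(rowSums(per_species)), per_species)
  rownames(per_species) <- NULL
  structure(list(per_sequence = per_sequence, counts = counts,
                 proportions = counts / n, threshold = t,
                 tie_tol = tie_tol, strict_ambiguity = strict_ambiguity,
                 per_species = per_species),
            class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  n <- sum(x$counts)
  cat(sprintf("best-close-match identification at t = %.5f (%.3f%%), n = %d\n",
              x$threshold, 100 * x$threshold, n))
  for (s in STATUS_LEVELS)
    cat(sprintf("  %-9s %4d (%.2f)\n", s, x$counts[[s]], x$proportions[[s]]))
  invisible(x)
}

#' Summarise one or two identification reports
#'
#' Rolls an [best_close_match()] report up to per-species and overall
#' percentages. When a second report (the same data identified at another
#' threshold) is supplied, each cell is formatted `"a/b"` — the percent
#' under the first and second thresholds — the layout used when comparing a
#' grid-optimised threshold against a percentile-rule threshold.
#'
#' @param report an `identification_report`.
#' @param other optional second `identification_report` on the same
#'   sequences.
#' @param digits rounding for percentages (default 0).
#' @return data.frame with one row per species plus an `ALL` row; columns
#'   `species`, `n`, and the four statuses as percent (numeric, or `"a/b"`
#'   character when `other` is given).
#' @export
summarize_identifications <- function(report, other = NULL, digits = 0) {
  stopifnot(inherits(report, "identification_report"))
  pct <- function(rep) {
    ps <- rep$per_species
    m <- as.matrix(ps[, STATUS_LEVELS])
    m <- 100 * m / ps$n
    all_row <- 100 * rep$counts / sum(rep$counts)
    rbind(m, ALL = all_row)
  }
  a <- pct(report)
  base <- data.frame(
    species = c(report$per_species$species, "ALL"),
    n = c(report$per_species$n, sum(report$counts)),
    stringsAsFactors = FALSE)
  if (is.null(other)) {
    out <- cbind(base, round(as.data.frame(a), digits))
  } else {
    stopifnot(inherits(other, "identification_report"))
    if (!identical(report$per_sequence$id, other$per_sequence$id))
      bg_stop("bg_shape_error", "reports cover different sequence sets")
    b <- pct(other)
    paired <- as.data.frame(matrix(
      paste0(round(a, digits), "/", round(b, digits)),
      nrow = nrow(a), dimnames = dimnames(a)), stringsAsFactors = FALSE)
    out <- cbind(base, paired)
  }
  rownames(out) <- NULL
  out
}

#' Write per-sequence identification results as TSV
#' @param report an `identification_report`.
#' @param path output file path.
#' @return Invisibly, `report`.
#' @export
write_identification <- function(report, path) {
  utils::write.table(report$per_sequence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}
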