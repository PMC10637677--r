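#' Per-sequence barcoding-gap extremes
#'
#' For every sequence belonging to a species with at least two members:
#' the maximum distance to a conspecific and the minimum distance to a
#' heterospecific. These are the per-sequence quantities whose two
#' distributions form (or fail to form) the barcoding gap.
#'
#' @param dist_matrix a `distance_matrix`.
#' @param labels species labels parallel to `dist_matrix$ids`.
#' @return data.frame (id, species, max_intra, min_inter); rows only for
#'   species with `>= 2` members.
#' @export
per_sequence_extremes <- function(dist_matrix, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    bg_stop("bg_single_species",
            "need at least 2 species for interspecific distances")
  tab <- table(labels)
  rows <- lapply(seq_along(labels), function(q) {
    if (tab[[labels[q]]] < 2L) return(NULL)
    v <- dist_matrix$values[q, ]
    v[q] <- NA_real_
    con <- labels == labels[q]
    data.frame(id = dist_matrix$ids[q], species = labels[q],
               max_intra = suppressWarnings(max(v[con], na.rm = TRUE)),
               min_inter = suppressWarnings(min(v[!con], na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$max_intra[!is.finite(out$max_intra)] <- NA_real_
  out$min_inter[!is.finite(out$min_inter)] <- NA_real_
  out
}

#' Per-species intra-/interspecific distance table
#'
#' For each species: mean and range of its intraspecific pairwise distances,
#' and mean and range of the distances from its members to all
#' heterospecifics pooled (one interspecific column per species, not a
#' species-pair matrix). Species with a single member get `NA` intraspecific
#' statistics.
#'
#' @inheritParams per_sequence_extremes
#' @return data.frame (species, n, mean_intra, min_intra, max_intra,
#'   mean_inter, min_inter, max_inter).
#' @export
species_distance_table <- function(dist_matrix, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    bg_stop("bg_single_species",
            "need at least 2 species for interspecific distances")
  sp <- sort(unique(labels))
  rows <- lapply(sp, function(s) {
    idx <- which(labels == s)
    intra <- dist_matrix$values[idx, idx, drop = FALSE]
    intra <- intra[lower.tri(intra)]
    intra <- intra[!is.na(intra)]
    inter <- dist_matrix$values[idx, -idx, drop = FALSE]
    inter <- inter[!is.na(inter)]
    data.frame(
      species = s, n = length(idx),
      mean_intra = if (length(intra)) mean(intra) else NA_real_,
      min_intra = if (length(intra)) min(intra) else NA_real_,
      max_intra = if (length(intra)) max(intra) else NA_real_,
      mean_inter = if (length(inter)) mean(inter) else NA_real_,
      min_inter = if (length(inter)) min(inter) else NA_real_,
      max_inter = if (length(inter)) max(inter) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full barcoding-gap table
#'
#' Combines [per_sequence_extremes()], [species_distance_table()] and the
#' overall mean +/- SD (sample SD, n-1 denominator) of the per-sequence
#' maximum-intraspecific and minimum-interspecific columns.
#'
#' @inheritParams per_sequence_extremes
#' @return A `gap_table` with fields `per_sequence`, `per_species`,
#'   `overall`.
#' @export
gap_table <- function(dist_matrix, labels) {
  ps <- per_sequence_extremes(dist_matrix, labels)
  overall <- list(
    mean_max_intra = mean(ps$max_intra, na.rm = TRUE),
    sd_max_intra = stats::sd(ps$max_intra, na.rm = TRUE),
    mean_min_inter = mean(ps$min_inter, na.rm = TRUE),
    sd_min_inter = stats::sd(ps$min_inter, na.rm = TRUE))
  structure(list(per_sequence = ps,
                 per_species = species_distance_table(dist_matrix, labels),
                 overall = overall),
            class = "gap_table")
}

#' @export
print.gap_table <- function(x, ...) {
  o <- x$overall
  cat(sprintf("gap_table: %d sequences, %d species\n",
              nrow(x$per_sequence), nrow(x$per_species)))
  cat(sprintf("  max intra: mean +/- SD = %.2f%% +/- %.2f%%\n",
              100 * o$mean_max_intra, 100 * o$sd_max_intra))
  cat(sprintf("  min inter: mean +/- SD = %.2f%% +/- %.2f%%\n",
              100 * o$mean_min_inter, 100 * o$sd_min_inter))
  g <- gap_exists(x)
  cat(if (g$gap) sprintf("  barcoding gap present: (%.4f, %.4f)\n",
                         g$interval[1], g$interval[2])
      else "  no barcoding gap (intra/inter distances overlap)\n")
  invisible(x)
}

#' Does a global barcoding gap exist?
#'
#' TRUE iff the largest intraspecific distance is strictly below the
#' smallest interspecific distance; the open interval between them is then
#' the gap — any threshold inside it separates conspecific from
#' heterospecific pairs perfectly.
#'
#' @param gt a [gap_table].
#' @return list with `gap` (logical) and `interval` (`c(max_intra,
#'   min_inter)` when the gap exists, otherwise `NULL`).
#' @export
gap_exists <- function(gt) {
  stopifnot(inherits(gt, "gap_table"))
  hi_intra <- suppressWarnings(max(gt$per_sequence$max_intra, na.rm = TRUE))
  lo_inter <- suppressWarnings(min(gt$per_sequence$min_inter, na.rm = TRUE))
  if (!is.finite(hi_intra) || !is.finite(lo_inter))
    return(list(gap = FALSE, interval = NULL))
  if (hi_intra < lo_inter)
    list(gap = TRUE, interval = c(hi_intra, lo_inter))
  else list(gap = FALSE, interval = NULL)
}

#' Export gap tables
#'
#' `write_species_distance_table()` writes the per-species table;
#' `write_gap_long()` writes the per-sequence extremes in long format
#' (sequence, type in \{max_intra, min_inter\}, value) ready for boxplots.
#'
#' @param gt a [gap_table].
#' @param path output file path.
#' @return Invisibly, `gt`.
#' @export
write_species_distance_table <- function(gt, path) {
  utils::write.table(gt$per_species, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(gt)
}

#' @rdname write_species_distance_table
#' @export
write_gap_long <- function(gt, path) {
  ps <- gt$per_sequence
  long <- rbind(
    data.frame(id = ps$id, species = ps$species, type = "max_intra",
               value = ps$max_intra, stringsAsFactors = FALSE),
    data.frame(id = ps$id, species = ps$species, type = "min_inter",
               value = ps$min_inter, stringsAsFactors = FALSE))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gt)
}
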