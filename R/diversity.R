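#' Haplotype count and haplotype diversity
#'
#' Haplotypes are equivalence classes of sequences under exact match over
#' the columns free of `N`/`-` in *all* sequences (complete deletion), the
#' convention of standard population-genetics software; an `N` is never
#' allowed to bridge two haplotypes. Haplotype diversity uses the
#' sample-size-corrected estimator
#' \deqn{H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' with \eqn{p_i} the haplotype relative frequencies; it is the probability
#' that two randomly drawn sequences carry different haplotypes.
#'
#' @param aln a [labeled_alignment] with `n >= 2`.
#' @return list with `n_haplotypes` and `haplotype_diversity`.
#' @examples
#' aln <- labeled_alignment(paste0("s", 1:5),
#'                          c("AAAA", "AAAA", "AAAA", "AAAT", "AATT"),
#'                          rep("X", 5))
#' haplotype_summary(aln)  # counts {3,1,1}: Hd = (5/4) * (1 - 0.44) = 0.70
#' @export
haplotype_summary <- function(aln) {
  n <- attr(aln, "n")
  if (n < 2L) bg_stop("bg_empty_input", "need at least 2 sequences")
  m <- aln_matrix(aln)
  usable <- colSums(m == "N" | m == "-") == 0L
  if (!any(usable))
    bg_stop("bg_no_usable_columns",
            "every column contains N or - in some sequence; haplotypes undefined")
  key <- apply(m[, usable, drop = FALSE], 1L, paste, collapse = "")
  counts <- as.integer(table(key))
  # integer form (n^2 - sum c_i^2) / (n (n-1)) keeps Hd exact at the extremes
  hd <- (n^2 - sum(counts^2)) / (n * (n - 1))
  list(n_haplotypes = length(counts), haplotype_diversity = hd)
}

#' Nucleotide diversity
#'
#' \eqn{\pi}: the mean proportion of differing sites over all unordered
#' sequence pairs, each pair compared under pairwise deletion. This is the
#' per-site expected difference between two randomly drawn sequences.
#'
#' @param aln a [labeled_alignment] with `n >= 2`.
#' @return `pi` as a proportion in `[0, 1]`.
#' @export
nucleotide_diversity <- function(aln) {
  n <- attr(aln, "n")
  if (n < 2L) bg_stop("bg_empty_input", "need at least 2 sequences")
  enc <- lapply(aln$seqs, encode_seq)
  total <- 0
  npairs <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pc <- pair_counts(enc[[i]], enc[[j]])
    if (pc$nc == 0L)
      bg_stop("bg_undefined_diversity", sprintf(
        "pair (%s, %s) has no comparable sites", aln$ids[i], aln$ids[j]))
    total <- total + (pc$ts + pc$tv) / pc$nc
    npairs <- npairs + 1L
  }
  total / npairs
}

#' Segregating (polymorphic) sites
#'
#' Counts alignment columns where at least two distinct unambiguous bases
#' (`A`, `C`, `G`, `T`) occur; `N` and `-` are ignored within a column, so a
#' column whose only variation involves missing data is not polymorphic.
#'
#' @param aln a [labeled_alignment] with `n >= 2`.
#' @return integer count `S`, `0 <= S <= L`.
#' @export
segregating_sites <- function(aln) {
  n <- attr(aln, "n")
  if (n < 2L) bg_stop("bg_empty_input", "need at least 2 sequences")
  m <- aln_matrix(aln)
  sum(apply(m, 2L, function(col) {
    length(unique(col[col %in% BASES])) >= 2L
  }))
}

#' Molecular-diversity summary for one alignment
#'
#' Bundles the haplotype count, haplotype diversity, segregating sites and
#' nucleotide diversity for a locus (the numbers a barcoding study reports
#' in one breath).
#'
#' @param aln a [labeled_alignment] with `n >= 2`.
#' @return A `diversity_summary`: `n`, `L`, `n_haplotypes`,
#'   `haplotype_diversity`, `segregating_sites`, `nucleotide_diversity`.
#' @export
diversity_summary <- function(aln) {
  hap <- haplotype_summary(aln)
  structure(list(
    n = attr(aln, "n"), L = attr(aln, "L"), locus = aln$locus,
    n_haplotypes = hap$n_haplotypes,
    haplotype_diversity = hap$haplotype_diversity,
    segregating_sites = segregating_sites(aln),
    nucleotide_diversity = nucleotide_diversity(aln)),
    class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("diversity_summary (%s): n = %d, L = %d\n", x$locus, x$n, x$L))
  cat(sprintf("  haplotypes: %d, Hd = %.3f\n",
              x$n_haplotypes, x$haplotype_diversity))
  cat(sprintf("  segregating sites: %d, pi = %.4f\n",
              x$segregating_sites, x$nucleotide_diversity))
  invisible(x)
}
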