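#' Labelled sequence alignments
#'
#' A `labeled_alignment` is the pipeline's universal input: a set of
#' pre-aligned nucleotide sequences of identical length, each carrying a
#' unique id and a species label. The reserved labels `"OUTGROUP"` and
#' `"UNIDENTIFIED"` (case-insensitive on input) mark sequences that the
#' gap-analysis filter can drop.
#'
#' Sequences are normalised on construction: uppercased, `U` mapped to `T`,
#' and any IUPAC ambiguity code other than `N` mapped to `N`, so that the
#' working alphabet is exactly `{A, C, G, T, N, -}`.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of aligned sequences, all the same length.
#' @param labels character vector of species names (or reserved tokens),
#'   parallel to `ids`.
#' @param locus free-text locus tag, e.g. `"COI"` or `"ITS2"`.
#' @return An object of class `labeled_alignment` with fields `ids`, `seqs`,
#'   `labels`, `locus`, and attributes `n` (sequences) and `L` (columns).
#' @examples
#' aln <- labeled_alignment(c("s1", "s2"), c("ACGT", "ACGA"), c("A", "A"))
#' aln
#' @export
labeled_alignment <- function(ids, seqs, labels, locus = "unknown") {
  ids <- as.character(ids)
  seqs <- normalize_seqs(as.character(seqs))
  labels <- normalize_labels(as.character(labels))
  if (length(ids) != length(seqs) || length(ids) != length(labels))
    bg_stop("bg_shape_error", "ids, seqs and labels must have equal length")
  if (anyDuplicated(ids))
    bg_stop("bg_duplicate_ids", paste0(
      "duplicate sequence ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  lens <- nchar(seqs)
  if (length(seqs) == 0L || lens[1] == 0L)
    bg_stop("bg_empty_alignment", "alignment must contain sequences of length > 0")
  if (length(unique(lens)) != 1L)
    bg_stop("bg_alignment_length", paste0(
      "sequences are not aligned to equal length; offending ids: ",
      paste(ids[lens != stats::median(lens)], collapse = ", ")))
  structure(
    list(ids = ids, seqs = seqs, labels = labels, locus = locus),
    n = length(ids), L = lens[1],
    class = "labeled_alignment"
  )
}

RESERVED_LABELS <- c("OUTGROUP", "UNIDENTIFIED")

normalize_labels <- function(labels) {
  up <- toupper(trimws(labels))
  ifelse(up %in% RESERVED_LABELS, up, trimws(labels))
}

normalize_seqs <- function(seqs) {
  s <- toupper(seqs)
  s <- chartr("U", "T", s)
  # IUPAC ambiguity codes (and anything else unexpected) collapse to N
  gsub("[^ACGTN-]", "N", s)
}

#' @export
print.labeled_alignment <- function(x, ...) {
  sp <- species_counts(x)
  cat(sprintf("labeled_alignment: %d sequences x %d columns (locus %s)\n",
              attr(x, "n"), attr(x, "L"), x$locus))
  cat(sprintf("  species: %d (+%d outgroup, %d unidentified)\n",
              length(sp),
              sum(x$labels == "OUTGROUP"), sum(x$labels == "UNIDENTIFIED")))
  invisible(x)
}

#' Number of sequences / alignment columns
#' @param aln a `labeled_alignment`.
#' @return integer count.
#' @export
n_sequences <- function(aln) attr(aln, "n")

#' @rdname n_sequences
#' @export
n_columns <- function(aln) attr(aln, "L")

# counts per proper species label (reserved tokens excluded)
species_counts <- function(aln) {
  tab <- table(aln$labels[!(aln$labels %in% RESERVED_LABELS)])
  tab[order(names(tab))]
}

# n x L character matrix view of the alignment
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = attr(aln, "n"), byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

#' Read an aligned FASTA file with a species-label table
#'
#' The FASTA must contain pre-aligned sequences of identical length. The
#' label table is a two-column tab-separated file with header `id<TAB>species`;
#' every FASTA record id must appear exactly once. The species column may use
#' the reserved tokens `OUTGROUP` / `UNIDENTIFIED` (case-insensitive).
#'
#' @param fasta_path path to the aligned FASTA file.
#' @param labels_path path to the tab-separated label table.
#' @param locus locus tag stored on the alignment.
#' @return A [labeled_alignment].
#' @seealso [write_labeled_fasta()] for the inverse.
#' @export
read_labeled_fasta <- function(fasta_path, labels_path, locus = "unknown") {
  dna <- Biostrings::readBStringSet(fasta_path)
  if (length(dna) == 0L)
    bg_stop("bg_empty_alignment", sprintf("no FASTA records in '%s'", fasta_path))
  # FASTA headers may carry descriptions after the id proper
  ids <- sub("\\s.*$", "", names(dna))
  lens <- Biostrings::width(dna)
  if (length(unique(lens)) != 1L)
    bg_stop("bg_alignment_length", paste0(
      "FASTA records are not aligned to equal length; offending ids: ",
      paste(ids[lens != stats::median(lens)], collapse = ", ")))
  seqs <- as.character(dna)

  lab <- utils::read.delim(labels_path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           strip.white = TRUE)
  if (!all(c("id", "species") %in% names(lab)))
    bg_stop("bg_label_table", sprintf(
      "label table '%s' must have header columns 'id' and 'species'", labels_path))
  missing <- setdiff(ids, lab$id)
  if (length(missing))
    bg_stop("bg_missing_label", paste0(
      "FASTA ids missing from label table: ", paste(missing, collapse = ", ")))
  labels <- lab$species[match(ids, lab$id)]
  labeled_alignment(ids, seqs, labels, locus = locus)
}

#' Write an alignment back to FASTA + label TSV
#'
#' Emits the normalised sequences in input order; round-trips through
#' [read_labeled_fasta()] field-for-field.
#'
#' @param aln a [labeled_alignment].
#' @param fasta_path,labels_path output file paths.
#' @return Invisibly, `aln`.
#' @export
write_labeled_fasta <- function(aln, fasta_path, labels_path) {
  con <- file(fasta_path, open = "wt")
  on.exit(close(con))
  writeLines(paste0(">", aln$ids, "\n", aln$seqs), con, sep = "\n")
  utils::write.table(
    data.frame(id = aln$ids, species = aln$labels, stringsAsFactors = FALSE),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(aln)
}

#' Trim an alignment to a column window
#'
#' Columns are 1-based and inclusive, the way alignment positions are cited
#' (e.g. restricting a COI alignment to its 632 bp working window).
#'
#' @param aln a [labeled_alignment].
#' @param start_col,end_col first and last column to keep, `1 <= start_col <=
#'   end_col <= L`.
#' @return The trimmed [labeled_alignment].
#' @export
trim_alignment <- function(aln, start_col, end_col) {
  L <- attr(aln, "L")
  if (!(start_col >= 1 && start_col <= end_col && end_col <= L))
    bg_stop("bg_bounds_error", sprintf(
      "invalid trim window [%s, %s] for alignment of %d columns",
      start_col, end_col, L))
  labeled_alignment(aln$ids, substr(aln$seqs, start_col, end_col),
                    aln$labels, locus = aln$locus)
}

#' Exclusion filter applied before gap analysis
#'
#' `filter_policy()` bundles the three independent switches; `apply_filter()`
#' drops unidentified sequences and outgroups first and only then decides
#' which species are singletons (a species left with exactly one sequence),
#' since a singleton has no intraspecific distances and is meaningless in a
#' barcoding-gap analysis.
#'
#' @param drop_unidentified,drop_outgroups,drop_singletons logical switches.
#' @return `filter_policy()`: a `filter_policy` object. `apply_filter()`: the
#'   filtered [labeled_alignment], input order preserved, with attribute
#'   `"excluded"` — a data.frame itemising every dropped id and the reason.
#' @examples
#' aln <- labeled_alignment(paste0("s", 1:4), rep("ACGT", 4),
#'                          c("A", "A", "B", "outgroup"))
#' apply_filter(aln)  # keeps the two A sequences; B is a singleton
#' @export
filter_policy <- function(drop_unidentified = TRUE, drop_outgroups = TRUE,
                          drop_singletons = TRUE) {
  structure(list(drop_unidentified = isTRUE(drop_unidentified),
                 drop_outgroups = isTRUE(drop_outgroups),
                 drop_singletons = isTRUE(drop_singletons)),
            class = "filter_policy")
}

#' @rdname filter_policy
#' @param aln a [labeled_alignment].
#' @param policy a `filter_policy`.
#' @export
apply_filter <- function(aln, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  reason <- rep(NA_character_, attr(aln, "n"))
  if (policy$drop_unidentified)
    reason[aln$labels == "UNIDENTIFIED"] <- "unidentified"
  if (policy$drop_outgroups)
    reason[aln$labels == "OUTGROUP"] <- "outgroup"
  keep1 <- is.na(reason)
  if (policy$drop_singletons) {
    tab <- table(aln$labels[keep1])
    singletons <- names(tab)[tab == 1L]
    is_singleton <- keep1 & aln$labels %in% singletons &
      !(aln$labels %in% RESERVED_LABELS)
    reason[is_singleton] <- "singleton"
  }
  keep <- is.na(reason)
  if (!any(keep))
    bg_stop("bg_empty_dataset", "filter removed every sequence")
  out <- labeled_alignment(aln$ids[keep], aln$seqs[keep], aln$labels[keep],
                           locus = aln$locus)
  attr(out, "excluded") <- data.frame(
    id = aln$ids[!keep], species = aln$labels[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE)
  out
}
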