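#' Pairwise genetic distances
#'
#' Distances are computed with pairwise deletion: for each pair of sequences,
#' only columns where both carry an unambiguous base (`A`, `C`, `G`, `T`)
#' are compared; columns with `N` or `-` in either sequence are dropped for
#' that pair only. Distances are proportions (substitutions/site); reporting
#' layers convert to percent.
#'
#' The Kimura 2-parameter distance distinguishes transitions (A<->G, C<->T)
#' from transversions:
#' \deqn{d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q)}
#' where `P` and `Q` are the transition- and transversion-difference
#' proportions among comparable sites. When a log argument is non-positive
#' the pair is saturated and a classed error (`bg_saturation`) carrying `P`
#' and `Q` is raised; a pair with no comparable sites raises
#' `bg_no_comparable_sites`.
#'
#' @param seqA,seqB aligned nucleotide strings of equal length.
#' @return `k2p_distance()` / `p_distance()`: a single non-negative
#'   proportion with attribute `"comparable_sites"`.
#' @examples
#' k2p_distance("AAAAAAAAAAAAAAAAAAAA", "GGAAAAAAAAAAAAAAAAAC")  # P=0.1, Q=0.05
#' @name distances
NULL

BASES <- c("A", "C", "G", "T")
IS_PURINE <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)

# integer-encode one sequence string: 1..4 for ACGT, NA for N/-
encode_seq <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], BASES)
  v
}

# site-category counts for a pair of encoded sequences
pair_counts <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  nc <- sum(ok)
  if (nc == 0L) return(list(nc = 0L, ts = 0L, tv = 0L))
  da <- a[ok]; db <- b[ok]
  diff <- da != db
  # transition iff both purines or both pyrimidines (and different)
  pur <- c(TRUE, FALSE, TRUE, FALSE)
  ts <- sum(diff & (pur[da] == pur[db]))
  list(nc = nc, ts = ts, tv = sum(diff) - ts)
}

k2p_from_PQ <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    bg_stop("bg_saturation",
            sprintf("K2P saturated (P=%.4g, Q=%.4g): log argument <= 0", P, Q),
            P = P, Q = Q)
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' @rdname distances
#' @export
k2p_distance <- function(seqA, seqB) {
  pc <- pair_prep(seqA, seqB)
  P <- pc$ts / pc$nc
  Q <- pc$tv / pc$nc
  structure(k2p_from_PQ(P, Q), comparable_sites = pc$nc)
}

#' @rdname distances
#' @export
p_distance <- function(seqA, seqB) {
  pc <- pair_prep(seqA, seqB)
  structure((pc$ts + pc$tv) / pc$nc, comparable_sites = pc$nc)
}

pair_prep <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB))
    bg_stop("bg_alignment_length", "sequences must have equal aligned length")
  a <- encode_seq(normalize_seqs(seqA))
  b <- encode_seq(normalize_seqs(seqB))
  pc <- pair_counts(a, b)
  if (pc$nc == 0L)
    bg_stop("bg_no_comparable_sites",
            "no comparable sites after pairwise deletion")
  pc
}

#' Distance matrix over a labelled alignment
#'
#' Evaluates every unordered pair once and mirrors the result. Pairs that are
#' saturated (K2P log argument non-positive) or have no comparable sites are
#' stored as `NA` and itemised in the matrix's `exceptions` table instead of
#' being silently clamped; downstream threshold and identification code
#' treats such pairs as lying beyond any threshold.
#'
#' @param aln a [labeled_alignment] with at least two sequences.
#' @param model `"K2P"` (Kimura 2-parameter) or `"P_DIST"` (raw proportion).
#' @return A `distance_matrix`: list with `ids`, `values` (n x n numeric,
#'   zero diagonal), `model`, `comparable_sites` (n x n integer) and
#'   `exceptions` (data.frame of id pairs with a reason).
#' @export
pairwise_distance_matrix <- function(aln, model = c("K2P", "P_DIST")) {
  model <- match.arg(model)
  n <- attr(aln, "n")
  if (n < 2L)
    bg_stop("bg_empty_input", "need at least 2 sequences for a distance matrix")
  enc <- lapply(aln$seqs, encode_seq)
  vals <- matrix(0, n, n)
  comp <- matrix(0L, n, n)
  exc <- list()
  for (i in seq_len(n - 1L)) {
    ai <- enc[[i]]
    for (j in (i + 1L):n) {
      pc <- pair_counts(ai, enc[[j]])
      comp[i, j] <- comp[j, i] <- pc$nc
      if (pc$nc == 0L) {
        vals[i, j] <- vals[j, i] <- NA_real_
        exc[[length(exc) + 1L]] <- data.frame(
          id1 = aln$ids[i], id2 = aln$ids[j], reason = "no_comparable_sites",
          P = NA_real_, Q = NA_real_, stringsAsFactors = FALSE)
        next
      }
      P <- pc$ts / pc$nc
      Q <- pc$tv / pc$nc
      d <- if (model == "P_DIST") {
        P + Q
      } else {
        tryCatch(k2p_from_PQ(P, Q), bg_saturation = function(e) NA_real_)
      }
      if (is.na(d))
        exc[[length(exc) + 1L]] <- data.frame(
          id1 = aln$ids[i], id2 = aln$ids[j], reason = "saturated",
          P = P, Q = Q, stringsAsFactors = FALSE)
      vals[i, j] <- vals[j, i] <- d
    }
  }
  dimnames(vals) <- dimnames(comp) <- list(aln$ids, aln$ids)
  distance_matrix(aln$ids, vals, model, comparable_sites = comp,
                  exceptions = if (length(exc)) do.call(rbind, exc) else
                    data.frame(id1 = character(), id2 = character(),
                               reason = character(), P = numeric(),
                               Q = numeric(), stringsAsFactors = FALSE))
}

#' Construct a distance matrix from precomputed values
#'
#' Useful for feeding externally computed distances into the threshold and
#' identification machinery. Values must form a symmetric matrix with zero
#' diagonal; `NA` marks undefined (e.g. saturated) pairs.
#'
#' @param ids sequence identifiers, one per row/column.
#' @param values symmetric n x n numeric matrix of proportions.
#' @param model distance model tag, `"K2P"` or `"P_DIST"`.
#' @param comparable_sites optional n x n integer matrix of per-pair site
#'   counts.
#' @param exceptions optional data.frame itemising undefined pairs.
#' @return A `distance_matrix` object.
#' @export
distance_matrix <- function(ids, values, model = c("K2P", "P_DIST"),
                            comparable_sites = NULL, exceptions = NULL) {
  model <- match.arg(model)
  values <- as.matrix(values)
  n <- length(ids)
  if (!all(dim(values) == c(n, n)))
    bg_stop("bg_shape_error", "values must be an n x n matrix matching ids")
  if (any(diag(values) != 0))
    bg_stop("bg_matrix_invalid", "distance matrix diagonal must be exactly 0")
  if (!isTRUE(all.equal(values, t(values))))
    bg_stop("bg_matrix_invalid", "distance matrix must be symmetric")
  if (any(values < 0, na.rm = TRUE))
    bg_stop("bg_matrix_invalid", "distances must be non-negative")
  dimnames(values) <- list(ids, ids)
  structure(list(ids = as.character(ids), values = values, model = model,
                 comparable_sites = comparable_sites,
                 exceptions = exceptions %||% data.frame()),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  v <- pairwise_values(x)
  cat(sprintf("distance_matrix (%s): %d sequences, %d pairs\n",
              x$model, length(x$ids), length(v) + nrow(x$exceptions)))
  if (length(v))
    cat(sprintf("  range %.4f-%.4f (%.2f%%-%.2f%%)\n",
                min(v), max(v), 100 * min(v), 100 * max(v)))
  if (nrow(x$exceptions))
    cat(sprintf("  %d undefined pair(s): %s\n", nrow(x$exceptions),
                paste(unique(x$exceptions$reason), collapse = ", ")))
  invisible(x)
}

#' Vector of unique pairwise distances
#' @param dm a `distance_matrix`.
#' @param na.rm drop undefined pairs (default TRUE).
#' @return numeric vector of the lower-triangle values.
#' @export
pairwise_values <- function(dm, na.rm = TRUE) {
  v <- dm$values[lower.tri(dm$values)]
  if (na.rm) v <- v[!is.na(v)]
  v
}

#' Write a distance matrix as square TSV
#'
#' Header row and first column carry the sequence ids; undefined pairs are
#' written as `NA`.
#' @param dm a `distance_matrix`.
#' @param path output file path.
#' @return Invisibly, `dm`.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(id = dm$ids, dm$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dm)
}
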