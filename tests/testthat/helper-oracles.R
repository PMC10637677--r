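# Independent oracles and fixture builders. Deliberately naive: plain loops
# and direct definitions, no reuse of the implementation's internals.

BASES4 <- c("A", "C", "G", "T")

random_alignment <- function(n, L, p_missing = 0, n_species = 2,
                             locus = "test") {
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(BASES4, L, replace = TRUE)
    if (p_missing > 0) {
      miss <- runif(L) < p_missing
      s[miss] <- sample(c("N", "-"), sum(miss), replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
  labels <- paste0("sp", rep_len(seq_len(n_species), n))
  labeled_alignment(paste0("q", seq_len(n)), seqs, labels, locus = locus)
}

# closed-form K2P from explicit site-category counts
k2p_closed_form <- function(ts, tv, nc) {
  P <- ts / nc; Q <- tv / nc
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# build a sequence pair with exactly `ts` transition and `tv` transversion
# differences over L comparable sites
pair_with_counts <- function(L, ts, tv) {
  a <- sample(BASES4, L, replace = TRUE)
  b <- a
  pos <- sample.int(L, ts + tv)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversion <- c(A = "C", G = "T", C = "G", T = "A")
  if (ts > 0) b[pos[seq_len(ts)]] <- transition[a[pos[seq_len(ts)]]]
  if (tv > 0) b[pos[ts + seq_len(tv)]] <- transversion[a[pos[ts + seq_len(tv)]]]
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# naive per-pair p-distance with pairwise deletion, character by character
p_dist_oracle <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  ok <- a %in% BASES4 & b %in% BASES4
  sum(a[ok] != b[ok]) / sum(ok)
}

# exhaustive best-close-match re-derivation from a raw values matrix
bcm_oracle <- function(values, labels, t, tie_tol = 1e-12) {
  n <- nrow(values)
  out <- character(n)
  for (q in 1:n) {
    ds <- values[q, ]
    ds[q] <- Inf
    ds[is.na(ds)] <- Inf
    m <- min(ds)
    if (!is.finite(m) || m > t) { out[q] <- "no_id"; next }
    sp <- unique(labels[ds <= m + tie_tol])
    out[q] <- if (length(sp) > 1) "ambiguous"
      else if (sp == labels[q]) "correct" else "incorrect"
  }
  out
}

# brute-force cumulative error of the within-threshold neighbour-set rule
threshold_id_oracle <- function(values, labels, t) {
  n <- nrow(values)
  err <- 0L
  for (q in 1:n) {
    ds <- values[q, ]
    ds[q] <- NA
    nb <- which(!is.na(ds) & ds <= t)
    if (length(nb) == 0) err <- err + 1L            # FN (no id)
    else if (any(labels[nb] != labels[q])) err <- err + 1L  # FP
  }
  err
}

# random symmetric distance matrix with labelled species of size >= 2
random_labeled_matrix <- function(n_max = 30) {
  k <- sample(2:5, 1)
  sizes <- pmin(sample(2:6, k, replace = TRUE), n_max)
  n <- as.integer(sum(sizes))
  labels <- rep(paste0("sp", seq_len(k)), sizes)
  v <- matrix(0, n, n)
  vals <- round(runif(n * (n - 1) / 2, 0, 0.3), 3)  # rounding makes ties common
  v[lower.tri(v)] <- vals
  v <- v + t(v)
  list(dm = distance_matrix(paste0("q", 1:n), v, "P_DIST"),
       labels = labels, n = n)
}

tmp_community_files <- function(sim, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  write_community(sim, dir)
}
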