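#' Specification of a synthetic barcode community
#'
#' Describes the world the generator simulates: `n_species` clusters on a
#' star phylogeny, each with `per_species_n` individuals, sequences of
#' `seq_length` aligned columns, small intraspecific divergence
#' (`target_intra`, expected pairwise p-distance between conspecifics) and
#' larger interspecific divergence (`target_inter`, expected pairwise
#' p-distance between species ancestors), and a transition:transversion
#' rate ratio `kappa`. `overlap_mode` plants a haplotype of species 1 into
#' species 2, reproducing the regime in which shared haplotypes destroy the
#' barcoding gap (the classic mitochondrial failure mode); with it on the
#' `target_intra < target_inter` requirement is waived.
#'
#' Defaults describe a clean-gap community: 4 species of 10 sequences,
#' 600 bp, intra 0.01, inter 0.15, kappa 2.
#'
#' @param n_species number of species clusters.
#' @param per_species_n integer vector of individuals per species (length 1
#'   recycled; singleton species allowed).
#' @param seq_length alignment length in sites.
#' @param target_intra expected intraspecific pairwise p-distance.
#' @param target_inter expected ancestor-to-ancestor pairwise p-distance.
#' @param kappa transition:transversion rate ratio (`> 0`).
#' @param overlap_mode copy one haplotype across the first two species.
#' @param seed integer seed; same spec + seed gives byte-identical output.
#' @return A `community_spec`.
#' @export
community_spec <- function(n_species = 4L, per_species_n = 10L,
                           seq_length = 600L, target_intra = 0.01,
                           target_inter = 0.15, kappa = 2,
                           overlap_mode = FALSE, seed = 1L) {
  if (n_species < 1L) bg_stop("bg_domain_error", "n_species must be >= 1")
  per_species_n <- as.integer(rep_len(per_species_n, n_species))
  if (any(per_species_n < 1L))
    bg_stop("bg_domain_error", "per_species_n entries must be >= 1")
  if (kappa <= 0) bg_stop("bg_domain_error", "kappa must be > 0")
  if (target_intra < 0 || target_inter < 0 || target_inter > 0.75)
    bg_stop("bg_domain_error", "targets must satisfy 0 <= target <= 0.75")
  if (!overlap_mode && !(target_intra < target_inter))
    bg_stop("bg_domain_error",
            "target_intra must be < target_inter unless overlap_mode is on")
  if (overlap_mode && n_species < 2L)
    bg_stop("bg_domain_error", "overlap_mode needs at least 2 species")
  structure(list(n_species = as.integer(n_species),
                 per_species_n = per_species_n,
                 seq_length = as.integer(seq_length),
                 target_intra = target_intra, target_inter = target_inter,
                 kappa = kappa, overlap_mode = isTRUE(overlap_mode),
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Mutate a sequence site-by-site
#'
#' Each site is substituted independently with probability `expected_p`;
#' given a substitution, the transition is chosen with probability
#' `kappa / (kappa + 2)` and each of the two transversions with probability
#' `1 / (kappa + 2)`. Only `A/C/G/T` sites mutate; `N`/`-` are carried
#' through. Uses the current R random-number stream.
#'
#' @param seq nucleotide string.
#' @param expected_p per-site substitution probability, `0 <= p < 0.75`.
#' @param kappa transition:transversion rate ratio.
#' @return The mutated string, with attribute `"n_substitutions"`.
#' @export
mutate_sequence <- function(seq, expected_p, kappa = 2) {
  if (expected_p < 0 || expected_p >= 0.75)
    bg_stop("bg_domain_error", "expected_p must be in [0, 0.75)")
  if (kappa <= 0) bg_stop("bg_domain_error", "kappa must be > 0")
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  eligible <- x %in% BASES
  hit <- eligible & stats::runif(length(x)) < expected_p
  idx <- which(hit)
  if (length(idx)) {
    p_ts <- kappa / (kappa + 2)
    u <- stats::runif(length(idx))
    # category 1 = transition, 2/3 = the two transversions
    cat3 <- 1L + (u >= p_ts) + (u >= p_ts + (1 - p_ts) / 2)
    TRANSITION <- c(A = "G", C = "T", G = "A", T = "C")
    TV1 <- c(A = "C", C = "A", G = "C", T = "A")
    TV2 <- c(A = "T", C = "G", G = "T", T = "G")
    from <- x[idx]
    x[idx] <- ifelse(cat3 == 1L, TRANSITION[from],
                     ifelse(cat3 == 2L, TV1[from], TV2[from]))
  }
  structure(paste(x, collapse = ""), n_substitutions = length(idx))
}

# Per-branch substitution probability giving a target expected pairwise
# p-distance between two tips joined through a common ancestor.
# Under the single-shot model the expected tip-to-tip p-distance is
#   D(p) = 2p - p^2 (1 + c),  c = (kappa^2 + 2) / (kappa + 2)^2
# (the p^2 term is the parallel/back-mutation correction: both branches may
# hit the same site, agreeing with probability c). Solving the quadratic for
# the smaller root gives p; targets above the ceiling 1/(1+c) are
# unattainable under this model.
branch_p_for_target <- function(target, kappa) {
  c_same <- (kappa^2 + 2) / (kappa + 2)^2
  disc <- 1 - (1 + c_same) * target
  if (disc < 0)
    bg_stop("bg_domain_error", sprintf(
      "target pairwise distance %.3f exceeds the model ceiling %.3f",
      target, 1 / (1 + c_same)))
  (1 - sqrt(disc)) / (1 + c_same)
}

#' Simulate a labelled barcode community
#'
#' Star phylogeny in two tiers: a uniform-random root sequence; one ancestor
#' per species, mutated from the root with a per-branch rate solved so the
#' expected ancestor-to-ancestor p-distance matches `target_inter`; and the
#' individuals of each species, mutated from their ancestor with a rate
#' solved so the expected conspecific pairwise p-distance matches
#' `target_intra`. With `overlap_mode`, the first individual of species 2
#' is replaced by a copy of the first individual of species 1, planting a
#' shared haplotype across the species boundary.
#'
#' Fully deterministic under `spec$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param spec a [community_spec].
#' @return list with `alignment` (a [labeled_alignment], locus
#'   `"synthetic"`) and `truth` (a `synthetic_truth`: root, ancestors,
#'   per-tip substitution counts, branch rates, the spec echo and seed).
#' @examples
#' sim <- simulate_community(community_spec(n_species = 2,
#'                                          per_species_n = 3, seed = 42))
#' sim$alignment
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  L <- spec$seq_length
  root <- paste(sample(BASES, L, replace = TRUE), collapse = "")
  p_inter <- branch_p_for_target(spec$target_inter, spec$kappa)
  p_intra <- branch_p_for_target(spec$target_intra, spec$kappa)
  ancestors <- vapply(seq_len(spec$n_species), function(s)
    as.character(mutate_sequence(root, p_inter, spec$kappa)), character(1))
  names(ancestors) <- sprintf("species_%02d", seq_len(spec$n_species))

  ids <- character(0); seqs <- character(0); labels <- character(0)
  n_subs <- integer(0)
  for (s in seq_len(spec$n_species)) {
    for (i in seq_len(spec$per_species_n[s])) {
      tip <- mutate_sequence(ancestors[[s]], p_intra, spec$kappa)
      ids <- c(ids, sprintf("sp%02d_%03d", s, i))
      seqs <- c(seqs, as.character(tip))
      labels <- c(labels, names(ancestors)[s])
      n_subs <- c(n_subs, attr(tip, "n_substitutions"))
    }
  }
  shared <- NULL
  if (spec$overlap_mode) {
    donor <- which(labels == names(ancestors)[1])[1]
    recip <- which(labels == names(ancestors)[2])[1]
    seqs[recip] <- seqs[donor]
    n_subs[recip] <- NA_integer_
    shared <- c(donor = ids[donor], recipient = ids[recip])
  }
  aln <- labeled_alignment(ids, seqs, labels, locus = "synthetic")
  truth <- structure(list(root = root, ancestors = ancestors,
                          n_substitutions = stats::setNames(n_subs, ids),
                          branch_p = c(inter = p_inter, intra = p_intra),
                          shared_haplotype = shared,
                          spec = spec, seed = spec$seed),
                     class = "synthetic_truth")
  list(alignment = aln, truth = truth)
}

#' Write a simulated community to disk
#'
#' Emits the FASTA + label TSV consumed by [read_labeled_fasta()] and a JSON
#' ground-truth file alongside.
#'
#' @param sim result of [simulate_community()].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix (default `"community"`).
#' @return Invisibly, the vector of paths written.
#' @export
write_community <- function(sim, dir, prefix = "community") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c(".fasta", "_labels.tsv",
                                           "_truth.json")))
  write_labeled_fasta(sim$alignment, paths[1], paths[2])
  tr <- sim$truth
  jsonlite::write_json(
    list(seed = tr$seed, spec = unclass(tr$spec),
         branch_p = as.list(tr$branch_p),
         ancestors = as.list(tr$ancestors),
         n_substitutions = as.list(tr$n_substitutions),
         shared_haplotype = as.list(tr$shared_haplotype)),
    paths[3], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
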