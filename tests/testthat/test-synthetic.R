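test_that("community_spec validates its invariants", {
  expect_s3_class(community_spec(), "community_spec")
  expect_error(community_spec(kappa = 0), class = "bg_domain_error")
  expect_error(community_spec(per_species_n = c(3, 0)),
               class = "bg_domain_error")
  expect_error(community_spec(target_intra = 0.2, target_inter = 0.1),
               class = "bg_domain_error")
  # same targets allowed once overlap_mode is on
  expect_s3_class(community_spec(target_intra = 0.2, target_inter = 0.1,
                                 overlap_mode = TRUE), "community_spec")
  expect_error(community_spec(n_species = 1, overlap_mode = TRUE),
               class = "bg_domain_error")
  expect_error(community_spec(target_inter = 0.9), class = "bg_domain_error")
})

test_that("mutate_sequence: identity at p = 0, domain checks", {
  set.seed(71)
  s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  expect_equal(as.character(mutate_sequence(s, 0)), s)
  expect_error(mutate_sequence(s, 0.8), class = "bg_domain_error")
  expect_error(mutate_sequence(s, 0.1, kappa = -1), class = "bg_domain_error")
  # N and - are carried through unmutated
  m <- as.character(mutate_sequence("N-N-", 0.74))
  expect_equal(m, "N-N-")
})

test_that("substitution categories follow kappa/(kappa+2) weights", {
  set.seed(72)
  s <- strrep("A", 1e5)
  # kappa = 0.5: transition fraction 0.2, each transversion 0.4
  m <- strsplit(as.character(mutate_sequence(s, 0.5, kappa = 0.5)), "")[[1]]
  subs <- m[m != "A"]
  expect_gt(length(subs), 4e4)
  frac <- table(factor(subs, levels = c("C", "G", "T"))) / length(subs)
  # binomial 3-sigma on these fractions at n ~ 5e4 is < 0.007
  expect_lt(abs(frac[["G"]] - 0.2), 0.01)   # transition
  expect_lt(abs(frac[["C"]] - 0.4), 0.01)
  expect_lt(abs(frac[["T"]] - 0.4), 0.01)
})

test_that("realized distance to parent concentrates around expected_p", {
  set.seed(73)
  L <- 1e5
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  m <- as.character(mutate_sequence(s, 0.05, kappa = 2))
  realized <- as.numeric(p_distance(s, m))
  expect_equal(realized, 0.05, tolerance = 3 * sqrt(0.05 * 0.95 / L) / 0.05)
})

test_that("simulate_community is reproducible and leaves the RNG alone", {
  spec <- community_spec(seed = 99)
  set.seed(1234)
  before <- .Random.seed
  a <- simulate_community(spec)
  expect_identical(.Random.seed, before)
  b <- simulate_community(spec)
  expect_identical(a$alignment$seqs, b$alignment$seqs)
  expect_identical(a$truth$ancestors, b$truth$ancestors)

  # byte-identical files on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_community(a, d1); p2 <- write_community(b, d2)
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_identical(readLines(p1[2]), readLines(p2[2]))

  # a different seed changes the sequences
  c_ <- simulate_community(community_spec(seed = 100))
  expect_false(identical(a$alignment$seqs, c_$alignment$seqs))
})

test_that("target_intra = 0 collapses each species to one haplotype", {
  sim <- simulate_community(community_spec(n_species = 2,
                                           per_species_n = 3,
                                           target_intra = 0, seed = 74))
  expect_lte(haplotype_summary(sim$alignment)$n_haplotypes, 2L)
  for (sp in unique(sim$alignment$labels)) {
    s <- sim$alignment$seqs[sim$alignment$labels == sp]
    expect_length(unique(s), 1)
  }
})

test_that("realized mean intraspecific distance is within 20% of target", {
  sim <- simulate_community(community_spec(seed = 75))
  dm <- pairwise_distance_matrix(sim$alignment, "P_DIST")
  labels <- sim$alignment$labels
  same <- outer(labels, labels, "==")
  intra <- dm$values[lower.tri(dm$values) & same]
  expect_equal(mean(intra), 0.01, tolerance = 0.2)
  inter <- dm$values[lower.tri(dm$values) & !same]
  # tip-to-tip inter distance exceeds the ancestor target by the intra noise
  expect_equal(mean(inter), 0.15 + 0.01, tolerance = 0.2)
})

test_that("overlap_mode plants a shared haplotype across species 1 and 2", {
  sim <- simulate_community(community_spec(overlap_mode = TRUE, seed = 76))
  tr <- sim$truth
  expect_named(tr$shared_haplotype, c("donor", "recipient"))
  i <- match(tr$shared_haplotype[["donor"]], sim$alignment$ids)
  j <- match(tr$shared_haplotype[["recipient"]], sim$alignment$ids)
  expect_identical(sim$alignment$seqs[i], sim$alignment$seqs[j])
  expect_false(sim$alignment$labels[i] == sim$alignment$labels[j])
})

test_that("write_community emits files read_labeled_fasta round-trips", {
  sim <- simulate_community(community_spec(n_species = 2, per_species_n = 4,
                                           seed = 77))
  dir <- withr::local_tempdir()
  paths <- write_community(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_labeled_fasta(paths[1], paths[2], locus = "synthetic")
  expect_equal(back$seqs, sim$alignment$seqs)
  expect_equal(back$labels, sim$alignment$labels)
  truth <- jsonlite::read_json(paths[3])
  expect_equal(truth$seed, 77)
  expect_equal(length(truth$ancestors), 2)
})
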