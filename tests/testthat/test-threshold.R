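# helper: distance_matrix whose intraspecific distances are exactly `intra`
# (one two-member species per value) and all interspecific distances `inter`
paired_species_matrix <- function(intra, inter = 0.5) {
  k <- length(intra)
  n <- 2 * k
  v <- matrix(inter, n, n)
  diag(v) <- 0
  for (i in seq_len(k)) v[2 * i - 1, 2 * i] <- v[2 * i, 2 * i - 1] <- intra[i]
  list(dm = distance_matrix(paste0("q", 1:n), v, "P_DIST"),
       labels = rep(paste0("sp", 1:k), each = 2))
}

test_that("local_minima_threshold finds the single dip between two modes", {
  d <- c(rep(0.01, 50), rep(0.20, 50))
  est <- local_minima_threshold(d)
  # oracle: same KDE on a 10,001-point grid, scan discrete sign changes
  dens <- stats::density(d, bw = "nrd0", n = 10001, from = 0, to = max(d))
  y <- dens$y; i <- 2:(length(y) - 1)
  oracle <- dens$x[i][y[i - 1] > y[i] & y[i] < y[i + 1]]
  expect_length(oracle, 1)
  expect_length(est$candidates, 1)
  expect_gt(est$value, 0.01)
  expect_lt(est$value, 0.20)
  expect_equal(est$value, oracle, tolerance = 2e-3)
})

test_that("degenerate or unimodal densities give a no-threshold estimate", {
  est <- local_minima_threshold(rep(0.05, 30))
  expect_true(est$no_threshold)
  expect_true(is.na(est$value))

  set.seed(31)
  est2 <- local_minima_threshold(rnorm(500, 0.1, 0.01))
  expect_true(est2$no_threshold || est2$value > 0)  # usually unimodal
})

test_that("a density plateau from underflow in a wide gap is one minimum", {
  # this community's KDE underflows to a flat run across the gap; pointwise
  # strict-minimum detection sees no dip there and reports only a spurious
  # far-tail wiggle (~0.20, cumulative error 40/40)
  sim <- simulate_community(community_spec(seed = 50034))
  dm <- pairwise_distance_matrix(sim$alignment)
  labels <- sim$alignment$labels
  same <- outer(labels, labels, "==")
  lower <- lower.tri(dm$values)
  est <- local_minima_threshold(dm)
  expect_gt(est$value, max(dm$values[lower & same]))
  expect_lt(est$value, min(dm$values[lower & !same]))
  expect_equal(threshold_id(dm, labels, est$value)$cumulative_error, 0L)
})

test_that("on a well-separated community the dip falls inside the true gap", {
  sim <- simulate_community(community_spec(seed = 301))
  dm <- pairwise_distance_matrix(sim$alignment)
  labels <- sim$alignment$labels
  est <- local_minima_threshold(dm)
  same <- outer(labels, labels, "==")
  lower <- lower.tri(dm$values)
  max_intra <- max(dm$values[lower & same])
  min_inter <- min(dm$values[lower & !same])
  expect_gt(est$value, max_intra)
  expect_lt(est$value, min_inter)
})

test_that("threshold_id applies the within-threshold neighbour-set rule", {
  # two identical conspecifics: both correct, zero error
  ps <- paired_species_matrix(c(0, 0.02))
  r <- threshold_id(ps$dm, ps$labels, 0.01)
  expect_equal(as.character(r$status), c("correct", "correct", "no_id", "no_id"))
  expect_equal(r$cumulative_error, 2L)
  expect_equal(sum(r$counts[c("TP", "FN", "FP", "TN")]), 4L)

  # t = 0 where a heterospecific sits at distance 0
  v <- matrix(c(0, 0, 0.1, 0, 0, 0.1, 0.1, 0.1, 0), 3, 3)
  dm0 <- distance_matrix(c("a", "b", "c"), v, "P_DIST")
  r0 <- threshold_id(dm0, c("X", "Y", "Y"), 0)
  expect_true(all(as.character(r0$status)[1:2] %in% c("incorrect", "ambiguous")))

  expect_error(threshold_id(ps$dm, ps$labels, -0.1), class = "bg_domain_error")
})

test_that("threshold_id statuses partition n and no_id is monotone in t", {
  set.seed(32)
  for (rep in 1:10) {
    rl <- random_labeled_matrix()
    prev_no_id <- Inf
    for (t in seq(0, 0.35, by = 0.05)) {
      r <- threshold_id(rl$dm, rl$labels, t)
      expect_equal(sum(table(r$status)), rl$n)
      n_no_id <- sum(r$status == "no_id")
      expect_lte(n_no_id, prev_no_id)
      prev_no_id <- n_no_id
    }
    expect_equal(prev_no_id, 0L)  # t >= max distance: everything has a match
  }
})

test_that("cumulative error matches the brute-force oracle on clean-gap data", {
  sim <- simulate_community(community_spec(seed = 302))
  dm <- pairwise_distance_matrix(sim$alignment)
  labels <- sim$alignment$labels
  same <- outer(labels, labels, "==")
  lower <- lower.tri(dm$values)
  max_intra <- max(dm$values[lower & same])
  min_inter <- min(dm$values[lower & !same])
  expect_lt(max_intra, min_inter)

  for (t in c(mean(c(max_intra, min_inter)), min_inter + 0.01, 0.002)) {
    r <- threshold_id(dm, labels, t)
    expect_equal(r$cumulative_error,
                 threshold_id_oracle(dm$values, labels, t))
  }
  gap_mid <- mean(c(max_intra, min_inter))
  expect_equal(threshold_id(dm, labels, gap_mid)$cumulative_error, 0L)
  expect_gt(threshold_id(dm, labels, min_inter)$cumulative_error, 0L)
})

test_that("optimize_threshold selects the minimal-error plateau", {
  # gap exactly covers grid points 0.005..0.007: intra up to 0.004,
  # inter from 0.008
  ps <- paired_species_matrix(c(0.001, 0.004), inter = 0.008)
  est <- optimize_threshold(ps$dm, ps$labels, grid = seq(0.001, 0.02, 0.001))
  expect_equal(est$candidates, c(0.004, 0.005, 0.006, 0.007))
  expect_equal(est$value, 0.004)  # smallest zero-error point: t >= max intra
  tab <- est$diagnostics$error_grid
  expect_true(all(tab$cumulative_error[tab$threshold %in% est$candidates] ==
                    min(tab$cumulative_error)))
  # oracle agreement across the whole grid
  expect_equal(tab$cumulative_error,
               vapply(tab$threshold, function(t)
                 threshold_id_oracle(ps$dm$values, ps$labels, t), integer(1)))

  single <- optimize_threshold(ps$dm, ps$labels, grid = 0.005)
  expect_equal(single$value, 0.005)
  expect_error(optimize_threshold(ps$dm, ps$labels, grid = c(0.2, 0.1)),
               class = "bg_domain_error")
})

test_that("percentile_threshold implements the coverage scan", {
  ps <- paired_species_matrix(seq(0.01, 0.20, by = 0.01), inter = 0.5)
  est <- percentile_threshold(ps$dm, ps$labels, coverage = 0.95)
  expect_equal(est$value, 0.19)  # 19/20 = 95%
  expect_equal(est$method, "PERCENTILE_95")

  expect_equal(percentile_threshold(ps$dm, ps$labels, coverage = 1)$value, 0.20)

  same <- paired_species_matrix(rep(0.03, 5))
  expect_equal(percentile_threshold(same$dm, same$labels)$value, 0.03)

  # all species singletons: no intraspecific pairs
  v <- matrix(c(0, 0.1, 0.1, 0), 2, 2)
  dm1 <- distance_matrix(c("a", "b"), v, "P_DIST")
  expect_error(percentile_threshold(dm1, c("X", "Y")),
               class = "bg_no_intraspecific")
  expect_error(percentile_threshold(dm1, c("X", "X"), coverage = 0),
               class = "bg_domain_error")
})

test_that("threshold estimates serialise their diagnostics", {
  ps <- paired_species_matrix(c(0.01, 0.02))
  est <- optimize_threshold(ps$dm, ps$labels)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_threshold_diagnostics(est, path)
  tab <- utils::read.delim(path)
  expect_named(tab, c("threshold", "TP", "FN", "FP", "TN", "cumulative_error"))
  expect_equal(nrow(tab), 20)
})
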