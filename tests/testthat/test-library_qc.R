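test_that("spikiness follows the successive-difference formula", {
  grid4 <- toy_grid(n_chrom = 1, chrom_bins = 4)
  expect_equal(spikiness(cell_counts("c", grid4, c(5, 5, 5, 5))), 0)
  grid3 <- toy_grid(n_chrom = 1, chrom_bins = 3)
  expect_equal(spikiness(cell_counts("c", grid3, c(1, 3, 1))), 0.8)
  # scale invariance
  expect_equal(spikiness(cell_counts("c", grid3, c(10, 30, 10))), 0.8)
  # differences do not cross chromosome boundaries
  grid22 <- toy_grid(n_chrom = 2, chrom_bins = 2)
  expect_equal(spikiness(cell_counts("c", grid22, c(0, 10, 0, 10))), 1)
  expect_error(spikiness(cell_counts("c", grid4, c(0, 0, 0, 0))), "zero")
})

# all permutations of a small vector (brute force)
combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(combinat_perms(v[-i]), function(r) c(v[i], r)))
  out
}

test_that("alternating counts maximise spikiness over all arrangements", {
  multiset <- c(0, 10, 0, 10, 0, 10)
  grid6 <- toy_grid(n_chrom = 1, chrom_bins = 6)
  perms <- unique(combinat_perms(multiset))
  s_all <- vapply(perms, function(v)
    spikiness(cell_counts("c", grid6, v)), numeric(1))
  s_alt <- spikiness(cell_counts("c", grid6, c(0, 10, 0, 10, 0, 10)))
  s_mono <- spikiness(cell_counts("c", grid6, sort(multiset)))
  expect_equal(s_alt, max(s_all))
  expect_gt(s_alt, s_mono)
})

test_that("segment counting splits chromosomes and matches stored segments", {
  grid3x <- toy_grid(n_chrom = 3, chrom_bins = 4)
  prof <- cn_profile("c", grid3x, rep(2L, 12))
  expect_equal(count_segments(prof), 3)   # one run per chromosome
  grid5 <- toy_grid(n_chrom = 1, chrom_bins = 5)
  prof2 <- cn_profile("c", grid5, c(2, 2, 3, 3, 2))
  expect_equal(count_segments(prof2), 3)
  # run-length computed independently agrees with the stored segments
  rl <- sum(vapply(split(prof2$states, prof2$grid$bins$chrom),
                   function(s) length(rle(s)$values), integer(1)))
  expect_equal(count_segments(prof2), rl)
})

test_that("Bhattacharyya distance matches the dense-summation oracle", {
  m <- emission_model(r1 = 8, p = 0.25)
  expect_equal(bhattacharyya_distance(m, states = c(1, 1)), 0,
               tolerance = 1e-10)
  expect_equal(bhattacharyya_distance(m),
               bd_oracle(m$r1, 2 * m$r1, m$p), tolerance = 1e-8)
  # separability grows with the baseline mean at fixed size parameter
  bds <- vapply(c(10, 30, 100), function(mu) {
    r1 <- 8
    bhattacharyya_distance(emission_model(r1, r1 / (r1 + mu)))
  }, numeric(1))
  expect_true(all(diff(bds) > 0))
  expect_error(bhattacharyya_distance(list(r1 = 1)), "fitted")
})

qc_fixture <- function(seed = 101) {
  # 8 clean libraries and 4 noisy ones (3x spikiness, 5x segments, halved
  # Bhattacharyya distance, depressed loglikelihood)
  set.seed(seed)
  n_clean <- 8; n_noisy <- 4
  data.frame(
    cell = sprintf("lib%02d", 1:12),
    spikiness = c(rnorm(n_clean, 0.20, 0.01), rnorm(n_noisy, 0.60, 0.03)),
    loglik = c(rnorm(n_clean, -10000, 100), rnorm(n_noisy, -13000, 150)),
    loglik_per_bin = c(rnorm(n_clean, -3.85, 0.04), rnorm(n_noisy, -5.0, 0.06)),
    n_segments = c(rpois(n_clean, 25), rpois(n_noisy, 125)),
    bhattacharyya = c(rnorm(n_clean, 1.1, 0.05), rnorm(n_noisy, 0.55, 0.04)),
    total_reads = rep(130000, 12),
    stringsAsFactors = FALSE)
}

test_that("identical libraries form a single fully selected cluster", {
  m <- qc_fixture()[rep(1, 10), ]
  m$cell <- sprintf("lib%02d", 1:10)
  out <- cluster_and_select(m)
  expect_equal(attr(out, "k"), 1L)
  expect_true(all(out$selected))
})

test_that("the clean cluster is separated and selected", {
  out <- cluster_and_select(qc_fixture())
  expect_equal(attr(out, "k"), 2L)
  expect_true(all(out$selected[1:8]))
  expect_false(any(out$selected[9:12]))
  # the selected cluster never has the maximal mean spikiness
  sel_spk <- mean(out$spikiness[out$selected])
  rej_spk <- mean(out$spikiness[!out$selected])
  expect_lt(sel_spk, rej_spk)
  # selected fraction matches the fixture design
  expect_equal(mean(out$selected), 8 / 12)
})

test_that("libraries with non-finite metrics are rejected before clustering", {
  m <- qc_fixture()
  m$loglik_per_bin[3] <- NaN
  out <- cluster_and_select(m)
  expect_true(is.na(out$cluster[3]))
  expect_false(out$selected[3])
  expect_true(all(out$selected[c(1:2, 4:8)]))
})

test_that("a lone usable library is selected with a warning", {
  m <- qc_fixture()[1, ]
  expect_warning(out <- cluster_and_select(m), "fewer than 2")
  expect_true(out$selected)
})

test_that("quality metrics assemble from fitted cells", {
  layout <- synthetic_layout(n_chrom = 3, chrom_bins = 30)
  truth <- simulate_karyotypes(layout, 2, q = 0.2, seed = 12)
  cells <- simulate_counts(truth, reads_per_cell = 4500, seed = 12)
  fits <- lapply(cells, karyo_hmm, n_restarts = 1)
  qm <- quality_metrics(fits)
  expect_equal(nrow(qm), 2)
  expect_true(all(qm$spikiness > 0))
  expect_true(all(qm$n_segments >= 3))   # at least one run per chromosome
  expect_true(all(is.finite(qm$bhattacharyya)))
})
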