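test_that("uniform mappability yields equal fixed-width bins", {
  layout <- genome_layout("chr1", 10e6)
  track <- data.frame(chrom = "chr1", start = 0, end = 10e6, value = 1)
  grid <- build_variable_bins(track, layout, target_width = 1e6)
  expect_equal(n_bins(grid), 10)
  expect_equal(grid$bins$width, rep(1e6, 10))
  expect_equal(grid$bins$start, seq(0, 9e6, by = 1e6))
  # boundary-for-boundary agreement with fixed-width binning
  expect_equal(grid$bins$start, uniform_bins(layout, 1e6)$bins$start)
  expect_equal(grid$bins$end, uniform_bins(layout, 1e6)$bins$end)
})

test_that("doubled mappability on the first half shrinks its bins", {
  layout <- genome_layout("chr1", 10e6)
  track <- data.frame(chrom = "chr1", start = c(0, 5e6), end = c(5e6, 10e6),
                      value = c(2, 1))
  grid <- build_variable_bins(track, layout, target_width = 1e6)
  expect_equal(n_bins(grid), 10)
  # total mass 15e6 over 10 bins: quota 1.5e6 -> 0.75 Mb bins at density 2,
  # 1.5 Mb bins at density 1 (greedy accumulation oracle)
  first_half <- grid$bins$end <= 5e6
  expect_equal(unique(grid$bins$width[first_half]), 0.75e6)
  late <- grid$bins$start >= 5e6
  expect_equal(unique(grid$bins$width[late]), 1.5e6)
  expect_equal(unname(grid$bins$mass), rep(1.5e6, 10), tolerance = 1e-9)
})

test_that("a chromosome shorter than the target width gets one bin", {
  layout <- genome_layout("chr1", 0.4e6)
  track <- data.frame(chrom = "chr1", start = 0, end = 0.4e6, value = 1)
  grid <- build_variable_bins(track, layout, target_width = 1e6)
  expect_equal(n_bins(grid), 1)
  expect_equal(grid$bins$start, 0)
  expect_equal(grid$bins$end, 0.4e6)
})

test_that("read positions act as point masses for bin placement", {
  layout <- genome_layout("chr1", 1e6)
  # 100 reads uniform over the first half only: bins concentrate there
  reads <- data.frame(chrom = "chr1", pos = seq(0, 499999, length.out = 100))
  grid <- build_variable_bins(reads, layout, target_width = 5e5)
  expect_equal(n_bins(grid), 2)
  expect_lt(grid$bins$end[1], 5e5)
  expect_equal(sum(grid$bins$mass), 100)
})

test_that("bins partition each chromosome without overlap", {
  set.seed(42)
  layout <- genome_layout(c("chrA", "chrB"), c(7.3e6, 3.1e6))
  track <- data.frame(
    chrom = rep(c("chrA", "chrB"), times = c(8, 4)),
    start = c(seq(0, 7e6, by = 1e6), seq(0, 3e6, by = 1e6)),
    end = c(seq(1e6, 7.3e6, by = 1e6)[1:7], 7.3e6,
            seq(1e6, 3.1e6, by = 1e6)[1:3], 3.1e6),
    value = runif(12, 0.2, 3))
  grid <- build_variable_bins(track, layout, target_width = 1e6)
  for (chr in layout$chrom) {
    b <- grid$bins[grid$bins$chrom == chr, ]
    expect_true(all(b$start < b$end))
    expect_true(all(diff(b$start) > 0))
    # contiguous partition: each bin starts where the previous ended
    expect_equal(b$start[-1], b$end[-nrow(b)])
    expect_lte(sum(b$width), layout$length[layout$chrom == chr])
  }
  # near-equal mass per bin within a chromosome
  for (chr in layout$chrom) {
    m <- grid$bins$mass[grid$bins$chrom == chr]
    expect_lt(diff(range(m)) / mean(m), 0.02)
  }
})

test_that("missing chromosomes are a hard error, zero mass a warning", {
  layout <- genome_layout(c("chr1", "chr2"), c(1e6, 1e6))
  track <- data.frame(chrom = "chr1", start = 0, end = 1e6, value = 1)
  expect_error(build_variable_bins(track, layout), "chr2")
  track2 <- rbind(track,
                  data.frame(chrom = "chr2", start = 0, end = 1e6, value = 0))
  expect_warning(grid <- build_variable_bins(track2, layout), "zero mappable")
  expect_equal(unique(grid$bins$chrom), "chr1")
})

test_that("blacklist removes bins only at >= 50% overlap", {
  grid <- toy_grid(n_chrom = 1, chrom_bins = 10)
  # empty blacklist: identity
  g0 <- apply_blacklist(grid, data.frame(chrom = character(),
                                         start = numeric(), end = numeric()))
  expect_equal(g0$bins, grid$bins)
  # full overlap of bin 5 (0-based bins 4e6-5e6): removed
  g1 <- apply_blacklist(grid, data.frame(chrom = "chr1", start = 4e6, end = 5e6))
  expect_equal(n_bins(g1), 9)
  expect_false(any(g1$bins$start == 4e6))
  expect_equal(attr(g1, "removed")$start, 4e6)
  # 40% overlap: retained (interval-arithmetic oracle: 0.4e6 / 1e6 < 0.5)
  g2 <- apply_blacklist(grid, data.frame(chrom = "chr1", start = 4e6, end = 4.4e6))
  expect_equal(n_bins(g2), 10)
  # 50% exactly: removed
  g3 <- apply_blacklist(grid, data.frame(chrom = "chr1", start = 4e6, end = 4.5e6))
  expect_equal(n_bins(g3), 9)
  # unknown chromosome: skipped with a message
  expect_message(
    g4 <- apply_blacklist(grid, data.frame(chrom = "chrUn", start = 0, end = 1e6)),
    "chrUn")
  expect_equal(n_bins(g4), 10)
})

test_that("GC assignment from a track is width-weighted", {
  grid <- toy_grid(n_chrom = 1, chrom_bins = 2)
  track <- data.frame(chrom = "chr1", start = c(0, 0.5e6, 1e6),
                      end = c(0.5e6, 1e6, 2e6), gc = c(0.3, 0.5, 0.45))
  g <- set_bin_gc(grid, track)
  expect_equal(g$bins$gc, c(0.4, 0.45))
  expect_error(set_bin_gc(grid, c(0.4, 1.2)), "0, 1")
})

test_that("bin grids serialise to BED and mappability loads from bedGraph", {
  layout <- genome_layout("chr1", 4e6)
  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t2000000\t2", "chr1\t2000000\t4000000\t1"), bg)
  grid <- build_variable_bins(bg, layout, target_width = 1e6)
  expect_equal(n_bins(grid), 4)
  expect_equal(grid$bins$mass, rep(1.5e6, 4), tolerance = 1e-9)
  bed <- tempfile(fileext = ".bed")
  write_bins_bed(grid, bed)
  tab <- read.table(bed, sep = "\t")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$V2, grid$bins$start)
  expect_equal(tab$V3, grid$bins$end)
})
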