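#' Synthetic genome layout for simulated cohorts
#'
#' By default emulates a mouse-scale genome: 20 chromosomes with lengths
#' decreasing from ~199 Mb to ~61 Mb (about 2.6 Gb in total, i.e. ~2,600
#' bins at the default 1 Mb bin width). Alternatively, a fixed number of
#' bins per chromosome can be requested for small test genomes.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_bins if given, every chromosome spans exactly this many
#'   bins of `bin_width` bp.
#' @param bin_width bin width used with `chrom_bins`.
#' @param ploidy baseline copy number (recycled).
#' @return A [genome_layout()] with chromosomes `chr1..chrN`.
#' @export
synthetic_layout <- function(n_chrom = 20L, chrom_bins = NULL,
                             bin_width = 1e6, ploidy = 2L) {
  lens <- if (is.null(chrom_bins)) {
    round(seq(199e6, 61e6, length.out = n_chrom) / 1e6) * 1e6
  } else rep(chrom_bins * bin_width, n_chrom)
  genome_layout(paste0("chr", seq_len(n_chrom)), lens, ploidy)
}

#' Uniform bin grid with simulated GC fractions
#'
#' Fixed-width bins with per-bin GC fractions drawn from a truncated
#' normal (mean 0.42, sd 0.04, clamped to [0.30, 0.65]), mimicking the
#' megabase-scale GC composition of mammalian genomes.
#'
#' @param layout a [genome_layout()].
#' @param width bin width in bp.
#' @param seed integer seed for the GC draw.
#' @return A `bin_grid` with GC assigned.
#' @export
synthetic_bins <- function(layout, width = 1e6, seed = 1L) {
  grid <- uniform_bins(layout, width)
  set.seed(seed %% 2147483647)
  g <- stats::rnorm(n_bins(grid), mean = 0.42, sd = 0.04)
  set_bin_gc(grid, pmin(pmax(g, 0.30), 0.65))
}

#' A canonical unimodal GC-bias curve
#'
#' Multiplicative coverage bias as a function of GC fraction: a downward
#' parabola peaking at `center`, floored at `floor_at` so bias never
#' reaches zero.
#'
#' @param strength curvature of the parabola.
#' @param center GC fraction of maximal coverage.
#' @param floor_at minimum relative coverage.
#' @return A function of the GC fraction.
#' @export
gc_bias_curve <- function(strength = 3, center = 0.45, floor_at = 0.2) {
  function(g) pmax(1 - strength * (g - center)^2, floor_at)
}

#' Simulate clonal + mis-segregation karyotypes for a cohort
#'
#' Every cell starts from the clonal base karyotype; with probability
#' `wgd_fraction` its genome doubles (whole-genome duplication, capped at
#' `c_max`); then a Poisson(`q` x number of chromosomes) number of
#' whole-chromosome gain/loss events is applied (uniform chromosome
#' choice, gain and loss equiprobable, floored at 0, capped at `c_max`).
#' With `p_segmental > 0` each event is, with that probability, segmental
#' instead: a uniform breakpoint is drawn within the chromosome and the
#' change applied to the suffix only. Cell `i` draws from a stream seeded
#' by `seed` and the cell counter, so cohorts are reproducible bit-exactly
#' and independent of evaluation order.
#'
#' @param layout a [genome_layout()].
#' @param n_cells number of cells.
#' @param base_karyotype integer per-chromosome clonal states; defaults to
#'   the layout's baseline ploidy.
#' @param q per-cell mis-segregation rate: expected events per cell is
#'   `q * n_chrom`.
#' @param wgd_fraction fraction of cells undergoing whole-genome
#'   duplication before the mis-segregation events.
#' @param c_max highest representable copy number.
#' @param bin_width bin width of the generated grid.
#' @param p_segmental probability that an event is segmental (default 0,
#'   whole-chromosome only).
#' @param seed integer seed.
#' @param grid optional pre-built `bin_grid`; defaults to
#'   [synthetic_bins()] on the layout.
#' @return An object of class `cohort_truth`: `layout`, `grid`, `states`
#'   (cells x bins integer matrix), `chrom_states` (cells x chromosomes,
#'   modal per-chromosome truth), `params`, `seed`.
#' @export
simulate_karyotypes <- function(layout, n_cells, base_karyotype = NULL,
                                q = 0.1, wgd_fraction = 0, c_max = 10L,
                                bin_width = 1e6, p_segmental = 0,
                                seed = 1L, grid = NULL) {
  stopifnot(q >= 0, q <= 1, n_cells >= 1)
  if (is.null(base_karyotype)) base_karyotype <- layout$ploidy
  base_karyotype <- as.integer(rep_len(base_karyotype, nrow(layout)))
  if (any(base_karyotype > c_max))
    stop("base karyotype state exceeds c_max")
  if (any(base_karyotype < 0)) stop("base karyotype states must be >= 0")
  if (is.null(grid)) grid <- synthetic_bins(layout, bin_width, seed = seed)
  b <- grid$bins
  n_chrom <- nrow(layout)
  chrom_of_bin <- match(b$chrom, layout$chrom)
  states <- matrix(0L, nrow = n_cells, ncol = nrow(b))
  chrom_states <- matrix(0L, nrow = n_cells, ncol = n_chrom,
                         dimnames = list(NULL, layout$chrom))
  for (i in seq_len(n_cells)) {
    set.seed((seed * 1000 + i) %% 2147483647)
    kar <- base_karyotype
    bins_i <- kar[chrom_of_bin]
    if (stats::runif(1) < wgd_fraction) {
      kar <- pmin(2L * kar, c_max)
      bins_i <- pmin(2L * bins_i, c_max)
    }
    n_ev <- stats::rpois(1, q * n_chrom)
    if (n_ev > 0) {
      chrs <- sample.int(n_chrom, n_ev, replace = TRUE)
      dirs <- sample(c(-1L, 1L), n_ev, replace = TRUE)
      segm <- stats::runif(n_ev) < p_segmental
      for (e in seq_len(n_ev)) {
        ch_bins <- which(chrom_of_bin == chrs[e])
        if (segm[e]) {
          bp <- sample.int(length(ch_bins), 1)
          idx <- ch_bins[seq(bp, length(ch_bins))]
          bins_i[idx] <- pmin(pmax(bins_i[idx] + dirs[e], 0L), c_max)
        } else {
          bins_i[ch_bins] <- pmin(pmax(bins_i[ch_bins] + dirs[e], 0L), c_max)
          kar[chrs[e]] <- min(max(kar[chrs[e]] + dirs[e], 0L), c_max)
        }
      }
    }
    states[i, ] <- bins_i
    chrom_states[i, ] <- vapply(seq_len(n_chrom), function(ch) {
      bi <- chrom_of_bin == ch
      as.integer(modal_state(bins_i[bi], b$width[bi]))
    }, integer(1))
  }
  structure(list(layout = layout, grid = grid, states = states,
                 chrom_states = chrom_states,
                 params = list(n_cells = n_cells, q = q,
                               wgd_fraction = wgd_fraction,
                               base_karyotype = base_karyotype,
                               c_max = c_max, p_segmental = p_segmental),
                 seed = as.integer(seed)),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort truth: %d cells, %d bins, q = %.2f, wgd = %.2f (seed %d)\n",
    nrow(x$states), ncol(x$states), x$params$q, x$params$wgd_fraction, x$seed))
  invisible(x)
}

#' Simulate per-cell binned read counts from a cohort truth
#'
#' Per cell, the expected count of a bin is proportional to
#' `state * width`, modulated by the multiplicative GC-bias curve, and the
#' whole vector is rescaled so the expected total equals
#' `reads_per_cell`. Counts are then drawn from a negative binomial with
#' that mean and the given `dispersion` (the NB size parameter: variance
#' `mu + mu^2 / dispersion`; large values approach Poisson noise).
#' Nullisomic bins emit exactly zero. Cell `i` draws from a stream seeded
#' by `seed + i`, independent of evaluation order.
#'
#' @param truth a `cohort_truth`.
#' @param reads_per_cell target expected reads per cell (default 130,000,
#'   about 50 reads per disomic 1 Mb bin on the default layout).
#' @param dispersion NB size parameter (default 15).
#' @param gc_bias `NULL` for no bias, or a function of the GC fraction,
#'   e.g. [gc_bias_curve()].
#' @param seed integer seed.
#' @return A list of [cell_counts()], one per cell.
#' @export
simulate_counts <- function(truth, reads_per_cell = 130000, dispersion = 15,
                            gc_bias = NULL, seed = 1L) {
  stopifnot(inherits(truth, "cohort_truth"), reads_per_cell > 0,
            dispersion > 0)
  b <- truth$grid$bins
  bias <- if (is.null(gc_bias)) rep(1, nrow(b)) else gc_bias(b$gc)
  n_cells <- nrow(truth$states)
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    set.seed((seed + i) %% 2147483647)
    mu <- truth$states[i, ] * b$width * bias
    if (sum(mu) == 0)
      stop("cell ", i, " has an all-zero karyotype; cannot scale counts")
    mu <- mu * reads_per_cell / sum(mu)
    x <- stats::rnbinom(length(mu), size = dispersion, mu = mu)
    x[truth$states[i, ] == 0L] <- 0L
    out[[i]] <- cell_counts(sprintf("cell_%03d", i), truth$grid, x)
  }
  out
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper: builds the layout and grid, draws karyotypes and
#' counts. All arguments are passed through to [simulate_karyotypes()] and
#' [simulate_counts()].
#'
#' @inheritParams simulate_karyotypes
#' @inheritParams simulate_counts
#' @param layout defaults to [synthetic_layout()].
#' @return list(truth = `cohort_truth`, cells = list of `cell_counts`).
#' @export
simulate_cohort <- function(layout = synthetic_layout(), n_cells = 40L,
                            base_karyotype = NULL, q = 0.1,
                            wgd_fraction = 0, c_max = 10L, bin_width = 1e6,
                            p_segmental = 0, reads_per_cell = 130000,
                            dispersion = 15, gc_bias = NULL, seed = 1L) {
  truth <- simulate_karyotypes(layout, n_cells, base_karyotype, q,
                               wgd_fraction, c_max, bin_width, p_segmental,
                               seed = seed)
  cells <- simulate_counts(truth, reads_per_cell, dispersion, gc_bias,
                           seed = seed)
  list(truth = truth, cells = cells)
}

#' Copy-number profiles of the simulation truth
#'
#' Wraps the true per-bin states as `cn_profile` objects so the karyotype
#' scores can be evaluated on the ground truth.
#'
#' @param truth a `cohort_truth`.
#' @return list of `cn_profile`.
#' @export
truth_profiles <- function(truth) {
  lapply(seq_len(nrow(truth$states)), function(i)
    cn_profile(sprintf("cell_%03d", i), truth$grid, truth$states[i, ]))
}

#' Compare decoded profiles against the simulation truth
#'
#' @param profiles list of `cn_profile` in cell order.
#' @param truth the `cohort_truth` they were simulated from.
#' @return A list: `per_cell_accuracy` (fraction of bins decoded to the
#'   true state, per cell), `accuracy` (overall per-bin), and `confusion`
#'   (truth x called contingency table); plus `modal_accuracy` over
#'   per-chromosome modal states.
#' @export
evaluate_calls <- function(profiles, truth) {
  called <- state_matrix(profiles)
  if (!all(dim(called) == dim(truth$states)))
    stop("profile/truth shape mismatch: ",
         paste(dim(called), collapse = "x"), " vs ",
         paste(dim(truth$states), collapse = "x"))
  per_cell <- rowMeans(called == truth$states)
  b <- truth$grid$bins
  chrom_of_bin <- match(b$chrom, truth$layout$chrom)
  modal_called <- t(apply(called, 1, function(s)
    vapply(seq_len(nrow(truth$layout)), function(ch) {
      bi <- chrom_of_bin == ch
      modal_state(s[bi], b$width[bi])
    }, numeric(1))))
  lev <- 0:max(truth$states, called)
  confusion <- table(truth = factor(truth$states, levels = lev),
                     called = factor(called, levels = lev))
  list(per_cell_accuracy = per_cell,
       accuracy = mean(called == truth$states),
       modal_accuracy = mean(modal_called == truth$chrom_states),
       confusion = confusion)
}

#' Write simulation truth states as TSV
#' @param truth a `cohort_truth`.
#' @param path output file.
#' @export
write_truth_tsv <- function(truth, path) {
  b <- truth$grid$bins
  long <- data.frame(cell = rep(sprintf("cell_%03d", seq_len(nrow(truth$states))),
                                each = ncol(truth$states)),
                     chrom = rep(b$chrom, nrow(truth$states)),
                     start = rep(b$start, nrow(truth$states)),
                     end = rep(b$end, nrow(truth$states)),
                     state = as.integer(t(truth$states)),
                     stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit minimal SAM records realising a cell's counts
#'
#' Writes one unpaired 50 bp alignment per counted read, deterministically
#' spread within each bin, so the alignment-counting stage can be
#' exercised without any external data. Round-tripping through
#' [count_reads()] reproduces the cell's counts exactly.
#'
#' @param cell a [cell_counts()].
#' @param path output `.sam` file.
#' @param read_length read length in bp.
#' @param mapq reported mapping quality.
#' @return The path, invisibly.
#' @export
write_cell_sam <- function(cell, path, read_length = 50L, mapq = 60L) {
  layout <- cell$grid$layout
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", layout$chrom,
                     as.integer(layout$length)), con)
  b <- cell$grid$bins
  seq_str <- strrep("A", read_length)
  qn <- 0L
  for (i in seq_len(nrow(b))) {
    n <- cell$counts[i]
    if (n == 0) next
    span <- max(b$width[i] - read_length, 1)
    pos0 <- b$start[i] + floor((seq_len(n) - 1) * span / n)
    writeLines(sprintf("r%06d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                       qn + seq_len(n), b$chrom[i],
                       as.integer(pos0 + 1L), mapq, read_length, seq_str),
               con)
    qn <- qn + n
  }
  invisible(path)
}
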