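#' Build mappability-based variable-width bins
#'
#' Partitions each chromosome into non-overlapping bins of variable size such
#' that every bin holds (approximately) the same mappable mass. The number of
#' bins per chromosome is `round(chromosome length / target_width)` (at least
#' one), so the mean bin width tracks `target_width` while individual widths
#' shrink in well-mapped regions and grow in poorly mapped ones. Boundaries
#' are placed by greedy left-to-right accumulation: a bin is closed at the
#' first base where the cumulative mass reaches the per-bin quota; the last
#' bin absorbs the remainder of the chromosome.
#'
#' @param mappability the mappable-mass source. One of: a data.frame with
#'   columns `chrom`, `start`, `end`, `value` (a per-base mass density track,
#'   0-based half-open, bedGraph semantics); a data.frame with columns
#'   `chrom`, `pos` (0-based leftmost positions of aligned reads from a
#'   euploid reference library, each read contributing unit mass); or a file
#'   path to a bedGraph/BigWig track or a BAM/SAM alignment, dispatched on
#'   extension.
#' @param layout a [genome_layout()]. Every chromosome in the layout must be
#'   covered by the mappability source; a chromosome with zero total mass
#'   emits zero bins with a warning.
#' @param target_width target mean bin width in bp (default 1 Mb, minimum
#'   10 kb).
#' @return An object of class `bin_grid`: a list with elements `layout`,
#'   `bins` (data.frame `chrom`, `start`, `end`, `width`, `gc`, `mass`) and
#'   `target_width`. GC fractions are `NA` until assigned with
#'   [set_bin_gc()].
#' @seealso [uniform_bins()] for the constant-mappability special case,
#'   [apply_blacklist()], [bin_read_counts()].
#' @export
build_variable_bins <- function(mappability, layout, target_width = 1e6) {
  stopifnot(inherits(layout, "genome_layout"))
  if (target_width < 1e4) stop("target_width must be >= 10 kb")
  mass <- normalize_mappability(mappability)
  missing <- setdiff(layout$chrom, unique(mass$chrom))
  if (length(missing) > 0)
    stop("chromosome(s) absent from mappability source: ",
         paste(missing, collapse = ", "))

  pieces <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    chr <- layout$chrom[i]
    len <- layout$length[i]
    seg <- mass[mass$chrom == chr & mass$start < len, , drop = FALSE]
    seg$end <- pmin(seg$end, len)
    seg <- seg[seg$value > 0 & seg$end > seg$start, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    total <- sum((seg$end - seg$start) * seg$value)
    if (total <= 0) {
      warning("chromosome ", chr, " has zero mappable mass; emitting no bins")
      next
    }
    n_bins <- max(1L, as.integer(round(len / target_width)))
    quota <- total / n_bins
    ends <- greedy_boundaries(seg, quota, n_bins)
    ends <- unique(c(ends, len))
    starts <- c(0, ends[-length(ends)])
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    m <- interval_mass(seg, starts, ends)
    pieces[[i]] <- data.frame(chrom = chr, start = starts, end = ends,
                              width = ends - starts, gc = NA_real_,
                              mass = m, stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, pieces)
  rownames(bins) <- NULL
  structure(list(layout = layout, bins = bins, target_width = target_width),
            class = "bin_grid")
}

# place n_bins - 1 interior boundaries where cumulative mass crosses k * quota
greedy_boundaries <- function(seg, quota, n_bins) {
  if (n_bins <= 1L) return(numeric(0))
  w <- seg$end - seg$start
  segmass <- w * seg$value
  cum <- cumsum(segmass)
  cum0 <- c(0, cum[-length(cum)])
  targets <- quota * seq_len(n_bins - 1L)
  ends <- numeric(n_bins - 1L)
  for (k in seq_along(targets)) {
    j <- which(cum >= targets[k] - 1e-9)[1]
    if (is.na(j)) j <- length(cum)
    # first base b in segment j with cum0[j] + (b - start + 1) * v >= target
    nb <- ceiling((targets[k] - cum0[j]) / seg$value[j] - 1e-9)
    nb <- min(max(nb, 1), w[j])
    ends[k] <- seg$start[j] + nb
  }
  ends
}

# total mass of each [starts, ends) interval under the density segments
interval_mass <- function(seg, starts, ends) {
  vapply(seq_along(starts), function(i) {
    ov_lo <- pmax(seg$start, starts[i])
    ov_hi <- pmin(seg$end, ends[i])
    sum(pmax(ov_hi - ov_lo, 0) * seg$value)
  }, numeric(1))
}

# Reduce any accepted mappability representation to a density track
# data.frame(chrom, start, end, value); read positions become unit point
# masses of width 1.
normalize_mappability <- function(x) {
  if (is.character(x) && length(x) == 1) {
    ext <- tolower(tools::file_ext(x))
    if (ext %in% c("bam", "sam")) {
      pos <- read_positions(x)
      x <- data.frame(chrom = pos$chrom, pos = pos$pos,
                      stringsAsFactors = FALSE)
    } else {
      gr <- rtracklayer::import(x)
      val <- if (!is.null(gr$score)) as.numeric(gr$score) else rep(1, length(gr))
      x <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      value = val, stringsAsFactors = FALSE)
    }
  }
  stopifnot(is.data.frame(x))
  if (all(c("chrom", "pos") %in% names(x)) && !("value" %in% names(x))) {
    x <- x[order(x$chrom, x$pos), ]
    x <- data.frame(chrom = x$chrom, start = x$pos, end = x$pos + 1,
                    value = 1, stringsAsFactors = FALSE)
    # merge coincident reads into stacked mass
    key <- paste(x$chrom, x$start)
    agg <- stats::aggregate(x$value, by = list(key = key), FUN = sum)
    first <- !duplicated(key)
    x <- x[first, , drop = FALSE]
    x$value <- agg$x[match(paste(x$chrom, x$start), agg$key)]
  }
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  x
}

#' Fixed-width bins (constant-mappability limit)
#'
#' @param layout a [genome_layout()].
#' @param width bin width in bp.
#' @return A `bin_grid` whose bins all have width `width` except for the
#'   last bin of each chromosome, which absorbs the remainder.
#' @export
uniform_bins <- function(layout, width = 1e6) {
  track <- data.frame(chrom = layout$chrom, start = 0,
                      end = layout$length, value = 1,
                      stringsAsFactors = FALSE)
  build_variable_bins(track, layout, target_width = width)
}

#' Number of bins in a grid
#' @param grid a `bin_grid`.
#' @export
n_bins <- function(grid) nrow(grid$bins)

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf(
    "Bin grid: %d bins over %d chromosomes (target %.2g Mb, mean width %.2f Mb)\n",
    n_bins(x), length(unique(x$bins$chrom)), x$target_width / 1e6,
    mean(x$bins$width) / 1e6))
  invisible(x)
}

#' Assign GC fractions to bins
#'
#' @param grid a `bin_grid`.
#' @param gc either a numeric vector of per-bin GC fractions (in bin order)
#'   or a data.frame track (`chrom`, `start`, `end`, `gc`; 0-based half-open)
#'   averaged width-weighted over each bin.
#' @return The grid with `bins$gc` filled in.
#' @export
set_bin_gc <- function(grid, gc) {
  if (is.numeric(gc)) {
    stopifnot(length(gc) == n_bins(grid))
    grid$bins$gc <- as.numeric(gc)
  } else {
    stopifnot(is.data.frame(gc), all(c("chrom", "start", "end", "gc") %in% names(gc)))
    b <- grid$bins
    out <- rep(NA_real_, nrow(b))
    for (chr in unique(b$chrom)) {
      bi <- which(b$chrom == chr)
      tr <- gc[gc$chrom == chr, , drop = FALSE]
      if (nrow(tr) == 0) next
      out[bi] <- vapply(bi, function(i) {
        lo <- pmax(tr$start, b$start[i]); hi <- pmin(tr$end, b$end[i])
        w <- pmax(hi - lo, 0)
        if (sum(w) == 0) return(NA_real_)
        sum(w * tr$gc) / sum(w)
      }, numeric(1))
    }
    grid$bins$gc <- out
  }
  if (any(!is.na(grid$bins$gc) &
          (grid$bins$gc < 0 | grid$bins$gc > 1)))
    stop("GC fractions must lie in [0, 1]")
  grid
}

#' Remove bins overlapping blacklisted regions
#'
#' Bins whose overlap with the blacklist covers at least half of the bin
#' width are dropped; all other bins are untouched. The removed bins are
#' recorded in the `removed` attribute of the returned grid.
#'
#' @param grid a `bin_grid`.
#' @param blacklist a data.frame (`chrom`, `start`, `end`; 0-based
#'   half-open, same assembly as the grid) or a BED file path. Intervals on
#'   chromosomes unknown to the grid are skipped with a message.
#' @param min_overlap minimum overlapping fraction of the bin width for
#'   removal (default 0.5).
#' @return The filtered `bin_grid`.
#' @export
apply_blacklist <- function(grid, blacklist, min_overlap = 0.5) {
  if (is.character(blacklist) && length(blacklist) == 1) {
    gr <- rtracklayer::import(blacklist)
    blacklist <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                            start = GenomicRanges::start(gr) - 1L,
                            end = GenomicRanges::end(gr),
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(blacklist)))
  unknown <- setdiff(unique(blacklist$chrom), grid$layout$chrom)
  if (length(unknown) > 0) {
    message("skipping blacklist intervals on unknown chromosome(s): ",
            paste(unknown, collapse = ", "))
    blacklist <- blacklist[!blacklist$chrom %in% unknown, , drop = FALSE]
  }
  if (nrow(blacklist) == 0) {
    attr(grid, "removed") <- grid$bins[0, ]
    return(grid)
  }
  b <- grid$bins
  bl_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    blacklist$chrom, IRanges::IRanges(blacklist$start + 1L, blacklist$end)))
  bin_gr <- GenomicRanges::GRanges(
    b$chrom, IRanges::IRanges(b$start + 1L, b$end))
  hits <- GenomicRanges::findOverlaps(bin_gr, bl_gr)
  ov <- IRanges::width(IRanges::pintersect(
    bin_gr[S4Vectors_queryHits(hits)], bl_gr[S4Vectors_subjectHits(hits)]))
  ov_per_bin <- tapply(ov, S4Vectors_queryHits(hits), sum)
  frac <- rep(0, nrow(b))
  frac[as.integer(names(ov_per_bin))] <- as.numeric(ov_per_bin)
  frac <- frac / b$width
  drop <- frac >= min_overlap
  attr(grid, "removed") <- b[drop, , drop = FALSE]
  grid$bins <- b[!drop, , drop = FALSE]
  rownames(grid$bins) <- NULL
  grid
}

# thin indirection so the S4Vectors generics resolve without attaching
S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)

#' Write a bin grid as BED
#'
#' Columns: chrom, start, end, name (`bin_<i>`), score (mappable mass),
#' strand (`.`), GC fraction.
#'
#' @param grid a `bin_grid`.
#' @param path output file.
#' @export
write_bins_bed <- function(grid, path) {
  b <- grid$bins
  out <- data.frame(b$chrom, format(b$start, scientific = FALSE, trim = TRUE),
                    format(b$end, scientific = FALSE, trim = TRUE),
                    paste0("bin_", seq_len(nrow(b))), b$mass, ".", b$gc)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
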