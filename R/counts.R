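#' Per-cell binned read counts
#'
#' Container for one cell's raw (and, after [gc_correct()], GC-corrected)
#' per-bin read counts.
#'
#' @param cell_id cell / library identifier.
#' @param grid the `bin_grid` the counts refer to.
#' @param counts non-negative integer vector, one entry per bin.
#' @param corrected optional numeric vector of corrected counts.
#' @param discarded number of qualifying reads falling outside all bins.
#' @return An object of class `cell_counts`.
#' @export
cell_counts <- function(cell_id, grid, counts, corrected = NULL,
                        discarded = 0L) {
  stopifnot(inherits(grid, "bin_grid"), length(counts) == n_bins(grid),
            all(counts >= 0))
  structure(list(cell_id = as.character(cell_id), grid = grid,
                 counts = as.integer(round(counts)), corrected = corrected,
                 total_reads = sum(counts), discarded = as.integer(discarded)),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("Cell '%s': %d reads in %d bins (%d discarded)%s\n",
              x$cell_id, x$total_reads, n_bins(x$grid), x$discarded,
              if (is.null(x$corrected)) "" else ", GC-corrected"))
  invisible(x)
}

# counts used for model fitting: corrected if available, else raw
working_counts <- function(cell) {
  if (is.null(cell$corrected)) cell$counts else cell$corrected
}

#' Count aligned reads per bin
#'
#' Assigns each primary, mapped, sufficiently unique read to the bin
#' containing its leftmost mapped base. Secondary and supplementary
#' alignments are always skipped; duplicates are skipped when
#' `discard_duplicates` is set; for paired data only first-in-pair mates are
#' counted, matching single-end semantics. Qualifying reads that fall
#' outside every bin (e.g. on blacklisted territory) are tallied in the
#' `discarded` slot.
#'
#' @param file path to a coordinate-sorted BAM or SAM file (one library per
#'   cell). SAM input is converted on the fly.
#' @param grid a `bin_grid`.
#' @param min_mapq minimum mapping quality (default 10). Records with
#'   missing MAPQ (255) are kept.
#' @param discard_duplicates drop reads with the PCR/optical duplicate flag
#'   (default TRUE).
#' @param cell_id identifier for the resulting `cell_counts`; defaults to
#'   the file base name.
#' @return A [cell_counts()] with raw counts.
#' @export
count_reads <- function(file, grid, min_mapq = 10L, discard_duplicates = TRUE,
                        cell_id = NULL) {
  stopifnot(n_bins(grid) > 0)
  if (is.null(cell_id))
    cell_id <- sub("\\.(bam|sam)$", "", basename(file), ignore.case = TRUE)
  if (tolower(tools::file_ext(file)) == "sam") {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "mapq", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(file, param = param)[[1]]
  if (length(rec$pos) == 0) {
    warning("no mapped reads in ", basename(file), "; all counts zero")
    return(cell_counts(cell_id, grid, integer(n_bins(grid))))
  }
  fl <- rec$flag
  keep <- bitwAnd(fl, 0x100) == 0 & bitwAnd(fl, 0x800) == 0      # primary
  if (discard_duplicates) keep <- keep & bitwAnd(fl, 0x400) == 0
  keep <- keep & (bitwAnd(fl, 0x1) == 0 | bitwAnd(fl, 0x40) != 0) # first mate
  mq <- rec$mapq
  keep <- keep & (is.na(mq) | mq == 255L | mq >= min_mapq)
  chrom <- as.character(rec$rname)[keep]
  pos0 <- rec$pos[keep] - 1L                                      # 0-based
  bad <- setdiff(unique(chrom), grid$layout$chrom)
  if (length(bad) > 0)
    stop("alignment reference name(s) not in genome layout: ",
         paste(bad, collapse = ", "))
  b <- grid$bins
  x <- integer(nrow(b))
  discarded <- 0L
  for (chr in unique(chrom)) {
    p <- pos0[chrom == chr]
    bi <- which(b$chrom == chr)
    if (length(bi) == 0) { discarded <- discarded + length(p); next }
    idx <- findInterval(p, b$start[bi])
    inside <- idx >= 1 & p < b$end[bi][pmax(idx, 1)]
    discarded <- discarded + sum(!inside)
    tab <- tabulate(idx[inside], nbins = length(bi))
    x[bi] <- x[bi] + tab
  }
  cell_counts(cell_id, grid, x, discarded = discarded)
}

#' Correct per-bin counts for GC bias
#'
#' Fits the GC-bias trend as an ordinary least-squares quadratic of mean
#' count on GC fraction, computed over 0.01-wide GC strata holding at least
#' `min_stratum` bins (the strata-level fit prevents single outlier bins
#' from dominating). Each bin's count is then rescaled by the global mean
#' count over the fitted trend at its GC value:
#' \deqn{\tilde x_i = x_i \, \bar x / f(g_i).}
#' Bins whose fitted value is non-positive (outside the supported GC range)
#' keep their raw count.
#'
#' @param cell a [cell_counts()]; needs at least 50 bins with nonzero
#'   counts and a GC fraction for every bin.
#' @param min_stratum minimum bins per GC stratum entering the fit.
#' @return The `cell_counts` with the `corrected` slot filled.
#' @export
gc_correct <- function(cell, min_stratum = 5L) {
  g <- cell$grid$bins$gc
  if (anyNA(g)) stop("GC fraction missing for some bins; call set_bin_gc()")
  x <- as.numeric(cell$counts)
  if (all(x == 0)) {
    warning("all counts zero; no GC fit attempted")
    cell$corrected <- x
    return(cell)
  }
  if (sum(x > 0) < 50)
    stop("need >= 50 bins with nonzero counts for a GC fit")
  stratum <- floor(g / 0.01)
  agg <- stats::aggregate(x, by = list(stratum = stratum), FUN = mean)
  cnt <- table(stratum)
  agg$n <- as.integer(cnt[as.character(agg$stratum)])
  agg <- agg[agg$n >= min_stratum, , drop = FALSE]
  if (nrow(agg) < 3) stop("fewer than 3 usable GC strata; cannot fit trend")
  gc_mid <- (agg$stratum + 0.5) * 0.01
  fit <- stats::lm(agg$x ~ gc_mid + I(gc_mid^2))
  f <- as.numeric(cbind(1, g, g^2) %*% stats::coef(fit))
  xt <- x * mean(x) / f
  bad <- f <= 0 | !is.finite(xt)
  xt[bad] <- x[bad]
  cell$corrected <- xt
  cell
}

#' Write per-cell counts as TSV
#'
#' One row per bin with columns cell, chrom, start, end, raw and corrected
#' counts (corrected is NA before [gc_correct()]).
#'
#' @param cells a `cell_counts` or list of them (shared grid).
#' @param path output file.
#' @export
write_counts_tsv <- function(cells, path) {
  if (inherits(cells, "cell_counts")) cells <- list(cells)
  rows <- lapply(cells, function(cc) {
    b <- cc$grid$bins
    data.frame(cell = cc$cell_id, chrom = b$chrom, start = b$start,
               end = b$end, raw = cc$counts,
               corrected = if (is.null(cc$corrected)) NA_real_ else cc$corrected,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-cell counts from TSV written by [write_counts_tsv()]
#'
#' @param path TSV file.
#' @param grid the `bin_grid` the counts were produced on.
#' @return A list of `cell_counts`, one per distinct cell in the file.
#' @export
read_counts_tsv <- function(path, grid) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lapply(split(tab, factor(tab$cell, levels = unique(tab$cell))), function(d) {
    stopifnot(nrow(d) == n_bins(grid))
    corr <- if (all(is.na(d$corrected))) NULL else d$corrected
    cell_counts(d$cell[1], grid, d$raw, corrected = corr)
  })
}
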