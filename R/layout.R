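#' Define a genome layout
#'
#' A genome layout holds the ordered chromosome names, their lengths and the
#' per-chromosome baseline (euploid) copy number against which aneuploidy is
#' measured. Autosomes default to ploidy 2; allosomes can be set per sample
#' sex via the `ploidy` argument.
#'
#' @param chrom character vector of chromosome names, in genome order.
#' @param length integer vector of chromosome lengths in bp.
#' @param ploidy baseline copy number per chromosome; recycled if length 1.
#' @return An object of class `genome_layout`: a data.frame with columns
#'   `chrom`, `length`, `ploidy`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(5e6, 3e6))
#' @export
genome_layout <- function(chrom, length, ploidy = 2L) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  ploidy <- as.integer(rep_len(ploidy, base::length(chrom)))
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  if (any(ploidy < 1)) stop("baseline ploidy must be >= 1")
  out <- data.frame(chrom = chrom, length = length, ploidy = ploidy,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Read a genome layout from a chromosome-sizes file
#'
#' Parses the standard 2-column (name, length) whitespace-separated text
#' format.
#'
#' @param path path to the chromosome-sizes file.
#' @inheritParams genome_layout
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path, ploidy = 2L) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  genome_layout(tab[[1]], tab[[2]], ploidy)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("Genome layout: %d chromosomes, %.1f Mb total\n",
              nrow(x), sum(x$length) / 1e6))
  print.data.frame(x, ...)
  invisible(x)
}

baseline_of <- function(layout, chrom) {
  layout$ploidy[match(chrom, layout$chrom)]
}
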