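#' Pseudo-bulk aggregation of single-cell libraries
#'
#' Sums the raw per-bin counts over cells — emulating a bulk sequencing
#' experiment from the single-cell data — and derives a normalised
#' coverage track in copy-number units: counts per Mb, scaled so that the
#' population median sits at the baseline ploidy. Minority subclones are
#' averaged away in this view, which is exactly the contrast the
#' single-cell scores are designed to expose.
#'
#' @param cells list of [cell_counts()] on one shared grid.
#' @return An object of class `pseudo_bulk`: `grid`, `counts` (per-bin
#'   sums), `normalized` (per-bin coverage in copy units), `n_cells`.
#' @export
pseudobulk <- function(cells) {
  stopifnot(length(cells) >= 1)
  grid <- cells[[1]]$grid
  for (cc in cells)
    if (!identical(cc$grid$bins$start, grid$bins$start) ||
        !identical(cc$grid$bins$chrom, grid$bins$chrom))
      stop("cells do not share one bin grid")
  m <- do.call(rbind, lapply(cells, function(cc) cc$counts))
  total <- colSums(m)
  b <- grid$bins
  cov <- total / (b$width / 1e6)
  base <- baseline_of(grid$layout, b$chrom)
  norm <- cov / stats::median(cov / base)
  structure(list(grid = grid, counts = as.integer(total), normalized = norm,
                 n_cells = length(cells)),
            class = "pseudo_bulk")
}

#' @export
print.pseudo_bulk <- function(x, ...) {
  cat(sprintf("Pseudo-bulk of %d cells: %d bins, %d reads total\n",
              x$n_cells, n_bins(x$grid), sum(x$counts)))
  invisible(x)
}

#' Write a pseudo-bulk track as bedGraph
#' @param pb a `pseudo_bulk`.
#' @param path output file.
#' @param what `"normalized"` (copy units) or `"counts"`.
#' @export
write_pseudobulk_bedgraph <- function(pb, path, what = "normalized") {
  what <- match.arg(what, c("normalized", "counts"))
  b <- pb$grid$bins
  out <- data.frame(b$chrom,
                    format(b$start, scientific = FALSE, trim = TRUE),
                    format(b$end, scientific = FALSE, trim = TRUE),
                    pb[[what]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Cluster cells by copy-number profile similarity
#'
#' Pairwise distance between two cells is the width-weighted mean absolute
#' difference of their per-bin states (in copies); cells are clustered
#' hierarchically with average linkage and the dendrogram leaf order is
#' returned for heatmap display.
#'
#' @param profiles list of `cn_profile` (>= 2) on one shared grid.
#' @return A list with `order` (leaf order, indices into `profiles`),
#'   `hclust` (the tree), `dist` (the distance matrix) and `labels`.
#' @export
cluster_cells <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  st <- state_matrix(profiles)
  w <- profiles[[1]]$grid$bins$width
  w <- w / sum(w)
  n <- nrow(st)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- sum(w * abs(st[i, ] - st[j, ]))
    }
  labels <- vapply(profiles, function(p) p$cell_id, character(1))
  dimnames(d) <- list(labels, labels)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(order = hc$order, hclust = hc, dist = d, labels = labels)
}

#' Flag cells with an odd modal chromosome copy number
#'
#' For each cell the modal (width-weighted majority) state of every
#' chromosome is computed, ties broken toward even states; a cell is
#' flagged when any chromosome's modal state is odd. In a population
#' sorted for a doubled DNA content this separates genuinely
#' near-tetraploid cells (odd chromosome copies possible) from cells in
#' G2, which must carry even copy numbers throughout.
#'
#' @param profiles list of `cn_profile`.
#' @return A list with `flagged` (logical per cell), `cell_ids` of flagged
#'   cells and `modal_states` (cells x chromosomes matrix).
#' @export
odd_state_cells <- function(profiles) {
  grid <- profiles[[1]]$grid
  b <- grid$bins
  chroms <- unique(b$chrom)
  modal <- t(vapply(profiles, function(p) {
    vapply(chroms, function(ch) {
      bi <- b$chrom == ch
      modal_state(p$states[bi], b$width[bi])
    }, numeric(1))
  }, numeric(length(chroms))))
  colnames(modal) <- chroms
  flagged <- apply(modal %% 2 == 1, 1, any)
  list(flagged = flagged,
       cell_ids = vapply(profiles, function(p) p$cell_id,
                         character(1))[flagged],
       modal_states = modal)
}

# width-weighted majority state; ties broken toward even states
modal_state <- function(states, w) {
  mass <- tapply(w, states, sum)
  vals <- as.integer(names(mass))
  best <- mass == max(mass)
  cand <- vals[best]
  ev <- cand[cand %% 2 == 0]
  if (length(ev) > 0) ev[1] else cand[1]
}

#' Genome-wide copy-number heatmap
#'
#' Rows are cells (in clustering order), columns are bins in genome order,
#' colour encodes the copy-number state with a fixed palette for states
#' 0..10.
#'
#' @param profiles list of `cn_profile`.
#' @param order row order, e.g. from [cluster_cells()]; default as given.
#' @param file optional output path (`.png`); when `NULL`, draws on the
#'   active device.
#' @param c_max highest state in the colour scale.
#' @return Invisibly, the file path (or NULL).
#' @export
genomewide_heatmap <- function(profiles, order = NULL, file = NULL,
                               c_max = 10L) {
  st <- state_matrix(profiles)
  if (is.null(order)) order <- seq_len(nrow(st))
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 200 + 20 * nrow(st))
    on.exit(grDevices::dev.off())
  }
  pal <- state_palette(c_max)
  m <- t(st[order, , drop = FALSE])      # bins x cells for image()
  graphics::image(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                  z = pmin(m, c_max), breaks = seq(-0.5, c_max + 0.5, by = 1),
                  col = pal, xlab = "bin (genome order)", ylab = "cell",
                  yaxt = "n", main = "copy-number states")
  bnd <- cumsum(rle(profiles[[1]]$grid$bins$chrom)$lengths)
  graphics::abline(v = bnd[-length(bnd)] + 0.5, col = "white", lwd = 0.5)
  invisible(file)
}
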