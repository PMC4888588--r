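#' Aneuploidy score of a cell population
#'
#' Divergence of the population from the baseline euploid state. Per bin
#' the score is the mean absolute difference, over cells, between the
#' decoded copy number and the chromosome's baseline ploidy; bins are then
#' averaged weighted by their width (variable-width bins cover unequal
#' territory). Divergence is measured in absolute copies, without dividing
#' by the baseline ploidy. The score is 0 exactly when every cell is
#' everywhere at baseline.
#'
#' @param profiles list of `cn_profile` sharing one bin grid.
#' @param layout a [genome_layout()] providing per-chromosome baseline
#'   ploidy; defaults to the grid's layout.
#' @param scope `"genome"` for one genome-wide value or `"chromosome"` for
#'   a named per-chromosome vector.
#' @return Numeric score(s), >= 0.
#' @export
aneuploidy_score <- function(profiles, layout = NULL, scope = "genome") {
  st <- state_matrix(profiles)
  grid <- profiles[[1]]$grid
  if (is.null(layout)) layout <- grid$layout
  b <- grid$bins
  base <- baseline_of(layout, b$chrom)
  d <- colMeans(abs(sweep(st, 2, base)))
  weighted_by_scope(d, b, scope)
}

#' Karyotype heterogeneity score of a cell population
#'
#' Cell-to-cell karyotype variation. Per bin, the copy-number states of
#' all cells are tabulated and the frequencies sorted descending
#' (n1 >= n2 >= ...); the bin's heterogeneity is
#' \deqn{h_i = \sum_j (j - 1)\, n_{(j)} / n_{cells},}
#' so a clonal bin (one shared state) scores 0 and the score grows with
#' both the number and the size of minority karyotypes. Bins are averaged
#' weighted by width. A single-cell population scores 0 by definition.
#'
#' @inheritParams aneuploidy_score
#' @return Numeric score(s), >= 0.
#' @export
heterogeneity_score <- function(profiles, scope = "genome") {
  st <- state_matrix(profiles)
  b <- profiles[[1]]$grid$bins
  n <- nrow(st)
  h <- if (n < 2) rep(0, ncol(st)) else apply(st, 2, function(col) {
    f <- sort(tabulate(col + 1L), decreasing = TRUE)
    f <- f[f > 0]
    sum((seq_along(f) - 1) * f) / n
  })
  weighted_by_scope(h, b, scope)
}

#' Aneuploidy and heterogeneity per chromosome
#'
#' Both scores restricted to each chromosome's bins, in chromosome order —
#' the per-chromosome scatter view that separates clonal aberrations (high
#' aneuploidy, low heterogeneity) from unstable ones (high heterogeneity).
#'
#' @inheritParams aneuploidy_score
#' @return data.frame with columns `chrom`, `aneuploidy`, `heterogeneity`.
#' @export
per_chromosome_measures <- function(profiles, layout = NULL) {
  d <- aneuploidy_score(profiles, layout, scope = "chromosome")
  h <- heterogeneity_score(profiles, scope = "chromosome")
  out <- data.frame(chrom = names(d), aneuploidy = as.numeric(d),
                    heterogeneity = as.numeric(h), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Population karyotype measures
#'
#' Convenience wrapper computing the genome-wide and per-chromosome
#' aneuploidy and heterogeneity scores in one object.
#'
#' @inheritParams aneuploidy_score
#' @param population population identifier.
#' @return An object of class `karyotype_measures`: `population`,
#'   `aneuploidy`, `heterogeneity`, `per_chromosome`, `n_cells`.
#' @export
karyotype_measures <- function(profiles, layout = NULL,
                               population = "population") {
  structure(list(population = population,
                 aneuploidy = unname(aneuploidy_score(profiles, layout)),
                 heterogeneity = unname(heterogeneity_score(profiles)),
                 per_chromosome = per_chromosome_measures(profiles, layout),
                 n_cells = length(profiles)),
            class = "karyotype_measures")
}

#' @export
print.karyotype_measures <- function(x, ...) {
  cat(sprintf("Karyotype measures for '%s' (%d cells)\n", x$population,
              x$n_cells))
  cat(sprintf("  aneuploidy    D = %.4f\n  heterogeneity H = %.4f\n",
              x$aneuploidy, x$heterogeneity))
  cat("  per chromosome:\n")
  print(x$per_chromosome, row.names = FALSE)
  invisible(x)
}

#' Write karyotype scores as TSV
#'
#' Writes the genome-wide row plus one row per chromosome (matching the
#' per-chromosome scatter axes).
#' @param km a `karyotype_measures`.
#' @param path output file.
#' @export
write_scores_tsv <- function(km, path) {
  rows <- rbind(
    data.frame(population = km$population, scope = "genome",
               aneuploidy = km$aneuploidy, heterogeneity = km$heterogeneity,
               n_cells = km$n_cells, stringsAsFactors = FALSE),
    data.frame(population = km$population, scope = km$per_chromosome$chrom,
               aneuploidy = km$per_chromosome$aneuploidy,
               heterogeneity = km$per_chromosome$heterogeneity,
               n_cells = km$n_cells, stringsAsFactors = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# cells x bins state matrix; hard error on grid mismatch
state_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ref <- profiles[[1]]$grid$bins
  for (p in profiles) {
    b <- p$grid$bins
    if (nrow(b) != nrow(ref) ||
        !identical(b$chrom, ref$chrom) || !identical(b$start, ref$start))
      stop("profiles do not share one bin grid")
  }
  do.call(rbind, lapply(profiles, function(p) p$states))
}

weighted_by_scope <- function(v, bins, scope) {
  scope <- match.arg(scope, c("genome", "chromosome"))
  w <- bins$width
  if (scope == "genome") return(sum(w * v) / sum(w))
  chr <- factor(bins$chrom, levels = unique(bins$chrom))
  num <- tapply(w * v, chr, sum)
  den <- tapply(w, chr, sum)
  out <- as.numeric(num / den)
  names(out) <- levels(chr)
  out
}
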