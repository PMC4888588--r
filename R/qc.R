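#' Spikiness of a library
#'
#' Bin-to-bin read-count variation: the sum of absolute successive
#' differences of the raw counts in genome order, divided by the total
#' count. Differences are never taken across chromosome boundaries. The
#' metric is scale-free (invariant to uniform count scaling); noisy
#' libraries show high spikiness.
#'
#' @param cell a [cell_counts()] (raw counts are used) with at least 2
#'   bins and a positive total.
#' @return Non-negative scalar.
#' @export
spikiness <- function(cell) {
  x <- as.numeric(cell$counts)
  if (length(x) < 2) stop("need at least 2 bins")
  if (sum(x) == 0) stop("all counts zero; spikiness undefined")
  chr <- cell$grid$bins$chrom
  num <- 0
  for (ch in unique(chr)) {
    xi <- x[chr == ch]
    if (length(xi) > 1) num <- num + sum(abs(diff(xi)))
  }
  num / sum(x)
}

#' Number of copy-number segments in a profile
#'
#' Counts maximal runs of constant copy-number state, chromosomes counted
#' separately; clean near-clonal libraries have few segments (at least one
#' per covered chromosome), noisy ones fragment into many.
#'
#' @param profile a `cn_profile`.
#' @return Integer segment count.
#' @export
count_segments <- function(profile) {
  nrow(profile$segments)
}

#' Bhattacharyya distance between neighbouring emission distributions
#'
#' Separability of the fitted copy-1 and copy-2 negative binomial
#' emissions, the closest biologically meaningful state pair:
#' \deqn{BD = -\ln \sum_x \sqrt{P_1(x) P_2(x)}.}
#' The sum runs from 0 to the point where both pmfs have absorbed all but
#' `1e-12` of their mass. Well-separated states (high-quality libraries)
#' give large BD.
#'
#' @param model a fitted [emission_model()].
#' @param states the pair of copy-number states compared (default 1 and 2).
#' @return Non-negative scalar.
#' @export
bhattacharyya_distance <- function(model, states = c(1L, 2L)) {
  if (!inherits(model, "emission_model")) stop("need a fitted emission model")
  stopifnot(length(states) == 2, all(states >= 1), all(states <= model$c_max))
  r <- states * model$r1
  upper <- max(stats::qnbinom(1 - 1e-12, size = r, prob = model$p)) + 1L
  xs <- 0:upper
  bc <- sum(sqrt(stats::dnbinom(xs, size = r[1], prob = model$p) *
                 stats::dnbinom(xs, size = r[2], prob = model$p)))
  max(-log(min(bc, 1)), 0)
}

#' Assemble per-library quality metrics
#'
#' @param fits list of [karyo_hmm()] fits (one per cell).
#' @return data.frame with one row per cell: `cell`, `spikiness`,
#'   `loglik`, `loglik_per_bin`, `n_segments`, `bhattacharyya`,
#'   `total_reads`.
#' @export
quality_metrics <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(cell = f$cell$cell_id,
               spikiness = spikiness(f$cell),
               loglik = f$loglik,
               loglik_per_bin = f$loglik / n_bins(f$cell$grid),
               n_segments = count_segments(f$profile),
               bhattacharyya = bhattacharyya_distance(f$model),
               total_reads = f$cell$total_reads,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster libraries on quality metrics and select the best cluster
#'
#' Libraries with any non-finite metric are rejected up front. The four
#' quality features — spikiness, per-bin loglikelihood, segment count and
#' Bhattacharyya distance — are z-standardised and clustered hierarchically
#' (Ward linkage on Euclidean distance). The tree is cut at `k` in
#' `1..k_max` clusters, with `k` chosen by the mean silhouette width
#' (declaring no structure, `k = 1`, when the best silhouette falls below
#' `silhouette_floor`). The selected cluster is the one whose members have
#' the best mean rank over low spikiness, high Bhattacharyya distance, low
#' segment count and high loglikelihood.
#'
#' @param metrics data.frame from [quality_metrics()].
#' @param k_max maximum number of clusters (default 3).
#' @param silhouette_floor minimum mean silhouette for declaring more than
#'   one cluster (default 0.3).
#' @return The metrics data.frame with added columns `cluster` (NA for
#'   rejected libraries) and `selected` (logical).
#' @export
cluster_and_select <- function(metrics, k_max = 3L, silhouette_floor = 0.3) {
  stopifnot(is.data.frame(metrics))
  feat_names <- c("spikiness", "loglik_per_bin", "n_segments", "bhattacharyya")
  feats <- as.matrix(metrics[, feat_names])
  ok <- apply(feats, 1, function(r) all(is.finite(r)))
  metrics$cluster <- NA_integer_
  metrics$selected <- FALSE
  if (sum(ok) < 2) {
    warning("fewer than 2 usable libraries; selecting all of them")
    metrics$selected[ok] <- TRUE
    metrics$cluster[ok] <- 1L
    return(metrics)
  }
  z <- scale(feats[ok, , drop = FALSE])
  z[!is.finite(z)] <- 0            # zero-variance feature carries no signal
  d <- stats::dist(z)
  hc <- stats::hclust(d, method = "ward.D2")
  best_k <- 1L
  best_sil <- -Inf
  labels_by_k <- list()
  for (k in seq(2L, max(2L, k_max))) {
    if (k > sum(ok) - 1L || k > k_max) break
    lab <- stats::cutree(hc, k = k)
    labels_by_k[[k]] <- lab
    sil <- mean(cluster::silhouette(lab, d)[, "sil_width"])
    if (!is.na(sil) && sil > best_sil) {
      best_sil <- sil
      best_k <- k
    }
  }
  if (best_sil < silhouette_floor) best_k <- 1L
  lab <- if (best_k == 1L) rep(1L, sum(ok)) else labels_by_k[[best_k]]
  metrics$cluster[ok] <- lab
  # composite quality: mean rank over the four features, oriented so that
  # smaller rank = better library
  sub <- metrics[ok, , drop = FALSE]
  ranks <- cbind(rank(sub$spikiness),
                 rank(-sub$bhattacharyya),
                 rank(sub$n_segments),
                 rank(-sub$loglik_per_bin))
  lib_rank <- rowMeans(ranks)
  cluster_rank <- tapply(lib_rank, lab, mean)
  sel_cluster <- as.integer(names(which.min(cluster_rank)))
  metrics$selected[ok] <- lab == sel_cluster
  attr(metrics, "k") <- best_k
  attr(metrics, "silhouette") <- if (is.finite(best_sil)) best_sil else NA_real_
  attr(metrics, "selected_cluster") <- sel_cluster
  metrics
}

#' Write the QC report TSV
#' @param metrics output of [cluster_and_select()].
#' @param path output file.
#' @export
write_qc_tsv <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
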