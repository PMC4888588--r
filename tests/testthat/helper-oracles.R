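# Independent reference implementations used as oracles. These share no
# code with the package internals: the forward pass works in the log
# domain, posteriors come from exhaustive path enumeration, and the
# Bhattacharyya coefficient from dense summation.

# log-domain forward algorithm over independent sequences
forward_loglik_oracle <- function(logE, A, pi, seq_lengths) {
  logsumexp <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  total <- 0
  offset <- 0
  for (L in seq_lengths) {
    la <- log(pi) + logE[offset + 1, ]
    if (L > 1) for (t in 2:L) {
      la <- vapply(seq_along(la), function(j)
        logsumexp(la + log(A[, j])), numeric(1)) + logE[offset + t, ]
    }
    total <- total + logsumexp(la)
    offset <- offset + L
  }
  total
}

# exact posteriors by enumeration over all S^T hidden paths (one sequence)
enumerate_posteriors_oracle <- function(logE, A, pi) {
  T_ <- nrow(logE); S <- ncol(logE)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  logw <- apply(paths, 1, function(z) {
    lw <- log(pi[z[1]]) + logE[1, z[1]]
    if (T_ > 1) for (t in 2:T_)
      lw <- lw + log(A[z[t - 1], z[t]]) + logE[t, z[t]]
    lw
  })
  m <- max(logw)
  w <- exp(logw - m)
  gamma <- matrix(0, T_, S)
  for (t in seq_len(T_))
    for (s in seq_len(S))
      gamma[t, s] <- sum(w[paths[, t] == s])
  gamma <- gamma / sum(w)
  list(gamma = gamma, loglik = m + log(sum(w)))
}

# dense-summation Bhattacharyya distance between two NB pmfs
bd_oracle <- function(r1, r2, p, upper = NULL) {
  if (is.null(upper))
    upper <- max(qnbinom(1 - 1e-14, size = c(r1, r2), prob = p)) + 10
  xs <- 0:upper
  -log(sum(sqrt(dnbinom(xs, size = r1, prob = p) *
                dnbinom(xs, size = r2, prob = p))))
}

# tiny two-chromosome test genome with known GC
toy_grid <- function(n_chrom = 2, chrom_bins = 10, bin_width = 1e6,
                     gc = 0.42, ploidy = 2) {
  layout <- genome_layout(paste0("chr", seq_len(n_chrom)),
                          rep(chrom_bins * bin_width, n_chrom), ploidy)
  grid <- uniform_bins(layout, bin_width)
  set_bin_gc(grid, rep_len(gc, n_bins(grid)))
}

# profile with given per-bin states on a toy grid
toy_profile <- function(states, grid, cell_id = "c") {
  cn_profile(cell_id, grid, states)
}

# hand-written SAM file: reads at given 0-based positions
write_toy_sam <- function(path, layout, chrom, pos0, flag = 0L, mapq = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", layout$chrom,
                     as.integer(layout$length)), con)
  n <- length(pos0)
  flag <- rep_len(flag, n)
  mapq <- rep_len(mapq, n)
  ord <- order(match(chrom, layout$chrom), pos0)
  writeLines(sprintf("r%04d\t%d\t%s\t%d\t%d\t50M\t*\t0\t0\t%s\t*",
                     seq_len(n), flag[ord], chrom[ord],
                     as.integer(pos0[ord] + 1L), mapq[ord],
                     strrep("A", 50)), con)
  invisible(path)
}
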