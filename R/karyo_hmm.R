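#' Fit the single-cell copy-number model for one cell
#'
#' The main entry point of the package: runs initialisation
#' ([initialize_model()]), Baum-Welch fitting ([baum_welch_fit()]) and
#' maximum-posterior decoding ([decode()]) for one cell's binned counts and
#' returns a classed model object carrying both the fitted HMM and the
#' decoded copy-number profile. With `n_restarts > 1` the baseline mean is
#' perturbed multiplicatively (seeded) and the restart with the highest
#' loglikelihood is kept; restarts stay in the basin implied by
#' `most_frequent_state`, which steers the modal decoded copy number
#' through the initialisation (a soft constraint, recorded in the fit —
#' set it to 4 to force a near-tetraploid interpretation of the modal
#' count level and compare loglikelihoods).
#'
#' @param cell a [cell_counts()]; corrected counts are used when present.
#' @param c_max highest modelled copy number (default 10).
#' @param most_frequent_state copy number assumed for the modal count
#'   level (default 2).
#' @param tol relative loglikelihood convergence tolerance (default 1e-4).
#' @param max_iter maximum EM iterations (default 200).
#' @param n_restarts number of seeded restarts (default 3).
#' @param seed integer seed driving the restart perturbations; `NULL`
#'   leaves the RNG state alone.
#' @return An object of class `karyo_hmm` with components `model`
#'   ([emission_model()]), `A`, `pi`, `gamma`, `loglik`, `iterations`,
#'   `converged`, `restart` (index of the winning restart), `profile`
#'   (the decoded [cn_profile()]), `cell`, and the call.
#' @examples
#' layout <- synthetic_layout(n_chrom = 4, chrom_bins = 30)
#' truth <- simulate_karyotypes(layout, n_cells = 1, q = 0.3, seed = 7)
#' cell <- simulate_counts(truth, reads_per_cell = 6000, seed = 7)[[1]]
#' fit <- karyo_hmm(cell, seed = 1)
#' fit
#' table(fit$profile$states)
#' @export
karyo_hmm <- function(cell, c_max = 10L, most_frequent_state = 2L,
                      tol = 1e-4, max_iter = 200L, n_restarts = 3L,
                      seed = NULL) {
  stopifnot(inherits(cell, "cell_counts"), n_restarts >= 1)
  init <- initialize_model(cell, c_max, most_frequent_state)
  factors <- 1
  if (n_restarts > 1) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    factors <- c(1, exp(stats::runif(n_restarts - 1, log(0.85), log(1.18))))
  }
  fits <- vector("list", length(factors))
  for (k in seq_along(factors)) {
    ini_k <- init
    if (factors[k] != 1) {
      mu1 <- init$model$mu1 * factors[k]
      r1 <- init$model$r1
      ini_k$model <- emission_model(r1, r1 / (r1 + mu1), c_max)
    }
    fits[[k]] <- baum_welch_fit(cell, ini_k, tol = tol, max_iter = max_iter)
  }
  # keep the highest-loglikelihood restart, honouring the soft ploidy
  # steer: restarts whose modal decoded state matches most_frequent_state
  # take precedence, so a restart drifting to a rescaled copy-number
  # interpretation (the intrinsic scale ambiguity of count-only data)
  # cannot override the requested baseline
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  modal <- vapply(fits, modal_decoded_state, integer(1))
  pool <- which(modal == most_frequent_state)
  if (length(pool) == 0) pool <- seq_along(fits)
  best_k <- pool[which.max(ll[pool])]
  best <- fits[[best_k]]
  # steering refit: when no restart decodes the requested modal ploidy,
  # reinterpret the fitted modal count level at most_frequent_state copies
  # and refit from there; kept only if it realises the requested ploidy
  if (modal[best_k] != most_frequent_state && modal[best_k] > 0) {
    mu1 <- best$model$mu1 * modal[best_k] / most_frequent_state
    r1 <- best$model$r1
    steer <- list(model = emission_model(r1, r1 / (r1 + mu1), c_max),
                  A = best$A, pi = best$pi)
    refit <- baum_welch_fit(cell, steer, tol = tol, max_iter = max_iter)
    if (modal_decoded_state(refit) == most_frequent_state) {
      best <- refit
      best_k <- 0L
    }
  }
  best$cell <- cell
  best$most_frequent_state <- as.integer(most_frequent_state)
  best$restart <- best_k
  best$profile <- decode(best, cell)
  best$call <- match.call()
  class(best) <- c("karyo_hmm", "hmm_fit")
  best
}

# most frequent decoded state of a raw fit
modal_decoded_state <- function(fit) {
  st <- max.col(fit$gamma, ties.method = "first") - 1L
  as.integer(names(which.max(table(st))))
}

#' @export
print.karyo_hmm <- function(x, ...) {
  cat("Single-cell copy-number HMM fit\n")
  cat(sprintf("  cell: %s  (%d bins, %d reads)\n", x$cell$cell_id,
              n_bins(x$cell$grid), x$cell$total_reads))
  cat(sprintf("  baseline mean mu1 = %.3f (r1 = %.3f, p = %.4f), states 0..%d\n",
              x$model$mu1, x$model$r1, x$model$p, x$model$c_max))
  cat(sprintf("  loglik = %.2f after %d EM iterations (%s)\n", x$loglik,
              x$iterations, if (x$converged) "converged" else "not converged"))
  tab <- table(factor(x$profile$states, levels = 0:x$model$c_max))
  tab <- tab[tab > 0]
  cat("  decoded states: ",
      paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

#' @method summary karyo_hmm
#' @export
summary.karyo_hmm <- function(object, ...) {
  prof <- object$profile
  modal <- as.integer(names(which.max(table(prof$states))))
  out <- list(cell_id = object$cell$cell_id,
              mu1 = object$model$mu1, r1 = object$model$r1, p = object$model$p,
              loglik = object$loglik, iterations = object$iterations,
              converged = object$converged,
              n_segments = nrow(prof$segments),
              modal_state = modal,
              mean_max_posterior = mean(prof$max_posterior),
              spikiness = spikiness(object$cell),
              bhattacharyya = bhattacharyya_distance(object$model))
  class(out) <- "summary.karyo_hmm"
  out
}

#' @export
print.summary.karyo_hmm <- function(x, ...) {
  cat(sprintf("Cell %s: modal state %d, %d segments\n", x$cell_id,
              x$modal_state, x$n_segments))
  cat(sprintf("  mu1 = %.3f, r1 = %.3f, p = %.4f, loglik = %.2f (%d iter%s)\n",
              x$mu1, x$r1, x$p, x$loglik, x$iterations,
              if (x$converged) ", converged" else ""))
  cat(sprintf("  QC: spikiness %.3f, Bhattacharyya %.3f, mean max posterior %.3f\n",
              x$spikiness, x$bhattacharyya, x$mean_max_posterior))
  invisible(x)
}

#' @method coef karyo_hmm
#' @export
coef.karyo_hmm <- function(object, ...) {
  c(mu1 = object$model$mu1, r1 = object$model$r1, p = object$model$p)
}

#' @method logLik karyo_hmm
#' @export
logLik.karyo_hmm <- function(object, ...) {
  structure(object$loglik, df = 3 + length(object$pi) * length(object$pi),
            nobs = n_bins(object$cell$grid), class = "logLik")
}

#' @export
fitted.karyo_hmm <- function(object, ...) {
  object$profile$states * object$model$mu1
}

#' Pearson residuals of a fitted copy-number model
#'
#' Computed against the decoded state's emission distribution: mean
#' `c * mu1`, variance `c * mu1 / p` (state 0 uses the copy-1 variance so
#' zero-count bins in nullisomic regions get residual 0 rather than 0/0).
#' @param object a `karyo_hmm` fit.
#' @param ... unused.
#' @method residuals karyo_hmm
#' @export
residuals.karyo_hmm <- function(object, ...) {
  x <- round(working_counts(object$cell))
  st <- object$profile$states
  mu <- st * object$model$mu1
  v <- pmax(st, 1) * object$model$mu1 / object$model$p
  (x - mu) / sqrt(v)
}

#' Simulate counts from a fitted copy-number HMM
#'
#' Draws hidden state paths from the fitted Markov chain (per chromosome,
#' starting from the fitted initial distribution) and counts from the tied
#' NB emissions — a parametric-bootstrap generator for the fitted cell.
#'
#' @param object a `karyo_hmm` fit.
#' @param nsim number of replicate cells.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `cell_counts` of length `nsim`.
#' @export
simulate.karyo_hmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  grid <- object$cell$grid
  seqs <- sequence_index(grid)
  S <- object$model$c_max + 1L
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    states <- integer(n_bins(grid))
    for (q in seq_along(seqs$start)) {
      idx <- seqs$start[q] + seq_len(seqs$len[q])
      st <- integer(seqs$len[q])
      st[1] <- sample.int(S, 1, prob = object$pi) - 1L
      for (t in seq_len(seqs$len[q] - 1L))
        st[t + 1L] <- sample.int(S, 1, prob = object$A[st[t] + 1L, ]) - 1L
      states[idx] <- st
    }
    x <- integer(length(states))
    nz <- states > 0
    x[nz] <- stats::rnbinom(sum(nz), size = states[nz] * object$model$r1,
                            prob = object$model$p)
    out[[s]] <- cell_counts(paste0(object$cell$cell_id, "_sim", s), grid, x)
  }
  out
}

#' Plot a fitted copy-number profile
#'
#' Binned counts along the genome, coloured by decoded copy-number state,
#' with chromosome boundaries and the fitted state means as guides.
#'
#' @param x a `karyo_hmm` fit.
#' @param max_state highest state to draw a mean line for.
#' @param ... passed to [graphics::plot()].
#' @method plot karyo_hmm
#' @export
plot.karyo_hmm <- function(x, max_state = 6, ...) {
  cnt <- round(working_counts(x$cell))
  st <- x$profile$states
  pal <- state_palette(x$model$c_max)
  graphics::plot(seq_along(cnt), cnt, pch = 16, cex = 0.5,
                 col = pal[st + 1L], xlab = "bin (genome order)",
                 ylab = "read count", ...)
  for (cc in seq_len(max_state))
    graphics::abline(h = cc * x$model$mu1, col = "grey70", lty = 3)
  bnd <- cumsum(rle(x$cell$grid$bins$chrom)$lengths)
  graphics::abline(v = bnd[-length(bnd)] + 0.5, col = "grey40", lty = 2)
  invisible(x)
}

# fixed palette for states 0..c_max (0 = dark blue through red/brown gains)
state_palette <- function(c_max = 10L) {
  base <- c("#1F78B4", "#A6CEE3", "#CCCCCC", "#FB9A99", "#E31A1C",
            "#B2DF8A", "#33A02C", "#FDBF6F", "#FF7F00", "#CAB2D6", "#6A3D9A")
  rep_len(base, c_max + 1L)
}

#' Write fitted model parameters as a key-value text file
#' @param fit a `karyo_hmm` or `hmm_fit`.
#' @param path output file.
#' @export
write_model_params <- function(fit, path) {
  kv <- c(r1 = fit$model$r1, p = fit$model$p, mu1 = fit$model$mu1,
          c_max = fit$model$c_max, loglik = fit$loglik,
          iterations = fit$iterations, converged = as.integer(fit$converged))
  writeLines(sprintf("%s\t%s", names(kv), format(kv, digits = 12)), path)
  invisible(path)
}
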