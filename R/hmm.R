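#' @useDynLib karyoHMM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DELTA_FLOOR <- -1e10

#' Copy-number emission model
#'
#' The hidden states are integer copy numbers `0..c_max`. State 0
#' (nullisomy) is a delta distribution at count zero; every state `c >= 1`
#' is a negative binomial with size `c * r1` and shared success probability
#' `p`, so the state means scale linearly with copy number
#' (`mean(c) = c * mu1` with `mu1 = r1 (1 - p) / p`) and so does the
#' variance. The tying keeps the model identifiable at single-cell depth.
#'
#' @param r1 size parameter of the copy-1 state (> 0).
#' @param p shared NB success probability, in (0, 1).
#' @param c_max highest modelled copy number (default 10, decasomy).
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(r1, p, c_max = 10L) {
  stopifnot(r1 > 0, p > 0, p < 1, c_max >= 1)
  structure(list(r1 = r1, p = p, c_max = as.integer(c_max),
                 mu1 = r1 * (1 - p) / p),
            class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
  cat(sprintf(
    "NB emission model: %d states (0..%d), mu1 = %.3f (r1 = %.3f, p = %.4f)\n",
    x$c_max + 1L, x$c_max, x$mu1, x$r1, x$p))
  invisible(x)
}

#' Emission log-probability of a count under one copy-number state
#'
#' State 0 is a point mass at zero: log-probability 0 for `x == 0` and a
#' finite floor (`-1e10`) otherwise, kept finite so downstream arithmetic
#' never propagates `-Inf`. States `c >= 1` evaluate the tied negative
#' binomial `NB(c * r1, p)`.
#'
#' @param state integer copy-number state in `0..c_max`.
#' @param x non-negative integer count (vectorised).
#' @param model an [emission_model()].
#' @return log-probabilities, same length as `x`.
#' @export
emission_logpmf <- function(state, x, model) {
  stopifnot(state >= 0, state <= model$c_max, all(x >= 0))
  if (state == 0) return(ifelse(x == 0, 0, DELTA_FLOOR))
  stats::dnbinom(x, size = state * model$r1, prob = model$p, log = TRUE)
}

# T x (c_max + 1) matrix of emission log-probabilities; computed on the
# unique count values and expanded, since low-coverage bins repeat counts
emission_logmatrix <- function(x, model) {
  u <- sort(unique(x))
  S <- model$c_max + 1L
  lu <- matrix(DELTA_FLOOR, nrow = length(u), ncol = S)
  lu[u == 0, 1] <- 0
  for (cc in seq_len(model$c_max))
    lu[, cc + 1L] <- stats::dnbinom(u, size = cc * model$r1, prob = model$p,
                                    log = TRUE)
  lu[match(x, u), , drop = FALSE]
}

#' Initialise the copy-number HMM for one cell
#'
#' The baseline mean `mu1` starts at the mode of the nonzero (corrected)
#' counts divided by `most_frequent_state`, so that the most common count
#' level is interpreted as that copy number; `r1` follows by
#' method-of-moments on the counts scaled to copy 1. Transitions start
#' sticky (self-transition 0.99, remainder uniform) and the initial
#' distribution is uniform.
#'
#' @param cell a [cell_counts()] (corrected counts used when present).
#' @param c_max highest modelled copy number.
#' @param most_frequent_state copy number assumed for the modal count level
#'   (default 2, disomy; set 4 to force a near-tetraploid interpretation).
#' @return A list with elements `model` ([emission_model()]), `A`
#'   (row-stochastic transition matrix) and `pi` (initial distribution).
#' @export
initialize_model <- function(cell, c_max = 10L, most_frequent_state = 2L) {
  stopifnot(most_frequent_state >= 1, most_frequent_state <= c_max)
  x <- round(working_counts(cell))
  xnz <- x[x > 0]
  if (length(xnz) == 0) stop("degenerate library: all counts zero")
  mode_x <- if (length(xnz) >= 10) {
    d <- stats::density(xnz)
    d$x[which.max(d$y)]
  } else stats::median(xnz)
  # the raw density mode of a skewed NB sits below the component mean;
  # anchor a window at the mode and take its mean as the modal count level
  win <- xnz[xnz >= 0.7 * mode_x & xnz <= 1.4 * mode_x]
  level <- if (length(win) >= 10) mean(win) else mode_x
  mu1 <- max(level / most_frequent_state, 0.5)
  v <- stats::var(win) / most_frequent_state
  r1 <- if (length(win) >= 10 && is.finite(v) && v > mu1)
    mu1^2 / (v - mu1) else mu1
  r1 <- min(max(r1, 1e-3), 1e6)
  p <- r1 / (r1 + mu1)
  S <- c_max + 1L
  A <- matrix(0.01 / (S - 1), S, S)
  diag(A) <- 0.99
  list(model = emission_model(r1, p, c_max),
       A = A, pi = rep(1 / S, S))
}

# independent observation sequences: one per chromosome, in grid order
sequence_index <- function(grid) {
  chr <- grid$bins$chrom
  r <- rle(chr)
  len <- r$lengths
  start0 <- cumsum(c(0L, len[-length(len)]))
  list(start = as.integer(start0), len = as.integer(len))
}

#' Fit the copy-number HMM by Baum-Welch
#'
#' Runs expectation-maximisation with the standard scaled forward-backward
#' recursions, treating each chromosome as an independent observation
#' sequence sharing one parameter set. The M-step updates the initial
#' distribution and transition matrix in closed form and the tied NB
#' parameters `(r1, p)` by one-dimensional bounded maximisation of the
#' expected loglikelihood over `r1`, with `p` profiled from the
#' expected-mean constraint (no closed form exists under the tying rule).
#' Corrected counts are rounded to the nearest integer for emission
#' evaluation. The loglikelihood is checked to be non-decreasing; a decrease
#' beyond numerical slack is an error.
#'
#' @param cell a [cell_counts()] with at least 20 bins.
#' @param init model triple from [initialize_model()] (model, A, pi).
#' @param tol relative loglikelihood improvement below which EM stops
#'   (default 1e-4); `Inf` performs a single evaluation of the initial
#'   model.
#' @param max_iter maximum EM iterations (default 200).
#' @return A list of class `hmm_fit`: `model`, `A`, `pi`, `gamma` (bins x
#'   states posterior matrix), `loglik`, `iterations`, `converged`.
#' @export
baum_welch_fit <- function(cell, init, tol = 1e-4, max_iter = 200L) {
  grid <- cell$grid
  if (n_bins(grid) < 20) stop("need at least 20 bins to fit the HMM")
  x <- as.integer(round(working_counts(cell)))
  seqs <- sequence_index(grid)
  model <- init$model
  A <- init$A
  pi <- init$pi
  S <- model$c_max + 1L
  u <- sort(unique(x))
  xf <- factor(x, levels = u)

  loglik_prev <- NA_real_
  converged <- FALSE
  iter <- 0L
  gamma <- NULL
  loglik <- NA_real_

  for (t in seq_len(max_iter)) {
    iter <- t
    logE <- emission_logmatrix(x, model)
    shift <- apply(logE, 1, max)
    E <- exp(logE - shift)
    fb <- fb_pass(E, A, pi, seqs$start, seqs$len)
    gamma <- fb$gamma
    loglik <- fb$loglik + sum(shift)
    if (!is.finite(loglik))
      stop("non-finite loglikelihood at EM iteration ", t)
    if (t > 1) {
      if (loglik < loglik_prev - 1e-6 * (1 + abs(loglik_prev)))
        stop("monotonicity violated at EM iteration ", t,
             " (", loglik_prev, " -> ", loglik, ")")
      if ((loglik - loglik_prev) / abs(loglik_prev) < tol) {
        converged <- TRUE
        break
      }
    } else if (is.infinite(tol)) {
      converged <- TRUE
      break
    }
    loglik_prev <- loglik
    if (t == max_iter) break

    # M-step: closed-form pi and A
    pi <- fb$start_gamma / sum(fb$start_gamma)
    rs <- rowSums(fb$xi_sum)
    keep <- rs > 0
    A_new <- A
    A_new[keep, ] <- fb$xi_sum[keep, , drop = FALSE] / rs[keep]
    A <- A_new
    # M-step: (r1, p) by profile maximisation under the tying rule
    model <- update_emissions(model, gamma, xf, u)
  }
  structure(list(model = model, A = A, pi = pi, gamma = gamma,
                 loglik = loglik, iterations = iter, converged = converged),
            class = "hmm_fit")
}

# expected NB loglikelihood aggregated over unique count values
update_emissions <- function(model, gamma, xf, u) {
  c_max <- model$c_max
  W <- rowsum(gamma[, -1, drop = FALSE], group = xf)   # |u| x c_max
  colmass <- colSums(W)
  den <- sum(colmass * seq_len(c_max))
  if (den <= 0) return(model)
  mu1 <- sum(colSums(W * u)) / den
  if (mu1 <= 0) return(model)
  qfun <- function(lr) {
    r1 <- exp(lr)
    p <- r1 / (r1 + mu1)
    q <- 0
    for (cc in seq_len(c_max)) {
      if (colmass[cc] == 0) next
      q <- q + sum(W[, cc] * stats::dnbinom(u, size = cc * r1, prob = p,
                                            log = TRUE))
    }
    q
  }
  opt <- stats::optimize(qfun, interval = log(model$r1) + c(-6, 6),
                         maximum = TRUE, tol = 1e-8)
  # expected loglik under the current parameters, as a safeguard: never
  # accept an update that lowers the EM objective
  q_old <- {
    q <- 0
    for (cc in seq_len(c_max)) {
      if (colmass[cc] == 0) next
      q <- q + sum(W[, cc] * stats::dnbinom(u, size = cc * model$r1,
                                            prob = model$p, log = TRUE))
    }
    q
  }
  if (opt$objective >= q_old) {
    r1 <- exp(opt$maximum)
    emission_model(r1, r1 / (r1 + mu1), c_max)
  } else {
    model
  }
}

#' Decode a fitted HMM into a copy-number profile
#'
#' Each bin is assigned the copy-number state with the highest posterior
#' probability; exact ties are broken toward the lower state (conservative
#' calls). Maximal runs of constant state within a chromosome form the
#' derived segments.
#'
#' @param fit an `hmm_fit` (or a [karyo_hmm()] object).
#' @param cell the [cell_counts()] the fit refers to; taken from the fit
#'   when it carries one.
#' @return An object of class `cn_profile`: `cell_id`, `grid`, `states`
#'   (integer per bin), `max_posterior`, `segments` (data.frame `chrom`,
#'   `start`, `end`, `state`, `n_bins`).
#' @export
decode <- function(fit, cell = fit$cell) {
  gamma <- fit$gamma
  stopifnot(all(is.finite(gamma)))
  states <- max.col(gamma, ties.method = "first") - 1L
  maxpost <- gamma[cbind(seq_len(nrow(gamma)), states + 1L)]
  cn_profile(cell$cell_id, cell$grid, states, maxpost)
}

#' Construct a copy-number profile from per-bin states
#'
#' @param cell_id cell identifier.
#' @param grid the `bin_grid`.
#' @param states integer per-bin copy-number states.
#' @param max_posterior optional per-bin maximum posterior probability.
#' @return A `cn_profile`.
#' @export
cn_profile <- function(cell_id, grid, states, max_posterior = NULL) {
  stopifnot(length(states) == n_bins(grid), all(states >= 0))
  if (is.null(max_posterior)) max_posterior <- rep(1, length(states))
  structure(list(cell_id = as.character(cell_id), grid = grid,
                 states = as.integer(states),
                 max_posterior = as.numeric(max_posterior),
                 segments = segments_from_states(grid, states)),
            class = "cn_profile")
}

segments_from_states <- function(grid, states) {
  b <- grid$bins
  out <- list()
  idx <- 0L
  for (chr in unique(b$chrom)) {
    bi <- which(b$chrom == chr)
    r <- rle(states[bi])
    hi <- cumsum(r$lengths)
    lo <- c(1L, hi[-length(hi)] + 1L)
    idx <- idx + 1L
    out[[idx]] <- data.frame(chrom = chr,
                             start = b$start[bi][lo], end = b$end[bi][hi],
                             state = r$values, n_bins = r$lengths,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.cn_profile <- function(x, ...) {
  tab <- table(x$states)
  cat(sprintf("Copy-number profile '%s': %d bins, %d segments; states: %s\n",
              x$cell_id, length(x$states), nrow(x$segments),
              paste(sprintf("%s:%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Write a copy-number profile as BED
#'
#' One row per bin: chrom, start, end, name = copy-number state, score =
#' `floor(1000 * max posterior)`, for loading into a genome browser.
#'
#' @param profile a `cn_profile`.
#' @param path output file.
#' @export
write_profile_bed <- function(profile, path) {
  b <- profile$grid$bins
  out <- data.frame(b$chrom,
                    format(b$start, scientific = FALSE, trim = TRUE),
                    format(b$end, scientific = FALSE, trim = TRUE),
                    profile$states,
                    floor(1000 * pmin(profile$max_posterior, 1)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write profile segments as TSV
#' @param profile a `cn_profile`.
#' @param path output file.
#' @export
write_segments_tsv <- function(profile, path) {
  seg <- cbind(cell = profile$cell_id, profile$segments)
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
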