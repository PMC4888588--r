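test_that("emission distributions follow the delta + tied-NB family", {
  m <- emission_model(r1 = 5, p = 0.2, c_max = 10)
  # delta nullisomy
  expect_equal(emission_logpmf(0, 0, m), 0)
  expect_lt(emission_logpmf(0, 7, m), -1e9)
  # state c >= 1: NB with size c*r1, checked against a term-by-term
  # log-gamma evaluation of the pmf
  for (k in c(0, 3, 17, 120)) {
    r <- 2 * m$r1
    oracle <- lgamma(k + r) - lgamma(r) - lgamma(k + 1) +
      r * log(m$p) + k * log(1 - m$p)
    expect_equal(emission_logpmf(2, k, m), oracle, tolerance = 1e-10)
  }
  # tying: mean of state c is exactly c * mu1
  for (cc in 1:10) {
    expect_equal(cc * m$r1 * (1 - m$p) / m$p, cc * m$mu1, tolerance = 1e-12)
  }
})

test_that("default state space spans nullisomy to decasomy", {
  grid <- toy_grid(n_chrom = 1, chrom_bins = 100)
  set.seed(1)
  cell <- cell_counts("c", grid, rnbinom(100, mu = 100, size = 20))
  init <- initialize_model(cell, c_max = 10)
  expect_equal(length(init$pi), 11)
  expect_equal(dim(init$A), c(11, 11))
  expect_equal(rowSums(init$A), rep(1, 11), tolerance = 1e-12)
})

test_that("initialisation anchors mu1 at the modal count level", {
  grid <- toy_grid(n_chrom = 1, chrom_bins = 500)
  set.seed(31)
  cell <- cell_counts("c", grid, rnbinom(500, mu = 100, size = 20))
  init2 <- initialize_model(cell, most_frequent_state = 2)
  expect_lt(abs(init2$model$mu1 - 50) / 50, 0.2)
  init4 <- initialize_model(cell, most_frequent_state = 4)
  expect_equal(init4$model$mu1, init2$model$mu1 / 2, tolerance = 1e-9)
  zero <- cell_counts("z", grid, integer(500))
  expect_error(initialize_model(zero), "degenerate")
})

test_that("forward-backward posteriors match exhaustive path enumeration", {
  set.seed(123)
  for (rep in 1:5) {
    T_ <- sample(4:8, 1)
    S <- sample(2:4, 1)
    A <- matrix(rexp(S * S), S)
    A <- A / rowSums(A)
    pi <- rexp(S); pi <- pi / sum(pi)
    logE <- matrix(log(runif(T_ * S, 0.01, 1)), T_, S)
    oracle <- enumerate_posteriors_oracle(logE, A, pi)
    shift <- apply(logE, 1, max)
    fb <- karyoHMM:::fb_pass(exp(logE - shift), A, pi, 0L, T_)
    expect_equal(fb$gamma, oracle$gamma, tolerance = 1e-10)
    expect_equal(fb$loglik + sum(shift), oracle$loglik, tolerance = 1e-10)
    expect_equal(rowSums(fb$gamma), rep(1, T_), tolerance = 1e-9)
  }
})

test_that("a single EM evaluation reproduces the forward-pass loglikelihood", {
  layout <- synthetic_layout(n_chrom = 3, chrom_bins = 40)
  truth <- simulate_karyotypes(layout, 1, q = 0.2, seed = 4)
  cell <- simulate_counts(truth, reads_per_cell = 8000, seed = 4)[[1]]
  init <- initialize_model(cell)
  fit <- baum_welch_fit(cell, init, tol = Inf)
  expect_equal(fit$iterations, 1L)
  x <- round(cell$counts)
  logE <- sapply(0:10, function(s) emission_logpmf(s, x, init$model))
  oracle <- forward_loglik_oracle(logE, init$A, init$pi, rep(40, 3))
  expect_equal(fit$loglik, oracle, tolerance = 1e-8)
})

test_that("EM increases the loglikelihood monotonically to convergence", {
  layout <- synthetic_layout(n_chrom = 4, chrom_bins = 50)
  truth <- simulate_karyotypes(layout, 3, q = 0.25, seed = 9)
  cells <- simulate_counts(truth, reads_per_cell = 10000, seed = 9)
  for (cell in cells) {
    init <- initialize_model(cell)
    lls <- vapply(1:6, function(k)
      baum_welch_fit(cell, init, tol = 0, max_iter = k)$loglik, numeric(1))
    expect_true(all(diff(lls) >= -1e-6 * (1 + abs(lls[-6]))))
    fit <- baum_welch_fit(cell, init)
    expect_true(fit$converged)
    expect_equal(rowSums(fit$gamma), rep(1, n_bins(cell$grid)),
                 tolerance = 1e-9)
  }
})

test_that("parameters and states are recovered from model-simulated data", {
  # 2,000 bins drawn from the model itself: sticky Markov chain over
  # states {1,2,3} and tied-NB emissions
  set.seed(17)
  grid <- toy_grid(n_chrom = 4, chrom_bins = 500)
  mu1 <- 44; r1 <- 8; p <- r1 / (r1 + mu1)
  A3 <- matrix(0.005, 3, 3); diag(A3) <- 0.99
  states <- integer(2000)
  for (ch in 0:3) {
    idx <- ch * 500 + 1:500
    s <- integer(500)
    s[1] <- sample(1:3, 1)
    for (t in 2:500) s[t] <- sample(1:3, 1, prob = A3[s[t - 1], ])
    states[idx] <- s
  }
  x <- rnbinom(2000, size = states * r1, prob = p)
  cell <- cell_counts("m", grid, x)
  mfs <- as.integer(names(which.max(table(states))))
  fit <- karyo_hmm(cell, most_frequent_state = mfs, n_restarts = 1)
  expect_lt(abs(coef(fit)["mu1"] - mu1) / mu1, 0.05)
  expect_gte(mean(fit$profile$states == states), 0.99)
})

test_that("constant disomic counts decode entirely disomic", {
  grid <- toy_grid(n_chrom = 1, chrom_bins = 100)
  init <- initialize_model(cell_counts("c", grid,
                                       rnbinom(100, mu = 60, size = 30)))
  cell <- cell_counts("c", grid, rep(round(2 * init$model$mu1), 100))
  fit <- baum_welch_fit(cell, init, tol = Inf)
  prof <- decode(fit, cell)
  expect_true(all(prof$states == 2))
})

test_that("decoding takes the max-posterior state with ties to the lower", {
  grid <- toy_grid(n_chrom = 1, chrom_bins = 3)
  gamma <- rbind(c(0.1, 0.2, 0.7, 0),
                 c(0.0, 0.5, 0.5, 0),
                 c(0.25, 0.25, 0.25, 0.25))
  fit <- structure(list(gamma = gamma,
                        cell = cell_counts("c", grid, c(1L, 1L, 1L))),
                   class = "hmm_fit")
  prof <- decode(fit)
  expect_equal(prof$states, c(2L, 1L, 0L))
})

test_that("segments are maximal constant-state runs that reconstruct states", {
  grid <- toy_grid(n_chrom = 2, chrom_bins = 5)
  states <- c(2, 2, 3, 3, 2, 2, 2, 2, 2, 2)
  prof <- cn_profile("c", grid, states)
  expect_equal(nrow(prof$segments), 4)    # 3 on chr1 + 1 on chr2
  rebuilt <- unlist(mapply(rep, prof$segments$state, prof$segments$n_bins,
                           SIMPLIFY = FALSE))
  expect_equal(as.integer(rebuilt), as.integer(states))
})

test_that("decoded states are invariant to proportional count scaling", {
  grid <- toy_grid(n_chrom = 1, chrom_bins = 60)
  states_true <- rep(c(2L, 3L, 2L), times = c(20, 20, 20))
  base <- 40L
  cell1 <- cell_counts("a", grid, states_true * base)
  init1 <- list(model = emission_model(20, 20 / (20 + base)),
                A = {A <- matrix(0.001, 11, 11); diag(A) <- 0.99; A / rowSums(A)},
                pi = rep(1 / 11, 11))
  fit1 <- baum_welch_fit(cell1, init1, tol = Inf)
  cell2 <- cell_counts("b", grid, states_true * base * 3L)
  init2 <- init1
  init2$model <- emission_model(20, 20 / (20 + 3 * base))
  fit2 <- baum_welch_fit(cell2, init2, tol = Inf)
  expect_equal(decode(fit1, cell1)$states, states_true)
  expect_equal(decode(fit2, cell2)$states, decode(fit1, cell1)$states)
})

test_that("homozygous deletions decode to nullisomy over their full extent", {
  layout <- synthetic_layout(n_chrom = 3, chrom_bins = 40)
  truth <- simulate_karyotypes(layout, 1, q = 0, seed = 3)
  truth$states[1, 41:55] <- 0L                 # 15-bin deletion on chr2
  cell <- simulate_counts(truth, reads_per_cell = 6000, seed = 3)[[1]]
  expect_true(all(cell$counts[41:55] == 0))
  fit <- karyo_hmm(cell, n_restarts = 1)
  expect_true(all(fit$profile$states[41:55] == 0))
  expect_true(all(fit$profile$states[-(41:55)] == 2))
})

test_that("restarts leave clean fits unchanged", {
  layout <- synthetic_layout(n_chrom = 4, chrom_bins = 60)
  truth <- simulate_karyotypes(layout, 1, q = 0.2, seed = 23)
  cell <- simulate_counts(truth, reads_per_cell = 240 * 60, seed = 23)[[1]]
  f1 <- karyo_hmm(cell, n_restarts = 1)
  f5 <- karyo_hmm(cell, n_restarts = 5, seed = 42)
  expect_equal(f1$profile$states, f5$profile$states)
})

test_that("forcing the wrong modal ploidy lowers the loglikelihood", {
  # near-tetraploid cell with one pentasomic and one trisomic chromosome:
  # a modal-disomy interpretation cannot represent the odd-copy states
  layout <- synthetic_layout(n_chrom = 6, chrom_bins = 50)
  base <- c(4L, 4L, 5L, 4L, 3L, 4L)
  truth <- simulate_karyotypes(layout, 1, base_karyotype = base, q = 0, seed = 8)
  cell <- simulate_counts(truth, reads_per_cell = 300 * 50, seed = 8)[[1]]
  f4 <- karyo_hmm(cell, most_frequent_state = 4, n_restarts = 1)
  f2 <- karyo_hmm(cell, most_frequent_state = 2, n_restarts = 1)
  modal4 <- as.integer(names(which.max(table(f4$profile$states))))
  expect_equal(modal4, 4L)
  expect_lt(f2$loglik, f4$loglik)
})

test_that("profiles export as BED with posterior scores", {
  layout <- synthetic_layout(n_chrom = 2, chrom_bins = 20)
  truth <- simulate_karyotypes(layout, 1, q = 0.3, seed = 6)
  cell <- simulate_counts(truth, reads_per_cell = 2000, seed = 6)[[1]]
  fit <- karyo_hmm(cell, n_restarts = 1)
  bed <- tempfile(fileext = ".bed")
  write_profile_bed(fit$profile, bed)
  tab <- read.table(bed, sep = "\t")
  expect_equal(nrow(tab), 40)
  expect_true(all(tab$V4 %in% 0:10))
  expect_true(all(tab$V5 >= 0 & tab$V5 <= 1000))
})
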