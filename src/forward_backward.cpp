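#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over one or more independent observation
// sequences sharing parameters. E holds per-position emission
// probabilities already shifted so that each row's maximum is 1 (the
// caller adds the shift constants back to the loglikelihood). Returns the
// posterior matrix gamma, the expected transition counts summed over all
// positions and sequences (xi_sum), the summed posterior at sequence
// starts (for the initial-distribution update) and the scaled-part
// loglikelihood sum(log c_t).
// [[Rcpp::export]]
List fb_pass(NumericMatrix E, NumericMatrix A, NumericVector pi,
             IntegerVector seq_start, IntegerVector seq_len) {
  const int T = E.nrow(), S = E.ncol(), nseq = seq_start.size();
  NumericMatrix gamma(T, S);
  NumericMatrix xi(S, S);
  NumericVector start_gamma(S);
  double loglik = 0.0;

  std::vector<double> alpha((size_t)T * S), beta((size_t)T * S), c(T);

  for (int q = 0; q < nseq; ++q) {
    const int t0 = seq_start[q], L = seq_len[q];
    // forward
    for (int t = 0; t < L; ++t) {
      const int row = t0 + t;
      double csum = 0.0;
      for (int j = 0; j < S; ++j) {
        double a;
        if (t == 0) {
          a = pi[j];
        } else {
          a = 0.0;
          for (int i = 0; i < S; ++i)
            a += alpha[(size_t)(row - 1) * S + i] * A(i, j);
        }
        a *= E(row, j);
        alpha[(size_t)row * S + j] = a;
        csum += a;
      }
      if (!(csum > 0.0) || !R_finite(csum))
        stop("forward pass underflow at position %d", row + 1);
      for (int j = 0; j < S; ++j) alpha[(size_t)row * S + j] /= csum;
      c[row] = csum;
      loglik += std::log(csum);
    }
    // backward
    for (int j = 0; j < S; ++j) beta[(size_t)(t0 + L - 1) * S + j] = 1.0;
    for (int t = L - 2; t >= 0; --t) {
      const int row = t0 + t;
      for (int i = 0; i < S; ++i) {
        double b = 0.0;
        for (int j = 0; j < S; ++j)
          b += A(i, j) * E(row + 1, j) * beta[(size_t)(row + 1) * S + j];
        beta[(size_t)row * S + i] = b / c[row + 1];
      }
    }
    // posteriors and expected transition counts
    for (int t = 0; t < L; ++t) {
      const int row = t0 + t;
      double gsum = 0.0;
      for (int j = 0; j < S; ++j) {
        double g = alpha[(size_t)row * S + j] * beta[(size_t)row * S + j];
        gamma(row, j) = g;
        gsum += g;
      }
      for (int j = 0; j < S; ++j) gamma(row, j) /= gsum;
      if (t == 0)
        for (int j = 0; j < S; ++j) start_gamma[j] += gamma(row, j);
      if (t < L - 1) {
        for (int i = 0; i < S; ++i) {
          const double ai = alpha[(size_t)row * S + i];
          if (ai == 0.0) continue;
          for (int j = 0; j < S; ++j)
            xi(i, j) += ai * A(i, j) * E(row + 1, j) *
                        beta[(size_t)(row + 1) * S + j] / c[row + 1];
        }
      }
    }
  }
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi,
                      _["start_gamma"] = start_gamma, _["loglik"] = loglik);
}
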