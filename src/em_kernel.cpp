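#include <Rcpp.h>
using namespace Rcpp;

// Genotypes are stored column-major as raw bytes holding the R-allele count
// per diploid genotype: AA = 0, RA = 1, RR = 2.  The byte matrix keeps a
// 500,000 x 500 panel near 250 MB and halves the per-iteration memory
// traffic relative to a double matrix, which is what bounds EM throughput.

// Expected R-allele fraction per SNP: Total_R[m] = sum_n dosage[m,n] * theta[n],
// with dosage = g/2.  Accumulation is in double precision.
// [[Rcpp::export(name = ".em_totals")]]
NumericVector em_totals(RawMatrix g, NumericVector theta) {
  const R_xlen_t M = g.nrow(), N = g.ncol();
  if (theta.size() != N) stop("theta length does not match panel donor count");
  NumericVector total_r(M);
  double* tr = REAL(total_r);
  for (R_xlen_t n = 0; n < N; ++n) {
    const Rbyte* col = &g(0, n);
    const double th = 0.5 * theta[n];
    if (th == 0.0) continue;
    for (R_xlen_t m = 0; m < M; ++m) tr[m] += th * col[m];
  }
  return total_r;
}

// Per-donor likelihood scores.  With u[m] = Reads_R[m]/Total_R[m] and
// v[m] = Reads_A[m]/Total_A[m] (zeroed where the total is zero), the
// genotype-cased sum collapses to
//   L_n = theta_n * ( sum_m dosage[m,n] * (u[m] - v[m]) + sum_m v[m] )
// because the A-allele dosage is 1 - dosage.  w = u - v, sum_v = sum(v).
// [[Rcpp::export(name = ".em_scores")]]
NumericVector em_scores(RawMatrix g, NumericVector theta, NumericVector w,
                        double sum_v) {
  const R_xlen_t M = g.nrow(), N = g.ncol();
  if (theta.size() != N) stop("theta length does not match panel donor count");
  if (w.size() != M) stop("weight length does not match panel SNP count");
  NumericVector scores(N);
  const double* ww = REAL(w);
  for (R_xlen_t n = 0; n < N; ++n) {
    const Rbyte* col = &g(0, n);
    double acc0 = 0.0, acc1 = 0.0;
    R_xlen_t m = 0;
    for (; m + 1 < M; m += 2) {
      acc0 += ww[m] * col[m];
      acc1 += ww[m + 1] * col[m + 1];
    }
    if (m < M) acc0 += ww[m] * col[m];
    scores[n] = theta[n] * (0.5 * (acc0 + acc1) + sum_v);
  }
  return scores;
}
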