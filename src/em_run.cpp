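#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Full EM driver over the genotype byte matrix `g` (M SNPs x N donors,
// column-major).  Bytes hold the R-allele count per genotype: AA = 0,
// RA = 1, RR = 2.
//
// Under Hardy-Weinberg genotypes at common-variant allele frequencies about
// half the entries are 0, so the matrix is first packed into a CSC-style
// sparse index over SNPs: for each SNP, the heterozygous donor indices
// followed by the R-homozygous ones.  One EM iteration is then a single
// sequential sweep over the index; the per-SNP expected totals and every
// donor's likelihood score are accumulated while the column indices are
// cache resident.  theta, totals and scores accumulate in double precision.
//
// Per iteration t:
//   Total_R[m] = sum_n dosage[m,n] * theta[n]      (dosage = g/2)
//   u[m] = Reads_R[m]/Total_R[m], v[m] = Reads_A[m]/Total_A[m]
//     (a term whose total is <= 0 is skipped; such reads are tallied)
//   L_n  = theta[n] * ( sum_m over hets 0.5*(u[m]-v[m])
//                     + sum_m over R-homs (u[m]-v[m]) + sum_m v[m] )
//   theta'[n] = L_n / sum(L)
//
// Stops after max_iter iterations, or earlier when tol > 0 and
// max|theta' - theta| <= tol.  Optionally records the theta trace (rows
// theta^0 .. theta^T) and the observed-data log-likelihood of every
// recorded theta (including the final one).
// [[Rcpp::export(name = ".em_run")]]
List em_run(RawMatrix g, NumericVector r, NumericVector a,
            NumericVector theta0, int max_iter, double tol,
            bool record_trace, bool record_loglik) {
  const R_xlen_t M = g.nrow(), N = g.ncol();
  if (r.size() != M || a.size() != M)
    stop("counts are not aligned with the panel");
  if (theta0.size() != N) stop("theta0 length does not match donor count");
  if (N > 65535) stop("panels beyond 65535 donors are not supported");
  const Rbyte* G = RAW(g);
  const double* rr = REAL(r);
  const double* aa = REAL(a);

  // pack without transposing: count hets/homs per SNP, then fill
  std::vector<uint64_t> off(2 * M + 1, 0);  // off[2m]..off[2m+2] brackets
  {
    std::vector<uint32_t> n_het(M, 0), n_hom(M, 0);
    for (R_xlen_t n = 0; n < N; ++n) {
      const Rbyte* col = G + n * M;
      for (R_xlen_t m = 0; m < M; ++m) {
        n_het[m] += (col[m] == 1);
        n_hom[m] += (col[m] == 2);
      }
    }
    uint64_t k = 0;
    for (R_xlen_t m = 0; m < M; ++m) {
      off[2 * m] = k;
      k += n_het[m];
      off[2 * m + 1] = k;
      k += n_hom[m];
    }
    off[2 * M] = k;
  }
  std::vector<uint16_t> idx(off[2 * M]);
  {
    std::vector<uint64_t> fill_het(M), fill_hom(M);
    for (R_xlen_t m = 0; m < M; ++m) {
      fill_het[m] = off[2 * m];
      fill_hom[m] = off[2 * m + 1];
    }
    for (R_xlen_t n = 0; n < N; ++n) {
      const Rbyte* col = G + n * M;
      for (R_xlen_t m = 0; m < M; ++m) {
        if (col[m] == 1) idx[fill_het[m]++] = (uint16_t)n;
        else if (col[m] == 2) idx[fill_hom[m]++] = (uint16_t)n;
      }
    }
  }

  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> scores(N);
  NumericMatrix trace;
  NumericVector ll_trace;
  if (record_trace) trace = NumericMatrix(max_iter + 1, N);
  if (record_loglik) ll_trace = NumericVector(max_iter + 1);
  if (record_trace)
    for (R_xlen_t n = 0; n < N; ++n) trace(0, n) = theta[n];

  double dmax = NA_REAL;
  double skipped_r = 0.0, skipped_a = 0.0;
  int iter = 0;
  bool converged = false, degenerate = false;

  for (int t = 0; t < max_iter; ++t) {
    std::fill(scores.begin(), scores.end(), 0.0);
    double sum_v = 0.0, ll = 0.0;
    skipped_r = 0.0;
    skipped_a = 0.0;
    bool incompatible = false;
    double* sc = scores.data();
    const double* th = theta.data();

    for (R_xlen_t m = 0; m < M; ++m) {
      const uint64_t h0 = off[2 * m], h1 = off[2 * m + 1], h2 = off[2 * m + 2];
      double acc_het = 0.0, acc_hom = 0.0;
      for (uint64_t i = h0; i < h1; ++i) acc_het += th[idx[i]];
      for (uint64_t i = h1; i < h2; ++i) acc_hom += th[idx[i]];
      const double Tr = 0.5 * acc_het + acc_hom;
      const double Ta = 1.0 - Tr;
      const double ri = rr[m], ai = aa[m];
      double u = 0.0, v = 0.0;
      if (Tr > 0.0) {
        u = ri / Tr;
        if (record_loglik && ri > 0.0) ll += ri * std::log(Tr);
      } else if (ri > 0.0) {
        skipped_r += ri;
        incompatible = true;
      }
      if (Ta > 0.0) {
        v = ai / Ta;
        if (record_loglik && ai > 0.0) ll += ai * std::log(Ta);
      } else if (ai > 0.0) {
        skipped_a += ai;
        incompatible = true;
      }
      sum_v += v;
      const double w = u - v;
      if (w != 0.0) {
        const double wh = 0.5 * w;
        for (uint64_t i = h0; i < h1; ++i) sc[idx[i]] += wh;
        for (uint64_t i = h1; i < h2; ++i) sc[idx[i]] += w;
      }
    }
    if (record_loglik) ll_trace[t] = incompatible ? R_NegInf : ll;

    double sum_L = 0.0;
    for (R_xlen_t n = 0; n < N; ++n) {
      scores[n] = theta[n] * (scores[n] + sum_v);
      sum_L += scores[n];
    }
    if (!(sum_L > 0.0)) { degenerate = true; iter = t; break; }

    dmax = 0.0;
    for (R_xlen_t n = 0; n < N; ++n) {
      const double nu = scores[n] / sum_L;
      const double d = std::fabs(nu - theta[n]);
      if (d > dmax) dmax = d;
      theta[n] = nu;
    }
    iter = t + 1;
    if (record_trace)
      for (R_xlen_t n = 0; n < N; ++n) trace(iter, n) = theta[n];
    if (tol > 0.0 && dmax <= tol) { converged = true; break; }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }

  // log-likelihood of the final theta needs one more totals sweep
  if (record_loglik && !degenerate) {
    double ll = 0.0;
    bool incompatible = false;
    const double* th = theta.data();
    for (R_xlen_t m = 0; m < M; ++m) {
      const uint64_t h0 = off[2 * m], h1 = off[2 * m + 1], h2 = off[2 * m + 2];
      double acc_het = 0.0, acc_hom = 0.0;
      for (uint64_t i = h0; i < h1; ++i) acc_het += th[idx[i]];
      for (uint64_t i = h1; i < h2; ++i) acc_hom += th[idx[i]];
      const double Tr = 0.5 * acc_het + acc_hom;
      const double ri = rr[m], ai = aa[m];
      if (ri > 0.0) {
        if (Tr > 0.0) ll += ri * std::log(Tr); else incompatible = true;
      }
      if (ai > 0.0) {
        if (1.0 - Tr > 0.0) ll += ai * std::log(1.0 - Tr);
        else incompatible = true;
      }
    }
    ll_trace[iter] = incompatible ? R_NegInf : ll;
  }

  List out = List::create(
    _["theta"] = NumericVector(theta.begin(), theta.end()),
    _["iterations"] = iter,
    _["converged"] = converged,
    _["degenerate"] = degenerate,
    _["last_change"] = dmax,
    _["skipped_r_reads"] = skipped_r,
    _["skipped_a_reads"] = skipped_a);
  if (record_trace) {
    out["trace"] = trace(Range(0, iter), _);
  }
  if (record_loglik) {
    out["loglik_trace"] = ll_trace[Range(0, iter)];
  }
  return out;
}
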