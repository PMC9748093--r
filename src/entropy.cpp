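#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Shared O(N^2) pass computing ApEn and SampEn match counts for embedding
// dimensions m and m+1 at several tolerances r.
//
// ApEn: per-template counts including the self-match, templates i = 1..N-m+1
// for dimension m and 1..N-m for dimension m+1; Phi^m = mean(log C_i^m).
// SampEn: pair counts excluding self-matches with both template sets
// restricted to i = 1..N-m (so numerator and denominator are comparable);
// SampEn = -log(A/B).
//
// metric: 0 = euclidean (d = sqrt(sum of squares) <= r), 1 = chebyshev.
// [[Rcpp::export]]
List cpp_entropy_counts(NumericVector x, int m, NumericVector r, int metric) {
  const int N = x.size();
  const int nr = r.size();
  if (N <= m + 1) stop("series too short: need N > m + 1");
  const int Nm = N - m + 1;   // templates of length m
  const int Nm1 = N - m;      // templates of length m + 1

  std::vector<double> r2(nr);
  double rmax2 = 0.0;
  for (int q = 0; q < nr; ++q) {
    if (r[q] <= 0) stop("tolerance r must be positive");
    r2[q] = (metric == 0) ? r[q] * r[q] : r[q];
    if (r2[q] > rmax2) rmax2 = r2[q];
  }

  // counts_m[q * Nm + i], self-match included
  std::vector<double> counts_m(static_cast<size_t>(nr) * Nm, 1.0);
  std::vector<double> counts_m1(static_cast<size_t>(nr) * Nm1, 1.0);
  std::vector<double> A(nr, 0.0), B(nr, 0.0);

  const double* xs = REAL(x);
  for (int i = 0; i < Nm - 1; ++i) {
    for (int j = i + 1; j < Nm; ++j) {
      double dm;
      if (metric == 0) {
        double s = 0.0;
        int k = 0;
        for (; k < m; ++k) {
          const double d = xs[i + k] - xs[j + k];
          s += d * d;
          if (s > rmax2) break;
        }
        if (k < m) continue;  // no tolerance can match
        dm = s;
      } else {
        double s = 0.0;
        int k = 0;
        for (; k < m; ++k) {
          const double d = std::fabs(xs[i + k] - xs[j + k]);
          if (d > s) s = d;
          if (s > rmax2) break;
        }
        if (k < m) continue;
        dm = s;
      }
      const bool in_m1_range = (j < Nm1);  // both templates exist at m + 1
      double dm1 = R_PosInf;
      if (in_m1_range) {
        const double d = xs[i + m] - xs[j + m];
        dm1 = (metric == 0) ? dm + d * d : std::max(dm, std::fabs(d));
      }
      for (int q = 0; q < nr; ++q) {
        if (dm <= r2[q]) {
          counts_m[static_cast<size_t>(q) * Nm + i] += 1.0;
          counts_m[static_cast<size_t>(q) * Nm + j] += 1.0;
          if (in_m1_range) B[q] += 1.0;
        }
        if (in_m1_range && dm1 <= r2[q]) {
          counts_m1[static_cast<size_t>(q) * Nm1 + i] += 1.0;
          counts_m1[static_cast<size_t>(q) * Nm1 + j] += 1.0;
          A[q] += 1.0;
        }
      }
    }
  }

  NumericVector apen(nr), sampen(nr), Aout(nr), Bout(nr);
  for (int q = 0; q < nr; ++q) {
    double phi_m = 0.0, phi_m1 = 0.0;
    for (int i = 0; i < Nm; ++i)
      phi_m += std::log(counts_m[static_cast<size_t>(q) * Nm + i] / Nm);
    phi_m /= Nm;
    for (int i = 0; i < Nm1; ++i)
      phi_m1 += std::log(counts_m1[static_cast<size_t>(q) * Nm1 + i] / Nm1);
    phi_m1 /= Nm1;
    apen[q] = phi_m - phi_m1;
    Aout[q] = A[q];
    Bout[q] = B[q];
    sampen[q] = (A[q] > 0.0 && B[q] > 0.0) ? -std::log(A[q] / B[q]) : R_PosInf;
  }
  return List::create(_["apen"] = apen, _["sampen"] = sampen,
                      _["A"] = Aout, _["B"] = Bout);
}

// Lempel-Ziv 1976 exhaustive-history parsing count c(n): the sequence is
// parsed left to right into the minimal number of words, each word being
// extended while it can still be reproduced from the extended prefix (an
// occurrence starting strictly before the word, overlap allowed); the count
// increments once per completed word, including the final (possibly still
// reproducible) word.
// [[Rcpp::export]]
int cpp_lz76_count(IntegerVector s) {
  const int n = s.size();
  if (n == 0) stop("empty sequence");
  int c = 0;
  int pos = 0;
  while (pos < n) {
    int len = 1;
    int cand = -1;  // remembered occurrence start for cheap extension
    while (pos + len <= n) {
      // is s[pos .. pos+len-1] a substring of s[0 .. pos+len-2]?
      bool found = false;
      if (cand >= 0 && cand + len - 1 <= pos + len - 2 &&
          s[cand + len - 1] == s[pos + len - 1]) {
        found = true;  // previous occurrence extends by one symbol
      } else {
        for (int q = 0; q + len - 1 <= pos + len - 2; ++q) {
          bool ok = true;
          for (int k = 0; k < len; ++k) {
            if (s[q + k] != s[pos + k]) { ok = false; break; }
          }
          if (ok) { cand = q; found = true; break; }
        }
      }
      if (!found) break;
      ++len;
    }
    // word is s[pos .. pos+len-1]: either first non-reproducible extension,
    // or the reproducible tail that hit the end of the sequence
    if (pos + len > n) len = n - pos;
    ++c;
    pos += len;
  }
  return c;
}
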