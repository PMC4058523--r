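#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Per-feature LSOSS building blocks for a matrix of features x samples and a
// set of case-column assignments (observed labels plus label permutations).
// For each feature and assignment: sort the case values, find the contiguous
// split k minimising the summed within-subset sums of squares (ties -> the
// smallest k), pick as outlier subset the side whose mean is farther from the
// control mean (ties -> the upper side), and return the contrast numerator
// mean(O) - mean(control), the pooled SD over O and controls
// (|O| + n_control - 2 df), the outlier-subset size and the split index.
// The t-statistic itself is assembled in R where the variance floor applies.
// [[Rcpp::export]]
List lsoss_core(NumericMatrix X, IntegerMatrix caseIdx) {
  const int F = X.nrow(), N = X.ncol();
  const int P = caseIdx.ncol(), n1 = caseIdx.nrow();
  const int n0 = N - n1;
  if (n1 < 2 || n0 < 2)
    stop("need at least 2 case and 2 control samples");

  NumericMatrix num(F, P), sd(F, P);
  IntegerMatrix osize(F, P), ksplit(F, P);
  std::vector<double> cv(n1);
  std::vector<long double> cs(n1), cs2(n1);
  std::vector<bool> isCase(N);
  std::vector<int> ctrl;
  ctrl.reserve(n0);

  for (int p = 0; p < P; ++p) {
    std::fill(isCase.begin(), isCase.end(), false);
    for (int i = 0; i < n1; ++i) {
      int c = caseIdx(i, p) - 1;
      if (c < 0 || c >= N) stop("case index out of range");
      if (isCase[c]) stop("duplicate case index in a permutation");
      isCase[c] = true;
    }
    ctrl.clear();
    for (int j = 0; j < N; ++j)
      if (!isCase[j]) ctrl.push_back(j);

    for (int f = 0; f < F; ++f) {
      for (int i = 0; i < n1; ++i) cv[i] = X(f, caseIdx(i, p) - 1);
      long double csum = 0.0L, csq = 0.0L;
      for (size_t j = 0; j < ctrl.size(); ++j) {
        double v = X(f, ctrl[j]);
        csum += v;
        csq += (long double)v * v;
      }
      double mc = (double)(csum / n0);
      double ssc = (double)(csq - csum * csum / n0);
      if (ssc < 0) ssc = 0;

      std::sort(cv.begin(), cv.end());
      long double a = 0.0L, a2 = 0.0L;
      for (int i = 0; i < n1; ++i) {
        a += cv[i];
        a2 += (long double)cv[i] * cv[i];
        cs[i] = a;
        cs2[i] = a2;
      }

      double best = R_PosInf;
      int bk = 1;
      for (int k = 1; k < n1; ++k) {
        long double s1 = cs[k - 1], q1 = cs2[k - 1];
        long double s2 = cs[n1 - 1] - s1, q2 = cs2[n1 - 1] - q1;
        double cost = (double)((q1 - s1 * s1 / k) + (q2 - s2 * s2 / (n1 - k)));
        if (cost < 0) cost = 0;
        if (cost < best) { best = cost; bk = k; }
      }

      double mlo = (double)(cs[bk - 1] / bk);
      double mhi = (double)((cs[n1 - 1] - cs[bk - 1]) / (n1 - bk));
      bool useHi = std::fabs(mhi - mc) >= std::fabs(mlo - mc);
      int osz = useHi ? (n1 - bk) : bk;
      double mo = useHi ? mhi : mlo;
      long double s1 = cs[bk - 1], q1 = cs2[bk - 1];
      long double sso_l = useHi
        ? (cs2[n1 - 1] - q1) - (cs[n1 - 1] - s1) * (cs[n1 - 1] - s1) / (n1 - bk)
        : q1 - s1 * s1 / bk;
      double sso = (double)sso_l;
      if (sso < 0) sso = 0;
      int df = osz + n0 - 2;
      double sp2 = (sso + ssc) / df;
      if (sp2 < 0) sp2 = 0;

      num(f, p) = mo - mc;
      sd(f, p) = std::sqrt(sp2);
      osize(f, p) = osz;
      ksplit(f, p) = bk;
    }
  }
  return List::create(_["num"] = num, _["sd"] = sd,
                      _["osize"] = osize, _["ksplit"] = ksplit);
}
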