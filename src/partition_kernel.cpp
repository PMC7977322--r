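#include <Rcpp.h>
using namespace Rcpp;

// Recursive partitioning of breeding values by selection path.
//
// The pedigree must be topologically sorted (parents before offspring).
// sire/dam hold 1-based row indices of the parents (0 = unknown), path
// holds 1-based path indices, bv is n x nTraits. Parental expectation
// coefficients cSire/cDam are 1/2, 1/2 in sire-dam mode and 1/2, 1/4 in
// sire-mgs mode. For each individual, in pedigree order:
//   pa_i = cSire * bv_sire + cDam * bv_dam   (unknown parent -> 0)
//   w_i  = bv_i - pa_i
//   part_i = cSire * part_sire + cDam * part_dam, then w_i is added to
//   the component of i's own path.
// Founders therefore get pa = 0, w = bv and their whole breeding value
// credited to their own path.
//
// Returns pa (n x T), w (n x T) and one n x nPaths partition matrix per
// trait. All traits are carried through a single pedigree pass; each is
// partitioned independently.
// [[Rcpp::export(name = ".partition_kernel")]]
List partition_kernel(IntegerVector sire, IntegerVector dam,
                      IntegerVector path, NumericMatrix bv,
                      int nPaths, double cSire, double cDam) {
  const int n = bv.nrow();
  const int nT = bv.ncol();
  NumericMatrix pa(n, nT), w(n, nT);
  List parts(nT);
  std::vector<NumericMatrix> pm;
  pm.reserve(nT);
  for (int t = 0; t < nT; ++t) {
    NumericMatrix m(n, nPaths);
    parts[t] = m;
    pm.push_back(m);
  }
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1, p = path[i] - 1;
    if (s >= i || d >= i)
      stop("pedigree not sorted: parent after offspring at row %d", i + 1);
    for (int t = 0; t < nT; ++t) {
      double pav = 0.0;
      if (s >= 0) pav += cSire * bv(s, t);
      if (d >= 0) pav += cDam * bv(d, t);
      pa(i, t) = pav;
      const double wi = bv(i, t) - pav;
      w(i, t) = wi;
      NumericMatrix& m = pm[t];
      for (int k = 0; k < nPaths; ++k) {
        double v = 0.0;
        if (s >= 0) v += cSire * m(s, k);
        if (d >= 0) v += cDam * m(d, k);
        m(i, k) = v;
      }
      m(i, p) += wi;
    }
  }
  return List::create(_["pa"] = pa, _["w"] = w, _["parts"] = parts);
}

// Streaming variant: runs the same recursion but returns only per-group
// accumulators (count, sum of bv and of each path partition, per trait)
// instead of per-individual columns. group holds 1-based group indices.
// Long-double accumulation keeps the group means in step with R's mean().
// [[Rcpp::export(name = ".partition_group_kernel")]]
List partition_group_kernel(IntegerVector sire, IntegerVector dam,
                            IntegerVector path, NumericMatrix bv,
                            int nPaths, double cSire, double cDam,
                            IntegerVector group, int nGroups) {
  const int n = bv.nrow();
  const int nT = bv.ncol();
  std::vector<std::vector<long double>> sumBv(nT,
      std::vector<long double>(nGroups, 0.0L));
  std::vector<std::vector<long double>> sumPart(nT,
      std::vector<long double>((size_t)nGroups * nPaths, 0.0L));
  std::vector<double> work((size_t)n * nPaths * nT, 0.0);
  IntegerVector count(nGroups);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1, p = path[i] - 1;
    const int g = group[i] - 1;
    if (s >= i || d >= i)
      stop("pedigree not sorted: parent after offspring at row %d", i + 1);
    count[g] += 1;
    for (int t = 0; t < nT; ++t) {
      double pav = 0.0;
      if (s >= 0) pav += cSire * bv(s, t);
      if (d >= 0) pav += cDam * bv(d, t);
      const double wi = bv(i, t) - pav;
      double* row = &work[((size_t)t * n + i) * nPaths];
      const double* srow = s >= 0 ? &work[((size_t)t * n + s) * nPaths] : 0;
      const double* drow = d >= 0 ? &work[((size_t)t * n + d) * nPaths] : 0;
      for (int k = 0; k < nPaths; ++k) {
        double v = 0.0;
        if (srow) v += cSire * srow[k];
        if (drow) v += cDam * drow[k];
        row[k] = v;
      }
      row[p] += wi;
      sumBv[t][g] += bv(i, t);
      long double* gp = &sumPart[t][(size_t)g * nPaths];
      for (int k = 0; k < nPaths; ++k) gp[k] += row[k];
    }
  }
  List outBv(nT), outPart(nT);
  for (int t = 0; t < nT; ++t) {
    NumericVector sb(nGroups);
    NumericMatrix sp(nGroups, nPaths);
    for (int g = 0; g < nGroups; ++g) {
      sb[g] = (double)sumBv[t][g];
      for (int k = 0; k < nPaths; ++k)
        sp(g, k) = (double)sumPart[t][(size_t)g * nPaths + k];
    }
    outBv[t] = sb;
    outPart[t] = sp;
  }
  return List::create(_["n"] = count, _["sum_bv"] = outBv,
                      _["sum_part"] = outPart);
}
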