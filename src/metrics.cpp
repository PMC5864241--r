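#include <Rcpp.h>
using namespace Rcpp;

// Mean nearest taxon distance per sample.
// X: taxa x samples abundance matrix; D: taxa x taxa distance matrix
// aligned to the rows of X. Samples with fewer than two present taxa
// yield NA (no nearest-neighbour distance is defined).
// [[Rcpp::export]]
NumericVector cpp_mntd(const NumericMatrix& X, const NumericMatrix& D,
                       const bool weighted) {
  const int nt = X.nrow(), ns = X.ncol();
  NumericVector out(ns);
  std::vector<int> idx;
  idx.reserve(nt);
  for (int s = 0; s < ns; ++s) {
    idx.clear();
    double tot = 0.0;
    for (int i = 0; i < nt; ++i)
      if (X(i, s) > 0) { idx.push_back(i); tot += X(i, s); }
    const int k = (int) idx.size();
    if (k < 2) { out[s] = NA_REAL; continue; }
    double acc = 0.0;
    for (int a = 0; a < k; ++a) {
      double mn = R_PosInf;
      for (int b = 0; b < k; ++b) {
        if (b == a) continue;
        const double d = D(idx[a], idx[b]);
        if (d < mn) mn = d;
      }
      acc += weighted ? (X(idx[a], s) / tot) * mn : mn / k;
    }
    out[s] = acc;
  }
  return out;
}

// betaMNTD for every unordered sample pair.
// For pair (k, m): 0.5 * [ sum_i f_ik * min_j d(i, j) + sum_j f_jm * min_i d(j, i) ]
// with the minimum taken over taxa present in the other sample; a taxon
// shared by both samples matches itself at distance zero (diag(D) == 0).
// Unweighted: the plain mean over all nearest-taxon distances pooled from
// both directions (the comdistnt convention).
// [[Rcpp::export]]
NumericMatrix cpp_bmntd(const NumericMatrix& X, const NumericMatrix& D,
                        const bool weighted) {
  const int nt = X.nrow(), ns = X.ncol();
  std::vector< std::vector<int> > idx(ns);
  std::vector< std::vector<double> > w(ns);
  for (int s = 0; s < ns; ++s) {
    double tot = 0.0;
    for (int i = 0; i < nt; ++i)
      if (X(i, s) > 0) { idx[s].push_back(i); tot += X(i, s); }
    const int k = (int) idx[s].size();
    w[s].resize(k);
    for (int a = 0; a < k; ++a)
      w[s][a] = weighted ? X(idx[s][a], s) / tot : 1.0;
  }
  NumericMatrix out(ns, ns);
  for (int s = 0; s < ns; ++s) out(s, s) = NA_REAL;
  for (int p = 0; p < ns; ++p) {
    for (int q = p + 1; q < ns; ++q) {
      if (idx[p].empty() || idx[q].empty()) {
        out(p, q) = out(q, p) = NA_REAL;
        continue;
      }
      double half1 = 0.0, half2 = 0.0;
      for (size_t a = 0; a < idx[p].size(); ++a) {
        double mn = R_PosInf;
        const int i = idx[p][a];
        for (size_t b = 0; b < idx[q].size(); ++b) {
          const double d = D(i, idx[q][b]);
          if (d < mn) mn = d;
        }
        half1 += w[p][a] * mn;
      }
      for (size_t b = 0; b < idx[q].size(); ++b) {
        double mn = R_PosInf;
        const int j = idx[q][b];
        for (size_t a = 0; a < idx[p].size(); ++a) {
          const double d = D(j, idx[p][a]);
          if (d < mn) mn = d;
        }
        half2 += w[q][b] * mn;
      }
      out(p, q) = out(q, p) = weighted ?
        0.5 * (half1 + half2) :
        (half1 + half2) / (double)(idx[p].size() + idx[q].size());
    }
  }
  return out;
}
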