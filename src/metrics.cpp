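#include <Rcpp.h>
using namespace Rcpp;

// Floyd-Warshall on a dense length matrix (Inf = no edge, diagonal 0).
static void fw_inplace(std::vector<double>& d, int n) {
  for (int k = 0; k < n; ++k) {
    for (int j = 0; j < n; ++j) {
      double dkj = d[k + n * j];
      if (!R_FINITE(dkj)) continue;
      for (int i = 0; i < n; ++i) {
        double via = d[i + n * k] + dkj;
        if (via < d[i + n * j]) d[i + n * j] = via;
      }
    }
  }
}

// [[Rcpp::export(name = ".fw_dist")]]
NumericMatrix fw_dist(NumericMatrix len) {
  int n = len.nrow();
  std::vector<double> d(len.begin(), len.end());
  fw_inplace(d, n);
  NumericMatrix out(n, n);
  std::copy(d.begin(), d.end(), out.begin());
  out.attr("dimnames") = len.attr("dimnames");
  return out;
}

// Local efficiency of selected nodes: efficiency of the weighted
// subgraph induced by each node's neighbours (lengths 1/w), 0 when the
// node has fewer than two neighbours.
// [[Rcpp::export(name = ".local_eff")]]
NumericVector local_eff(NumericMatrix w, IntegerVector nodes) {
  int n = w.nrow();
  NumericVector out(nodes.size());
  std::vector<int> nb;
  std::vector<double> d;
  for (int t = 0; t < nodes.size(); ++t) {
    int i = nodes[t] - 1;
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (w(i, j) > 0) nb.push_back(j);
    }
    int m = (int)nb.size();
    if (m < 2) { out[t] = 0.0; continue; }
    d.assign((size_t)m * m, R_PosInf);
    for (int a = 0; a < m; ++a) {
      d[a + m * a] = 0.0;
      for (int b = 0; b < m; ++b) {
        if (a != b && w(nb[a], nb[b]) > 0) d[a + m * b] = 1.0 / w(nb[a], nb[b]);
      }
    }
    fw_inplace(d, m);
    double acc = 0.0;
    for (int a = 0; a < m; ++a) {
      for (int b = 0; b < m; ++b) {
        if (a != b && R_FINITE(d[a + m * b])) acc += 1.0 / d[a + m * b];
      }
    }
    out[t] = acc / ((double)m * (m - 1));
  }
  return out;
}
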