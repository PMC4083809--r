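#include <Rcpp.h>
using namespace Rcpp;

// Correlation of 2-D fields with a binary ball stencil, summing in-domain
// pixels only (the discrete analogue of integrating B(x,y)f(y) over the
// image domain). Interior pixels use precomputed linear offsets; border
// pixels fall back to bounds-checked gathering. Summation order is fixed,
// so results are bit-reproducible.

namespace {

struct Taps {
  std::vector<int> di, dj, lin;
  std::vector<double> w;
  int k;
};

Taps make_taps(const NumericMatrix& kernel, int nr) {
  Taps t;
  int kr = kernel.nrow(), kc = kernel.ncol();
  t.k = kr / 2;
  for (int b = 0; b < kc; ++b)
    for (int a = 0; a < kr; ++a)
      if (kernel(a, b) != 0.0) {
        int di = a - t.k, dj = b - kc / 2;
        t.di.push_back(di);
        t.dj.push_back(dj);
        t.lin.push_back(di + dj * nr);
        t.w.push_back(kernel(a, b));
      }
  return t;
}

void correlate_one(const double* x, double* out, int nr, int nc,
                   const Taps& t) {
  int k = t.k;
  int K = (int)t.di.size();
  bool unit = true;
  for (int q = 0; q < K; ++q)
    if (t.w[q] != 1.0) { unit = false; break; }
  for (int j = 0; j < nc; ++j) {
    bool jin = (j >= k) && (j < nc - k);
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      if (jin && i >= k && i < nr - k) {
        const double* p = x + i + j * nr;
        if (unit) {
          for (int q = 0; q < K; ++q) s += p[t.lin[q]];
        } else {
          for (int q = 0; q < K; ++q) s += t.w[q] * p[t.lin[q]];
        }
      } else {
        for (int q = 0; q < K; ++q) {
          int ii = i + t.di[q], jj = j + t.dj[q];
          if (ii >= 0 && ii < nr && jj >= 0 && jj < nc)
            s += t.w[q] * x[ii + jj * nr];
        }
      }
      out[i + j * nr] = s;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix ball_correlate_cpp(NumericMatrix x, NumericMatrix kernel) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  Taps t = make_taps(kernel, nr);
  correlate_one(x.begin(), out.begin(), nr, nc, t);
  return out;
}

// Same gather applied to several fields at once.

// [[Rcpp::export]]
List ball_correlate_many_cpp(List xs, NumericMatrix kernel) {
  int m = xs.size();
  List res(m);
  NumericMatrix first = as<NumericMatrix>(xs[0]);
  int nr = first.nrow(), nc = first.ncol();
  Taps t = make_taps(kernel, nr);
  for (int q = 0; q < m; ++q) {
    NumericMatrix xi = as<NumericMatrix>(xs[q]);
    NumericMatrix oi(nr, nc);
    correlate_one(xi.begin(), oi.begin(), nr, nc, t);
    res[q] = oi;
  }
  return res;
}
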